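make_track <- function(x, y, dt = 5, id = 1L) {
  track(track_id = id, frame = seq_along(x) - 1L, x_um = x, y_um = y,
        dt_s = dt)
}

test_that("linking follows single detections and obeys the gap-frame bound", {
  # one detection per frame drifting 1 um/frame
  det <- lapply(0:9, function(f) data.frame(x_um = f * 1, y_um = 0))
  ts <- link_tracks(det, link_params(), dt_s = 5)
  expect_equal(length(ts$tracks), 1L)
  expect_equal(nrow(ts$tracks[[1L]]), 10L)
  expect_equal(ts$tracks[[1L]]$x_um, 0:9)

  # 6-frame hole with gap_max_frames = 5: two separate tracks
  det_gap <- lapply(0:19, function(f) {
    if (f >= 7 && f <= 12) data.frame(x_um = numeric(0), y_um = numeric(0))
    else data.frame(x_um = f * 0.5, y_um = 0)
  })
  ts2 <- link_tracks(det_gap, link_params(), dt_s = 5)
  expect_equal(length(ts2$tracks), 2L)

  # a 5-frame hole is bridged
  det_gap5 <- lapply(0:19, function(f) {
    if (f >= 7 && f <= 11) data.frame(x_um = numeric(0), y_um = numeric(0))
    else data.frame(x_um = f * 0.5, y_um = 0)
  })
  ts3 <- link_tracks(det_gap5, link_params(), dt_s = 5)
  expect_equal(length(ts3$tracks), 1L)
  expect_equal(nrow(ts3$tracks[[1L]]), 15L)
})

test_that("two well-separated crossing walkers link like the optimal assignment", {
  set.seed(77)
  for (rep in 1:50) {
    # two constant-velocity walkers whose mutual distance stays well above
    # the per-frame step, so the optimal frame assignment is unambiguous
    v1 <- stats::runif(2, -1, 1); v2 <- stats::runif(2, -1, 1)
    p1 <- c(0, 0); p2 <- c(30, 30)
    nf <- 12L
    det <- lapply(seq_len(nf) - 1L, function(f) {
      data.frame(x_um = c(p1[1] + f * v1[1], p2[1] + f * v2[1]),
                 y_um = c(p1[2] + f * v1[2], p2[2] + f * v2[2]))
    })
    ts <- link_tracks(det, link_params(), dt_s = 1)
    expect_equal(length(ts$tracks), 2L)
    ends <- vapply(ts$tracks, function(tr) c(tr$x_um[1L], tr$y_um[1L]),
                   numeric(2L))
    # per-frame brute-force minimal-total-distance assignment keeps each
    # walker on its own track, so both tracks are straight lines
    for (tr in ts$tracks) {
      expect_equal(diff(tr$x_um), rep(diff(tr$x_um)[1L], nf - 1L))
      expect_equal(diff(tr$y_um), rep(diff(tr$y_um)[1L], nf - 1L))
    }
    expect_equal(sort(ends[1L, ]), c(0, 30))
  }
})

test_that("track speed is the mean of per-interval speeds in um/min", {
  tr <- make_track(x = seq(0, 9), y = rep(0, 10), dt = 5)  # 1 um / 5 s
  expect_equal(track_speed(tr), 12)
  expect_equal(track_speed(make_track(rep(2, 8), rep(3, 8))), 0)
  set.seed(9)
  trr <- make_track(cumsum(rnorm(20)), cumsum(rnorm(20)), dt = 15)
  manual <- {
    sp <- c()
    for (i in 1:19) {
      d <- sqrt((trr$x_um[i + 1] - trr$x_um[i])^2 +
                  (trr$y_um[i + 1] - trr$y_um[i])^2)
      sp <- c(sp, d / 15 * 60)
    }
    mean(sp)
  }
  expect_equal(track_speed(trr), manual)
  expect_error(track_speed(make_track(1, 1)), "2 samples")
})

test_that("MSD obeys the stationary and ballistic closed forms", {
  still <- track_set(lapply(1:3, function(i) make_track(rep(i, 12), rep(0, 12))),
                     dt_s = 5)
  expect_true(all(msd(still)$msd_um2 == 0))

  v <- 0.4  # um/s
  ball <- track_set(list(make_track((0:20) * v * 5, rep(0, 21), dt = 5)),
                    dt_s = 5)
  curve <- msd(ball)
  expect_true(all(abs(curve$msd_um2 - (v * curve$lag_s)^2) /
                    (v * curve$lag_s)^2 <= 1e-9))
})

test_that("MSD equals the all-overlapping-pairs oracle exactly", {
  set.seed(31)
  tracks <- lapply(1:50, function(i) {
    n <- sample(8:25, 1L)
    make_track(cumsum(rnorm(n)), cumsum(rnorm(n)), dt = 5, id = i)
  })
  ts <- track_set(tracks, dt_s = 5)
  curve <- msd(ts)
  per_track <- lapply(tracks, function(tr) {
    oracle_msd_track(tr, seq_len(max(1L, floor(0.5 * (nrow(tr) - 1L)))))
  })
  for (lag_i in seq_len(nrow(curve))) {
    vals <- unlist(lapply(per_track, function(v)
      if (length(v) >= lag_i) v[lag_i] else NULL))
    expect_equal(curve$msd_um2[lag_i], mean(vals), tolerance = 1e-12)
    expect_identical(curve$n[lag_i], length(vals))
  }
})

test_that("random-walk ensemble MSD matches 2*sigma^2*n at small lags", {
  set.seed(55)
  sigma <- 0.8
  tracks <- lapply(1:500, function(i) {
    make_track(cumsum(rnorm(20, 0, sigma)), cumsum(rnorm(20, 0, sigma)),
               dt = 5, id = i)
  })
  curve <- msd(track_set(tracks, dt_s = 5))
  for (n_lag in 1:3) {
    expect_lt(abs(curve$msd_um2[n_lag] - 2 * sigma^2 * n_lag) /
                (2 * sigma^2 * n_lag), 0.05)
  }
})

test_that("speed and MSD are invariant under global translation and rotation", {
  set.seed(8)
  tracks <- lapply(1:5, function(i)
    make_track(cumsum(rnorm(15)), cumsum(rnorm(15)), id = i))
  ts <- track_set(tracks, dt_s = 5)
  th <- 0.7; shift <- c(40, -12)
  moved <- track_set(lapply(tracks, function(tr) {
    x2 <- cos(th) * tr$x_um - sin(th) * tr$y_um + shift[1L]
    y2 <- sin(th) * tr$x_um + cos(th) * tr$y_um + shift[2L]
    make_track(x2, y2, id = attr(tr, "track_id"))
  }), dt_s = 5)
  expect_equal(vapply(ts$tracks, track_speed, numeric(1L)),
               vapply(moved$tracks, track_speed, numeric(1L)))
  expect_equal(msd(ts)$msd_um2, msd(moved)$msd_um2)
})

test_that("chemotaxis gate counts strictly positive net displacement", {
  toward <- lapply(1:7, function(i) make_track(c(0, 5), c(0, 0), id = i))
  away <- lapply(8:10, function(i) make_track(c(0, -1), c(0, 2), id = i))
  ts <- track_set(c(toward, away), dt_s = 15)
  g <- chemotaxis_gate(ts, threshold = 0.8)
  expect_equal(g$fraction_toward, 0.7)
  expect_false(g$passed)

  all_toward <- track_set(lapply(1:10, function(i)
    make_track(c(0, 1), c(0, 0), id = i)), dt_s = 15)
  expect_true(chemotaxis_gate(all_toward)$passed)

  # zero net displacement counts against (strict inequality)
  loop <- track_set(list(make_track(c(0, 3, 0), c(0, 1, 0))), dt_s = 15)
  expect_equal(chemotaxis_gate(loop)$fraction_toward, 0)
})

test_that("fully biased synthetic track sets always pass the gate", {
  for (seed in 1:10) {
    ts <- gen_tracks(prw_params(bias_strength = 1, n_tracks = 20L,
                                n_frames = 15L, seed = seed))
    expect_true(chemotaxis_gate(ts)$passed)
  }
})

test_that("spider coordinates shift every track to the origin", {
  tr <- make_track(c(5, 6, 9), c(7, 7, 4))
  sp <- spider_coordinates(track_set(list(tr), dt_s = 5))
  expect_equal(sp$tracks[[1L]]$x_um[1L], 0)
  expect_equal(sp$tracks[[1L]]$y_um[1L], 0)
  # translation invariance
  tr2 <- make_track(c(5, 6, 9) + 11, c(7, 7, 4) + 11)
  sp2 <- spider_coordinates(track_set(list(tr2), dt_s = 5))
  expect_equal(sp$tracks[[1L]]$x_um, sp2$tracks[[1L]]$x_um)
  expect_equal(sp$tracks[[1L]]$y_um, sp2$tracks[[1L]]$y_um)
  # endpoint equals the net displacement vector
  expect_equal(sp$tracks[[1L]]$x_um[3L], 9 - 5)
  expect_equal(sp$tracks[[1L]]$y_um[3L], 4 - 7)
})

test_that("gradient profile recovers flat fields and linear ramps", {
  flat <- plane_image(matrix(120, 40, 60))
  gp <- gradient_profile(flat, "x")
  expect_equal(gp$slope, 0)
  expect_true(all(gp$profile == 120))

  ramp <- plane_image(matrix(rep(0:59, each = 40), 40, 60))
  gpr <- gradient_profile(ramp, "x")
  expect_equal(gpr$slope, 1)
  expect_equal(gpr$monotone_trend, 1)

  # noisy ramps: slope within 3 standard errors, 100 seeds
  for (seed in 1:100) {
    set.seed(seed)
    noisy <- matrix(rep(0:59, each = 40), 40, 60) +
      matrix(rnorm(2400, 0, 10), 40, 60)
    noisy <- pmin(pmax(round(noisy), 0), 65535)
    gpn <- gradient_profile(plane_image(noisy), "x")
    fit <- stats::lm(gpn$profile ~ gpn$position_px)
    se <- summary(fit)$coefficients[2L, 2L]
    expect_lt(abs(gpn$slope - 1), 3 * se + 0.05)
  }
})

test_that("tracks survive a CSV round trip", {
  ts <- gen_tracks(prw_params(n_tracks = 4L, n_frames = 10L, seed = 6L))
  f <- tempfile(fileext = ".csv")
  write_tracks_csv(ts, f)
  back <- read_tracks_csv(f, dt_s = 5)
  expect_equal(length(back$tracks), 4L)
  for (i in 1:4) {
    expect_equal(back$tracks[[i]]$x_um, ts$tracks[[i]]$x_um,
                 tolerance = 1e-4)
  }
})

test_that("positional noise never decreases mean measured speed", {
  for (seed in 1:100) {
    set.seed(seed)
    tracks <- lapply(1:5, function(i)
      make_track(cumsum(rnorm(40, 0, 0.5)), cumsum(rnorm(40, 0, 0.5)),
                 id = i))
    clean <- mean(vapply(tracks, track_speed, numeric(1L)))
    noisy_tracks <- lapply(tracks, function(tr) {
      make_track(tr$x_um + rnorm(40, 0, 0.5), tr$y_um + rnorm(40, 0, 0.5),
                 id = attr(tr, "track_id"))
    })
    noisy <- mean(vapply(noisy_tracks, track_speed, numeric(1L)))
    expect_gte(noisy, clean)
  }
})
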