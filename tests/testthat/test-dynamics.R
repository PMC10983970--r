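test_that("the 3x3 top-hat suppresses flat and smooth background", {
  const <- image_stack(list(matrix(500, 20, 20)))
  out <- regional_maxima_3x3(const)
  expect_true(all(out$frames[[1L]]$pixels == 0))

  # single pixel on zero background keeps its value
  m <- matrix(0, 15, 15); m[8, 8] <- 777
  out2 <- regional_maxima_3x3(plane_image(m))
  expect_equal(out2$pixels[8, 8], 777)
  expect_true(all(out2$pixels >= 0))
  expect_equal(sum(out2$pixels), 777)

  # linear ramp + one spot: ramp suppressed, spot preserved
  ramp <- matrix(rep(seq(0, 290, by = 10), each = 30), 30, 30)
  spot <- ramp; spot[15, 15] <- spot[15, 15] + 400
  th <- regional_maxima_3x3(plane_image(spot))$pixels
  expect_gte(th[15, 15], 400)
  th_nospot <- th; th_nospot[14:16, 14:16] <- 0
  expect_lte(max(th_nospot), 2 * 10)  # at most one ramp increment survives
})

test_that("the top-hat equals the brute-force erosion/dilation oracle", {
  set.seed(17)
  m <- matrix(sample(0:2000, 18 * 22, replace = TRUE), 18, 22)
  expect_equal(regional_maxima_3x3(plane_image(m))$pixels, oracle_tophat3(m))
})

test_that("the top-hat is invariant to adding a constant offset", {
  set.seed(23)
  m <- matrix(sample(0:500, 400, replace = TRUE), 20, 20)
  t1 <- regional_maxima_3x3(plane_image(m))$pixels
  t2 <- regional_maxima_3x3(plane_image(m + 1000))$pixels
  expect_equal(t1, t2)
})

make_ptrack <- function(id, frames, pixel) {
  list(id = id, frames = as.integer(frames),
       pixels = rep(list(pixel), length(frames)))
}

test_that("trace extraction enforces endpoint, duration and overlap rules", {
  frames <- lapply(1:20, function(i) matrix(i * 10, 8, 8))
  stk <- image_stack(frames, frame_interval_s = 0.75)
  tracks <- list(
    make_ptrack(1L, 0:10, 5L),    # touches frame 0: dropped
    make_ptrack(2L, 5:11, 6L),    # 7 frames < 8: dropped
    make_ptrack(3L, 13:19, 7L),   # touches last frame: dropped
    make_ptrack(4L, 4:15, 9L),    # survives
    make_ptrack(5L, c(3, 5:13), 10L)  # skips frame 4: dropped
  )
  traces <- extract_traces(stk, tracks)
  expect_equal(length(traces), 1L)
  expect_equal(attr(traces[[1L]], "id"), 4L)
  expect_equal(traces[[1L]]$value[1L], 0)  # baseline subtracted
  expect_equal(traces[[1L]]$t_s, (4:15) * 0.75)
  expect_equal(traces[[1L]]$value, (0:11) * 10)

  # two surviving tracks sharing a pixel in a common frame are both dropped
  tracks2 <- list(make_ptrack(1L, 4:15, 9L), make_ptrack(2L, 10:17, 9L),
                  make_ptrack(3L, 2:12, 20L))
  traces2 <- extract_traces(stk, tracks2)
  expect_equal(length(traces2), 1L)
  expect_equal(attr(traces2[[1L]], "id"), 3L)
})

test_that("running-average smoothing truncates at boundaries", {
  tr <- intensity_trace(t_s = 0:4, value = c(0, 0, 5, 0, 0))
  sm <- smooth_trace(tr, 5L)
  expect_equal(sm$value[3L], 1)
  expect_equal(sm$value[1L], mean(c(0, 0, 5)))  # truncated window
  expect_equal(nrow(sm), 5L)

  const <- intensity_trace(t_s = 0:9, value = rep(3.5, 10))
  expect_equal(smooth_trace(const)$value, rep(3.5, 10))

  set.seed(5)
  v <- rnorm(30)
  sm2 <- smooth_trace(intensity_trace(0:29, v), 5L)
  expect_true(all(sm2$value <= max(v) & sm2$value >= min(v)))
})

test_that("noiseless kinetic traces are recovered essentially exactly", {
  spec <- kinetic_trace_spec(A_asm = 100, r = 1, t0_s = 10,
                             k_dis = log(2) / 5, t_peak_s = 20,
                             n_frames = 60L)
  fit <- fit_lifetime(gen_intensity_trace(spec))
  expect_true(all(fit$converged))
  expect_lt(abs(fit$t_half_asm_s - 10) / 10, 0.01)
  expect_lt(abs(fit$t_half_dis_s - 25) / 25, 0.01)
  expect_lt(abs(fit$lifetime_s - 15) / 15, 0.01)
  expect_lt(abs(fit$A_asm - 100) / 100, 0.01)
  expect_lt(abs(fit$r - 1) / 1, 0.01)
})

test_that("monotone traces flag the missing branch and leave lifetime undefined", {
  rising <- intensity_trace(t_s = (0:19) * 0.75,
                            value = 100 / (1 + exp(-0.5 * ((0:19) * 0.75 - 6))))
  f <- fit_lifetime(rising)
  expect_false(f$converged[["disassembly"]])
  expect_true(is.na(f$lifetime_s))

  falling <- intensity_trace(t_s = (0:19) * 0.75,
                             value = 90 * exp(-0.2 * (0:19) * 0.75))
  f2 <- fit_lifetime(falling)
  expect_false(f2$converged[["assembly"]])
  expect_true(is.na(f2$lifetime_s))
})

test_that("lifetime fits are equivariant under time shift", {
  spec <- kinetic_trace_spec(n_frames = 60L)
  tr <- gen_intensity_trace(spec)
  f0 <- fit_lifetime(tr)
  shift <- 12.25
  tr_s <- intensity_trace(tr$t_s + shift, tr$value)
  f1 <- fit_lifetime(tr_s)
  expect_lt(abs(f1$t0_s - (f0$t0_s + shift)), 1e-6)
  expect_lt(abs(f1$t_half_dis_s - (f0$t_half_dis_s + shift)), 1e-6)
  expect_lt(abs(f1$lifetime_s - f0$lifetime_s), 1e-6)
})

test_that("amplitude scaling rescales amplitudes and preserves rates", {
  tr <- gen_intensity_trace(kinetic_trace_spec(n_frames = 60L))
  f1 <- fit_lifetime(tr)
  tr2 <- intensity_trace(tr$t_s, tr$value * 7)
  f2 <- fit_lifetime(tr2)
  expect_equal(f2$A_asm / f1$A_asm, 7, tolerance = 1e-6)
  expect_equal(f2$A_dis / f1$A_dis, 7, tolerance = 1e-6)
  expect_equal(f2$r, f1$r, tolerance = 1e-6)
  expect_equal(f2$k_dis, f1$k_dis, tolerance = 1e-6)
  expect_equal(f2$lifetime_s, f1$lifetime_s, tolerance = 1e-6)
})

test_that("noisy traces recover kinetics within 10% at the median", {
  ests <- sapply(1:100, function(s) {
    tr <- gen_intensity_trace(kinetic_trace_spec(noise_sd_frac = 0.05,
                                                 n_frames = 60L, seed = s))
    f <- fit_lifetime(smooth_trace(tr))
    c(t0 = f$t0_s, half_k = log(2) / f$k_dis)
  })
  expect_lt(abs(stats::median(ests["t0", ]) - 10) / 10, 0.10)
  expect_lt(abs(stats::median(ests["half_k", ]) - 5) / 5, 0.10)
})

test_that("the minimum-duration rule equals 6 s at default settings", {
  expect_equal(min_duration_s(), 6)
  expect_equal(min_duration_s(lifetime_params(min_frames = 10L,
                                              frame_interval_s = 0.5)), 5)
})

test_that("lifetime_fit behaves like a standard fitted-model object", {
  tr <- gen_intensity_trace(kinetic_trace_spec(n_frames = 60L))
  f <- fit_lifetime(tr)
  cf <- coef(f)
  expect_named(cf, c("A_asm", "r", "t0_s", "A_dis", "k_dis", "t_peak_s",
                     "t_half_asm_s", "t_half_dis_s", "lifetime_s"))
  expect_equal(length(fitted(f)), nrow(tr))
  expect_equal(residuals(f), tr$value - fitted(f))
  expect_output(print(f), "lifetime")
  expect_output(print(summary(f)), "SSE")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
  # predictions reproduce the noiseless model away from the peak
  expect_equal(predict(f, 5), 100 / (1 + exp(-0.5 * (5 - 10))),
               tolerance = 1e-4)
})

test_that("the sum-variant lifetime equals t0 plus the decay half-time", {
  tr <- gen_intensity_trace(kinetic_trace_spec(n_frames = 60L))
  f <- fit_lifetime(tr, lifetime_params(lifetime_mode = "sum"))
  expect_equal(f$lifetime_s, f$t_half_asm_s + log(2) / f$k_dis,
               tolerance = 1e-9)
})
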