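#' A single cell (or punctum) trajectory
#'
#' @param track_id identifier.
#' @param frame 0-based frame indices, strictly increasing.
#' @param x_um,y_um positions in micrometres.
#' @param dt_s uniform frame interval in seconds; sample times are
#'   `frame * dt_s`.
#' @return data.frame of class `track` with columns `frame`, `t_s`, `x_um`,
#'   `y_um` and attribute `track_id`.
#' @export
track <- function(track_id, frame, x_um, y_um, dt_s) {
  stopifnot(length(frame) == length(x_um), length(x_um) == length(y_um))
  if (any(diff(frame) <= 0)) stop("frame indices must be strictly increasing")
  if (dt_s <= 0) stop("dt_s must be > 0")
  out <- data.frame(frame = as.integer(frame), t_s = frame * dt_s,
                    x_um = x_um, y_um = y_um)
  attr(out, "track_id") <- track_id
  attr(out, "dt_s") <- dt_s
  class(out) <- c("track", "data.frame")
  out
}

#' A set of tracks sharing an acquisition interval
#'
#' @param tracks list of [track()] objects.
#' @param dt_s shared frame interval, s.
#' @param gradient_axis unit vector of the chemoattractant gradient direction;
#'   default +x (source on the right).
#' @export
track_set <- function(tracks, dt_s, gradient_axis = c(1, 0)) {
  stopifnot(is.list(tracks))
  ga <- gradient_axis / sqrt(sum(gradient_axis^2))
  structure(list(tracks = tracks, dt_s = dt_s, gradient_axis = ga),
            class = "track_set")
}

#' @export
length.track_set <- function(x) length(x$tracks)

#' @export
print.track_set <- function(x, ...) {
  ns <- vapply(x$tracks, nrow, integer(1L))
  cat(sprintf("<track_set> %d tracks, dt = %g s, %d-%d samples each\n",
              length(x$tracks), x$dt_s,
              if (length(ns)) min(ns) else 0L, if (length(ns)) max(ns) else 0L))
  invisible(x)
}

#' Track linking parameters
#'
#' Defaults follow the simple linear-assignment tracking settings used for
#' chemotaxing cells: 25 um frame-to-frame linking radius, 10 um gap-closing
#' radius over at most 5 skipped frames.
#'
#' @param link_max_um maximum frame-to-frame link distance, um.
#' @param gap_max_um maximum gap-closing distance, um.
#' @param gap_max_frames maximum frames a gap may span (>= 1).
#' @param min_track_frames tracks with fewer samples are discarded.
#' @export
link_params <- function(link_max_um = 25.0, gap_max_um = 10.0,
                        gap_max_frames = 5L, min_track_frames = 2L) {
  stopifnot(link_max_um > 0, gap_max_um > 0, gap_max_frames >= 1,
            min_track_frames >= 1)
  structure(list(link_max_um = link_max_um, gap_max_um = gap_max_um,
                 gap_max_frames = as.integer(gap_max_frames),
                 min_track_frames = as.integer(min_track_frames)),
            class = "link_params")
}

# greedy one-to-one assignment by ascending distance; returns two-column
# matrix of (i, j) index pairs with d(i, j) <= dmax
greedy_assign <- function(pa, pb, dmax) {
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(cbind(integer(0), integer(0)))
  d <- sqrt(outer(pa[, 1L], pb[, 1L], `-`)^2 +
              outer(pa[, 2L], pb[, 2L], `-`)^2)
  ord <- order(d)
  used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
  out <- matrix(integer(0), 0L, 2L)
  for (k in ord) {
    if (d[k] > dmax) break
    i <- (k - 1L) %% nrow(pa) + 1L
    j <- (k - 1L) %/% nrow(pa) + 1L
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      out <- rbind(out, c(i, j))
    }
  }
  out
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment (ascending distance,
#' each detection used at most once, links beyond `link_max_um` forbidden),
#' followed by a gap-closing pass that re-joins track ends to later track
#' starts within `gap_max_frames` and `gap_max_um`, again greedily by
#' distance. Tracks shorter than `min_track_frames` are dropped.
#'
#' @param detections list, one element per frame (0-based frame = position -
#'   1), each a matrix/data.frame with columns `x_um`, `y_um` (empty frames
#'   allowed).
#' @param params a [link_params()].
#' @param dt_s frame interval, s.
#' @return a [track_set()].
#' @export
link_tracks <- function(detections, params = link_params(), dt_s = 1) {
  stopifnot(is.list(detections), inherits(params, "link_params"))
  as_mat <- function(d) {
    if (is.null(d) || NROW(d) == 0L) return(matrix(numeric(0), 0L, 2L))
    m <- as.matrix(as.data.frame(d)[, c("x_um", "y_um")])
    unname(m)
  }
  pts <- lapply(detections, as_mat)
  nf <- length(pts)
  # active track: list(frames, xy matrix); frame-to-frame pass
  open <- list(); closed <- list()
  for (f in seq_len(nf)) {
    p <- pts[[f]]
    ends <- if (length(open)) {
      do.call(rbind, lapply(open, function(tr) tr$xy[nrow(tr$xy), ]))
    } else matrix(numeric(0), 0L, 2L)
    asg <- greedy_assign(ends, p, params$link_max_um)
    taken_det <- logical(nrow(p)); extended <- logical(length(open))
    if (nrow(asg)) {
      for (k in seq_len(nrow(asg))) {
        i <- asg[k, 1L]; j <- asg[k, 2L]
        open[[i]]$frames <- c(open[[i]]$frames, f - 1L)
        open[[i]]$xy <- rbind(open[[i]]$xy, p[j, ])
        extended[i] <- TRUE; taken_det[j] <- TRUE
      }
    }
    closed <- c(closed, open[!extended])
    open <- open[extended]
    for (j in which(!taken_det)) {
      open[[length(open) + 1L]] <- list(frames = f - 1L,
                                        xy = p[j, , drop = FALSE])
    }
  }
  segs <- c(closed, open)
  # gap closing: join segment ends to later segment starts
  repeat {
    n <- length(segs)
    if (n < 2L) break
    cand <- NULL
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      fe <- segs[[i]]$frames[length(segs[[i]]$frames)]
      fs <- segs[[j]]$frames[1L]
      gap <- fs - fe
      if (gap < 2L || gap > params$gap_max_frames + 1L) next
      d <- sqrt(sum((segs[[i]]$xy[nrow(segs[[i]]$xy), ] -
                       segs[[j]]$xy[1L, ])^2))
      if (d <= params$gap_max_um) cand <- rbind(cand, c(i, j, d))
    }
    if (is.null(cand)) break
    best <- cand[which.min(cand[, 3L]), ]
    i <- best[1L]; j <- best[2L]
    segs[[i]]$frames <- c(segs[[i]]$frames, segs[[j]]$frames)
    segs[[i]]$xy <- rbind(segs[[i]]$xy, segs[[j]]$xy)
    segs[[j]] <- NULL
  }
  segs <- Filter(function(s) length(s$frames) >= params$min_track_frames,
                 segs)
  tracks <- lapply(seq_along(segs), function(id) {
    s <- segs[[id]]
    track(track_id = id, frame = s$frames, x_um = s$xy[, 1L],
          y_um = s$xy[, 2L], dt_s = dt_s)
  })
  track_set(tracks, dt_s = dt_s)
}

#' Mean track speed in um/min
#'
#' The speed of each consecutive sample pair (Euclidean displacement over its
#' time interval) is averaged over the track; gapped intervals contribute one
#' displacement over the full gapped time.
#'
#' @param tr a [track()].
#' @export
track_speed <- function(tr) {
  stopifnot(inherits(tr, "track"))
  if (nrow(tr) < 2L) stop("track needs at least 2 samples")
  disp <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  dts <- diff(tr$t_s)
  mean(disp / dts) * 60
}

#' Time-averaged mean square displacement
#'
#' Per track, the MSD at lag `tau = n * dt` is the average of
#' `|r(t + tau) - r(t)|^2` over all overlapping interval pairs; the curve is
#' the unweighted mean of per-track MSDs at each lag, computed up to
#' `max_lag_fraction` of each track's duration.
#'
#' @param tracks a [track_set()] (tracks must have uniform sampling).
#' @param max_lag_fraction largest lag as a fraction of track duration;
#'   default 0.5 to bound estimator variance at long lags.
#' @return data.frame with `lag_s`, `msd_um2`, `n` (tracks contributing).
#' @export
msd <- function(tracks, max_lag_fraction = 0.5) {
  stopifnot(inherits(tracks, "track_set"))
  per_track <- lapply(tracks$tracks, function(tr) {
    n <- nrow(tr)
    if (n < 2L) return(NULL)
    max_lag <- max(1L, floor(max_lag_fraction * (n - 1L)))
    vapply(seq_len(max_lag), function(lag) {
      dx <- tr$x_um[(1L + lag):n] - tr$x_um[1L:(n - lag)]
      dy <- tr$y_um[(1L + lag):n] - tr$y_um[1L:(n - lag)]
      mean(dx^2 + dy^2)
    }, numeric(1L))
  })
  per_track <- Filter(Negate(is.null), per_track)
  if (!length(per_track)) {
    return(data.frame(lag_s = numeric(0), msd_um2 = numeric(0),
                      n = integer(0)))
  }
  max_n <- max(vapply(per_track, length, integer(1L)))
  msd_um2 <- n_tr <- numeric(max_n)
  for (lag in seq_len(max_n)) {
    vals <- unlist(lapply(per_track, function(v) {
      if (length(v) >= lag) v[lag] else NULL
    }))
    msd_um2[lag] <- mean(vals)
    n_tr[lag] <- length(vals)
  }
  data.frame(lag_s = seq_len(max_n) * tracks$dt_s, msd_um2 = msd_um2,
             n = as.integer(n_tr))
}

#' Chemotaxis directionality gate
#'
#' A track counts as migrating toward the source when its net displacement
#' (last minus first position) has strictly positive projection on the
#' gradient axis; a dataset passes when the toward-fraction reaches the
#' threshold (default 0.8, the standard gate for a well-established
#' gradient).
#'
#' @param tracks a [track_set()] with `gradient_axis` set.
#' @param threshold passing fraction; default 0.8.
#' @return list with `fraction_toward`, `threshold`, `passed`, and
#'   `projection_um` (per-track net displacement along the axis).
#' @export
chemotaxis_gate <- function(tracks, threshold = 0.8) {
  stopifnot(inherits(tracks, "track_set"))
  if (!length(tracks$tracks)) stop("empty track set")
  ax <- tracks$gradient_axis
  proj <- vapply(tracks$tracks, function(tr) {
    if (nrow(tr) < 2L) stop("tracks need at least 2 samples")
    dx <- tr$x_um[nrow(tr)] - tr$x_um[1L]
    dy <- tr$y_um[nrow(tr)] - tr$y_um[1L]
    dx * ax[1L] + dy * ax[2L]
  }, numeric(1L))
  frac <- mean(proj > 0)
  list(fraction_toward = frac, threshold = threshold,
       passed = frac >= threshold, projection_um = proj)
}

#' Spider-plot coordinates
#'
#' Translates every track so its first sample sits at the origin (no
#' rotation); overlaying the results reads net directionality at a glance.
#'
#' @param tracks a [track_set()].
#' @return a [track_set()] of origin-shifted tracks.
#' @export
spider_coordinates <- function(tracks) {
  stopifnot(inherits(tracks, "track_set"))
  if (!length(tracks$tracks)) stop("empty track set")
  shifted <- lapply(tracks$tracks, function(tr) {
    out <- tr
    out$x_um <- tr$x_um - tr$x_um[1L]
    out$y_um <- tr$y_um - tr$y_um[1L]
    out
  })
  track_set(shifted, dt_s = tracks$dt_s, gradient_axis = tracks$gradient_axis)
}

#' Gradient line-scan profile
#'
#' Validates a chemoattractant gradient by averaging pixel intensity per
#' column (axis "x") or per row (axis "y") and fitting a least-squares line.
#'
#' @param image a [plane_image()] of the gradient channel.
#' @param axis "x" (default) or "y".
#' @return list with `position_px`, `profile` (mean intensity), `slope`
#'   (counts per pixel), `intercept`, `monotone_trend` (sign of the slope).
#' @export
gradient_profile <- function(image, axis = c("x", "y")) {
  stopifnot(inherits(image, "plane_image"))
  axis <- match.arg(axis)
  prof <- if (axis == "x") colMeans(image$pixels) else rowMeans(image$pixels)
  pos <- seq_along(prof)
  fit <- stats::lm.fit(cbind(1, pos), prof)
  list(position_px = pos, profile = as.numeric(prof),
       slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       monotone_trend = sign(unname(fit$coefficients[2L])))
}

#' Read / write tracks as CSV
#'
#' Columns: `track_id, frame, t_s, x_um, y_um`.
#'
#' @param tracks a [track_set()].
#' @param path CSV file.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  rows <- do.call(rbind, lapply(tracks$tracks, function(tr) {
    data.frame(track_id = attr(tr, "track_id"), frame = tr$frame,
               t_s = tr$t_s, x_um = tr$x_um, y_um = tr$y_um)
  }))
  if (is.null(rows)) {
    rows <- data.frame(track_id = integer(0), frame = integer(0),
                       t_s = numeric(0), x_um = numeric(0), y_um = numeric(0))
  }
  utils::write.csv(format_float_df(rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @param dt_s frame interval, s.
#' @param gradient_axis gradient direction for the returned set.
#' @export
read_tracks_csv <- function(path, dt_s = NULL, gradient_axis = c(1, 0)) {
  df <- utils::read.csv(path)
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("tracks CSV must have columns ", paste(need, collapse = ", "))
  }
  if (is.null(dt_s)) {
    if (!"t_s" %in% names(df)) stop("supply dt_s or a t_s column")
    steps <- unlist(tapply(df$t_s, df$track_id,
                           function(t) diff(sort(t)), simplify = FALSE))
    dt_s <- min(steps[steps > 0])
  }
  tracks <- lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), ]
    track(track_id = d$track_id[1L], frame = d$frame,
          x_um = d$x_um, y_um = d$y_um, dt_s = dt_s)
  })
  track_set(unname(tracks), dt_s = dt_s, gradient_axis = gradient_axis)
}
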