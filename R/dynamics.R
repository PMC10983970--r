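#' Adhesion-lifetime analysis parameters
#'
#' @param min_frames minimum track duration in frames (default 8; at the
#'   750 ms acquisition interval this is the 6-s minimum duration rule).
#' @param smooth_window running-average window in frames, odd (default 5).
#' @param exclude_endpoint_tracks drop punctae present in the first or last
#'   frame of the video (default TRUE): their assembly or disassembly was not
#'   observed in full.
#' @param frame_interval_s seconds per frame, default 0.75.
#' @param lifetime_mode "interval" (default): lifetime = span between the
#'   half-maximal assembly and disassembly times; "sum": assembly t-half plus
#'   the decay half-time.
#' @export
lifetime_params <- function(min_frames = 8L, smooth_window = 5L,
                            exclude_endpoint_tracks = TRUE,
                            frame_interval_s = 0.75,
                            lifetime_mode = c("interval", "sum")) {
  if (min_frames < 2) stop("min_frames must be >= 2")
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    stop("smooth_window must be odd and >= 1")
  }
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  structure(list(min_frames = as.integer(min_frames),
                 smooth_window = as.integer(smooth_window),
                 exclude_endpoint_tracks = isTRUE(exclude_endpoint_tracks),
                 frame_interval_s = frame_interval_s,
                 lifetime_mode = match.arg(lifetime_mode)),
            class = "lifetime_params")
}

#' Minimum track duration in seconds
#'
#' Duration convention: a track lasting `n` frames spans `n *
#' frame_interval_s` seconds (each frame owns one full interval), so the
#' default 8-frame minimum at 750 ms equals 6 s.
#'
#' @param params a [lifetime_params()].
#' @export
min_duration_s <- function(params = lifetime_params()) {
  params$min_frames * params$frame_interval_s
}

#' Per-adhesion intensity time series
#'
#' @param t_s sample times, strictly increasing.
#' @param value intensities.
#' @param id punctum/track identifier.
#' @param baseline_subtracted has the first-frame value been subtracted?
#' @export
intensity_trace <- function(t_s, value, id = NA,
                            baseline_subtracted = FALSE) {
  stopifnot(length(t_s) == length(value))
  if (any(diff(t_s) <= 0)) stop("times must be strictly increasing")
  if (baseline_subtracted && length(value) && abs(value[1L]) > 1e-9) {
    stop("baseline-subtracted trace must start at 0")
  }
  out <- data.frame(t_s = t_s, value = value)
  attr(out, "id") <- id
  attr(out, "baseline_subtracted") <- baseline_subtracted
  class(out) <- c("intensity_trace", "data.frame")
  out
}

# 3x3 min/max filters with replicate padding: a flat neighbourhood maps to
# itself, so the top-hat of a constant frame is exactly zero, including at
# borders.
filter3 <- function(m, fun) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- function(d) pmin(pmax(seq_len(nr) + d, 1L), nr)
  ci <- function(d) pmin(pmax(seq_len(nc) + d, 1L), nc)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- fun(out, m[ri(dr), ci(dc)])
  }
  out
}

#' Background suppression via a 3x3 regional-maxima (white top-hat) filter
#'
#' Each frame is replaced by `frame - opening(frame)` with a 3x3 square
#' structuring element. Smooth background (including linear illumination
#' ramps) is suppressed to ~0 while local maxima at the punctae scale are
#' retained; the output is non-negative everywhere and exactly zero where the
#' 3x3 neighbourhood is flat.
#'
#' @param stack an [image_stack()] (a single [plane_image()] is also
#'   accepted).
#' @return same type as the input, filtered.
#' @export
regional_maxima_3x3 <- function(stack) {
  tophat <- function(img) {
    op <- filter3(filter3(img$pixels, pmin), pmax)  # opening = dilate(erode)
    plane_image(img$pixels - op, img$pixel_size_um,
                if (img$bit_max > 255) 16L else 8L)
  }
  if (inherits(stack, "plane_image")) return(tophat(stack))
  stopifnot(inherits(stack, "image_stack"))
  image_stack(lapply(stack$frames, tophat),
              frame_interval_s = stack$frame_interval_s)
}

#' Extract per-punctum intensity traces from a stack
#'
#' Applies the duration and endpoint filters, then reads each surviving
#' punctum's mean intensity over its pixel set frame by frame and subtracts
#' the first-frame value (baseline) from every sample.
#'
#' Tracks touching frame 0 or the final frame are dropped (their assembly or
#' disassembly is censored); tracks shorter than `min_frames` are dropped;
#' tracks that skip frames or whose pixel sets ever overlap another track's
#' are dropped (the automated stand-in for manual curation of merged or
#' frame-skipping punctae).
#'
#' @param stack an [image_stack()].
#' @param punctae_tracks list of punctum tracks, each a list with `id`,
#'   `frames` (0-based, consecutive) and `pixels` (list of linear pixel index
#'   vectors, one per frame).
#' @param params a [lifetime_params()].
#' @return list of [intensity_trace()] objects (possibly empty).
#' @export
extract_traces <- function(stack, punctae_tracks,
                           params = lifetime_params()) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- length(stack$frames)
  keep <- vapply(punctae_tracks, function(tr) {
    fr <- tr$frames
    if (params$exclude_endpoint_tracks &&
        (0L %in% fr || (nf - 1L) %in% fr)) return(FALSE)
    if (length(fr) < params$min_frames) return(FALSE)
    if (any(diff(fr) != 1L)) return(FALSE)  # frame-skipping
    TRUE
  }, logical(1L))
  kept <- punctae_tracks[keep]
  # overlap rejection: two kept tracks sharing any pixel in any common frame
  if (length(kept) > 1L) {
    bad <- logical(length(kept))
    for (i in seq_along(kept)) for (j in seq_along(kept)) {
      if (i >= j) next
      common <- intersect(kept[[i]]$frames, kept[[j]]$frames)
      for (f in common) {
        pi <- kept[[i]]$pixels[[match(f, kept[[i]]$frames)]]
        pj <- kept[[j]]$pixels[[match(f, kept[[j]]$frames)]]
        if (length(intersect(pi, pj))) { bad[i] <- bad[j] <- TRUE; break }
      }
    }
    kept <- kept[!bad]
  }
  lapply(kept, function(tr) {
    vals <- vapply(seq_along(tr$frames), function(k) {
      mean(stack$frames[[tr$frames[k] + 1L]]$pixels[tr$pixels[[k]]])
    }, numeric(1L))
    vals <- vals - vals[1L]
    intensity_trace(t_s = tr$frames * stack$frame_interval_s, value = vals,
                    id = tr$id, baseline_subtracted = TRUE)
  })
}

#' Running-average smoothing of a trace
#'
#' Centred moving mean; at the boundaries the window truncates to the
#' available samples. Length is unchanged and the output never leaves the
#' range of the input values inside each window.
#'
#' @param trace an [intensity_trace()].
#' @param window odd window size in frames; default 5.
#' @export
smooth_trace <- function(trace, window = 5L) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (window %% 2 == 0 || window < 1) stop("window must be odd and >= 1")
  half <- (window - 1L) %/% 2L
  n <- nrow(trace)
  sm <- vapply(seq_len(n), function(i) {
    mean(trace$value[max(1L, i - half):min(n, i + half)])
  }, numeric(1L))
  out <- trace
  out$value <- sm
  if (isTRUE(attr(out, "baseline_subtracted")) && abs(sm[1L]) > 1e-9) {
    attr(out, "baseline_subtracted") <- FALSE  # boundary mean can shift t=0
  }
  out
}

# deterministic start values for the logistic fit from empirical crossings
logistic_start <- function(t, v) {
  A <- max(v)
  half_i <- which(v >= A / 2)[1L]
  t10 <- t[which(v >= 0.1 * A)[1L]]
  t90 <- t[which(v >= 0.9 * A)[1L]]
  r0 <- if (is.finite(t90 - t10) && t90 > t10) 4 / (t90 - t10) else 1
  list(A = A, r = r0, t0 = t[half_i])
}

#' Fit adhesion assembly/disassembly kinetics and derive the lifetime
#'
#' The trace is split at its maximum (`t_peak`): samples up to and including
#' the peak are fitted with the logistic `A / (1 + exp(-r (t - t0)))`
#' (assembly) and samples from the peak on with the exponential decay
#' `A_dis exp(-k (t - t_peak))` (disassembly), both by bounded least squares.
#' The assembly t-half is the logistic midpoint `t0`; the disassembly t-half
#' is `t_peak + ln(2) / k`; the lifetime is the interval between them (or
#' their sum of half-times under `lifetime_mode = "sum"`).
#'
#' The peak sample always closes the assembly branch; the decay fit starts
#' half a smoothing window past the peak (falling back to the peak itself for
#' short tails), because the argmax sample usually still lies on the rising
#' branch and running-average windows straddling the peak mix both branches,
#' biasing the decay rate. When both branches converge, the peak
#' time is refined to the intersection of the two fitted curves (the discrete
#' argmax is only accurate to one frame interval). A monotone trace (argmax
#' at the first or last sample) leaves the missing branch flagged unconverged
#' and the lifetime undefined.
#'
#' @param trace a smoothed, baseline-subtracted [intensity_trace()] with at
#'   least `min_frames` samples.
#' @param params a [lifetime_params()].
#' @return Object of class `lifetime_fit`; see [coef.lifetime_fit()],
#'   [predict.lifetime_fit()], [plot.lifetime_fit()].
#' @export
fit_lifetime <- function(trace, params = lifetime_params()) {
  stopifnot(inherits(trace, "intensity_trace"))
  t <- trace$t_s; v <- trace$value
  if (length(v) < params$min_frames) {
    stop("trace shorter than min_frames (", params$min_frames, ")")
  }
  peak_i <- which.max(v)
  t_peak <- t[peak_i]
  conv_asm <- conv_dis <- FALSE
  A_asm <- r <- t0 <- A_dis <- k_dis <- sse_asm <- sse_dis <- NA_real_
  fit_asm <- fit_dis <- NULL
  if (peak_i > 1L) {
    ta <- t[1:peak_i]; va <- v[1:peak_i]
    if (length(ta) >= 3L && max(va) > 0) {
      st <- logistic_start(ta, va)
      fit_asm <- tryCatch(
        minpack.lm::nlsLM(
          va ~ A / (1 + exp(-r * (ta - t0))),
          start = list(A = st$A, r = st$r, t0 = st$t0),
          lower = c(A = 1e-12, r = 1e-9, t0 = -Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit_asm)) {
        cf <- stats::coef(fit_asm)
        if (all(is.finite(cf)) && cf[["r"]] > 0) {
          A_asm <- cf[["A"]]; r <- cf[["r"]]; t0 <- cf[["t0"]]
          sse_asm <- sum(stats::resid(fit_asm)^2)
          conv_asm <- TRUE
        }
      }
    }
  }
  if (peak_i < length(v)) {
    # the peak sample itself usually still lies on the assembly branch
    # (the true peak rarely falls on the sampling grid), and samples whose
    # running-average window straddles the peak mix both branches; both are
    # excluded from the decay fit whenever the tail has enough samples
    margin <- (params$smooth_window - 1L) %/% 2L
    n <- length(v)
    d_start <- if (n - (peak_i + margin) >= 3L) peak_i + 1L + margin
    else if (n - peak_i >= 3L) peak_i + 1L
    else peak_i
    td <- t[d_start:length(t)]; vd <- v[d_start:length(v)]
    if (length(td) >= 2L && vd[1L] > 0) {
      pos <- vd > 0
      k0 <- if (sum(pos) >= 2L) {
        sl <- stats::lm.fit(cbind(1, td[pos]), log(vd[pos]))$coefficients[2L]
        max(-sl, 1e-6)
      } else 0.1
      fit_dis <- tryCatch(
        minpack.lm::nlsLM(
          vd ~ Ad * exp(-k * (td - t_peak)),
          start = list(Ad = vd[1L], k = k0),
          lower = c(Ad = 1e-12, k = 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit_dis)) {
        cf <- stats::coef(fit_dis)
        if (all(is.finite(cf)) && cf[["k"]] > 0) {
          A_dis <- cf[["Ad"]]; k_dis <- cf[["k"]]
          sse_dis <- sum(stats::resid(fit_dis)^2)
          conv_dis <- TRUE
        }
      }
    }
  }
  if (conv_asm && conv_dis) {
    # refine the peak time to the intersection of the two fitted branches:
    # the discrete argmax is only accurate to one frame interval
    dt <- stats::median(diff(t))
    h <- function(tt) {
      A_asm / (1 + exp(-r * (tt - t0))) -
        A_dis * exp(-k_dis * (tt - t[peak_i]))
    }
    lo <- t[peak_i] - 2 * dt; hi <- t[peak_i] + 2 * dt
    if (is.finite(h(lo)) && is.finite(h(hi)) && h(lo) * h(hi) < 0) {
      t_ref <- stats::uniroot(h, c(lo, hi), tol = 1e-10)$root
      A_dis <- A_dis * exp(-k_dis * (t_ref - t[peak_i]))
      t_peak <- t_ref
    }
  }
  t_half_asm <- if (conv_asm) t0 else NA_real_
  t_half_dis <- if (conv_dis) t_peak + log(2) / k_dis else NA_real_
  lifetime <- NA_real_
  if (conv_asm && conv_dis) {
    lifetime <- switch(params$lifetime_mode,
      interval = t_half_dis - t_half_asm,
      sum = t_half_asm + log(2) / k_dis)
    if (params$lifetime_mode == "interval" && lifetime < 0) {
      lifetime <- NA_real_  # half-max ordering violated; fit unusable
    }
  }
  structure(list(
    A_asm = A_asm, r = r, t0_s = t0,
    A_dis = A_dis, k_dis = k_dis, t_peak_s = t_peak,
    t_half_asm_s = t_half_asm, t_half_dis_s = t_half_dis,
    lifetime_s = lifetime, sse_asm = sse_asm, sse_dis = sse_dis,
    converged = c(assembly = conv_asm, disassembly = conv_dis),
    lifetime_mode = params$lifetime_mode, trace = trace
  ), class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat("<lifetime_fit>\n")
  cat(sprintf("  assembly:    %s  (A = %.4g, r = %.4g /s, t0 = %.4g s)\n",
              if (x$converged[["assembly"]]) "converged" else "NOT converged",
              x$A_asm, x$r, x$t0_s))
  cat(sprintf("  disassembly: %s  (A = %.4g, k = %.4g /s, t_peak = %.4g s)\n",
              if (x$converged[["disassembly"]]) "converged"
              else "NOT converged",
              x$A_dis, x$k_dis, x$t_peak_s))
  cat(sprintf("  t-half assembly %.4g s, t-half disassembly %.4g s\n",
              x$t_half_asm_s, x$t_half_dis_s))
  cat(sprintf("  lifetime (%s) = %.4g s\n", x$lifetime_mode, x$lifetime_s))
  invisible(x)
}

#' @export
summary.lifetime_fit <- function(object, ...) {
  out <- list(
    coefficients = coef(object),
    sse = c(assembly = object$sse_asm, disassembly = object$sse_dis),
    converged = object$converged,
    n = nrow(object$trace),
    lifetime_s = object$lifetime_s,
    lifetime_mode = object$lifetime_mode
  )
  class(out) <- "summary.lifetime_fit"
  out
}

#' @export
print.summary.lifetime_fit <- function(x, ...) {
  cat(sprintf("Adhesion lifetime fit over %d samples\n", x$n))
  print(round(x$coefficients, 6))
  cat(sprintf("SSE: assembly %.4g, disassembly %.4g\n",
              x$sse[1L], x$sse[2L]))
  cat(sprintf("lifetime (%s): %.4g s\n", x$lifetime_mode, x$lifetime_s))
  invisible(x)
}

#' Coefficients of a lifetime fit
#'
#' @param object a `lifetime_fit`.
#' @param ... unused.
#' @return named vector: `A_asm`, `r`, `t0_s`, `A_dis`, `k_dis`, `t_peak_s`,
#'   `t_half_asm_s`, `t_half_dis_s`, `lifetime_s`.
#' @export
coef.lifetime_fit <- function(object, ...) {
  c(A_asm = object$A_asm, r = object$r, t0_s = object$t0_s,
    A_dis = object$A_dis, k_dis = object$k_dis,
    t_peak_s = object$t_peak_s, t_half_asm_s = object$t_half_asm_s,
    t_half_dis_s = object$t_half_dis_s, lifetime_s = object$lifetime_s)
}

#' Predicted intensity from a lifetime fit
#'
#' @param object a `lifetime_fit`.
#' @param t_s times at which to evaluate; defaults to the fitted trace times.
#' @param ... unused.
#' @export
predict.lifetime_fit <- function(object, t_s = NULL, ...) {
  if (is.null(t_s)) t_s <- object$trace$t_s
  out <- rep(NA_real_, length(t_s))
  asm <- t_s <= object$t_peak_s
  if (object$converged[["assembly"]]) {
    out[asm] <- object$A_asm /
      (1 + exp(-object$r * (t_s[asm] - object$t0_s)))
  }
  if (object$converged[["disassembly"]]) {
    out[!asm] <- object$A_dis *
      exp(-object$k_dis * (t_s[!asm] - object$t_peak_s))
  }
  out
}

#' @export
fitted.lifetime_fit <- function(object, ...) predict(object)

#' @export
residuals.lifetime_fit <- function(object, ...) {
  object$trace$value - fitted(object)
}

#' Plot a lifetime fit
#'
#' Trace samples with the fitted assembly and disassembly curves and the two
#' half-maximal time points.
#'
#' @param x a `lifetime_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lifetime_fit <- function(x, ...) {
  graphics::plot(x$trace$t_s, x$trace$value, pch = 16, cex = 0.6,
                 xlab = "time (s)", ylab = "intensity (baseline-subtracted)",
                 ...)
  tt <- seq(min(x$trace$t_s), max(x$trace$t_s), length.out = 300)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  graphics::abline(v = c(x$t_half_asm_s, x$t_half_dis_s), lty = 3,
                   col = "grey40")
  invisible(x)
}

#' Track punctae through a stack and assemble per-frame pixel sets
#'
#' Convenience wrapper for the lifetime pipeline: detects punctae on each
#' (optionally top-hat filtered) frame, links their centroids across frames
#' with [link_tracks()], and attaches each punctum's pixel set per frame so
#' [extract_traces()] can read intensities.
#'
#' @param stack an [image_stack()].
#' @param mask cell mask shared by all frames (NULL: whole frame).
#' @param det_params a [detection_params()].
#' @param lnk_params a [link_params()]; defaults to a tight 1-um linking
#'   radius with no gap closing, appropriate for near-stationary adhesions.
#' @return list of punctum tracks in the format [extract_traces()] expects.
#' @export
track_punctae <- function(stack, mask = NULL,
                          det_params = detection_params(),
                          lnk_params = link_params(link_max_um = 1,
                                                   gap_max_um = 0.001,
                                                   gap_max_frames = 1L)) {
  stopifnot(inherits(stack, "image_stack"))
  px <- stack$frames[[1L]]$pixel_size_um
  dets <- lapply(stack$frames, function(fr) {
    m <- if (is.null(mask)) matrix(TRUE, nrow(fr$pixels), ncol(fr$pixels))
    else mask
    detect_punctae(fr, m, det_params)
  })
  cent <- lapply(dets, function(ps) {
    data.frame(x_um = ps$punctae$centroid_col * px,
               y_um = ps$punctae$centroid_row * px)
  })
  ts <- link_tracks(cent, lnk_params, dt_s = stack$frame_interval_s)
  lapply(ts$tracks, function(tr) {
    pixels <- lapply(seq_len(nrow(tr)), function(k) {
      f <- tr$frame[k] + 1L
      ps <- dets[[f]]
      # recover which punctum this sample came from by centroid match
      d <- (ps$punctae$centroid_col * px - tr$x_um[k])^2 +
        (ps$punctae$centroid_row * px - tr$y_um[k])^2
      id <- ps$punctae$id[which.min(d)]
      which(ps$label == id)
    })
    list(id = attr(tr, "track_id"), frames = tr$frame, pixels = pixels)
  })
}
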