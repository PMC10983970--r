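#' Specification for a synthetic single-cell punctae image
#'
#' Describes a fluorescence image of one cell: an elliptical cell body at a
#' cytoplasmic intensity level over a darker extracellular field, containing
#' diffraction-limited punctae rendered as 2-D Gaussian spots, plus camera
#' noise. Defaults emulate adhesion imaging at 0.1 um/px where punctae occupy
#' roughly 0.02-0.5 um^2 after thresholding.
#'
#' Spots are rendered by evaluating the Gaussian at pixel centres (no
#' supersampling): detection operates on thresholded blobs, so sub-pixel
#' rendering fidelity is not needed.
#'
#' @param shape_px integer (rows, cols) image shape.
#' @param pixel_size_um micrometres per pixel edge.
#' @param cell_ellipse list with `center` (row, col, px), `semi_axes`
#'   (a, b, px) and `rotation` (radians).
#' @param n_punctae number of spots to place inside the cell (>= 0).
#' @param spot_sigma_px Gaussian sigma of each spot in pixels.
#' @param spot_amplitude peak intensity above the cytoplasmic level (> 0).
#' @param background_mean cytoplasmic (in-cell) mean intensity in counts.
#' @param background_sd Gaussian noise SD in counts (>= 0).
#' @param outside_mean extracellular mean intensity; default 0.
#' @param noise_model "gaussian" (additive, default) or "poisson" (applied to
#'   the expected photon count).
#' @param min_separation_px minimum pairwise distance between spot centres;
#'   must exceed `2 * spot_sigma_px` so spots stay resolvable.
#' @param bit_depth 8 or 16.
#' @param seed integer RNG seed; all randomness is local to this seed.
#' @return Object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(shape_px = c(200L, 200L),
                                 pixel_size_um = 0.1,
                                 cell_ellipse = list(
                                   center = c(100, 100),
                                   semi_axes = c(70, 50),
                                   rotation = 0),
                                 n_punctae = 5L,
                                 spot_sigma_px = 1.5,
                                 spot_amplitude = 2000,
                                 background_mean = 300,
                                 background_sd = 30,
                                 outside_mean = 0,
                                 noise_model = c("gaussian", "poisson"),
                                 min_separation_px = 8,
                                 bit_depth = 16L,
                                 seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(shape_px) == 2L, all(shape_px >= 8))
  if (n_punctae < 0) stop("n_punctae must be >= 0")
  if (spot_amplitude <= 0) stop("spot_amplitude must be > 0")
  if (background_sd < 0) stop("background_sd must be >= 0")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (spot_sigma_px <= 0) stop("spot_sigma_px must be > 0")
  if (min_separation_px <= 2 * spot_sigma_px) {
    stop("min_separation_px must exceed 2 * spot_sigma_px")
  }
  stopifnot(length(cell_ellipse$center) == 2L,
            length(cell_ellipse$semi_axes) == 2L,
            all(cell_ellipse$semi_axes > 0))
  if (is.null(cell_ellipse$rotation)) cell_ellipse$rotation <- 0
  structure(list(
    shape_px = as.integer(shape_px), pixel_size_um = pixel_size_um,
    cell_ellipse = cell_ellipse, n_punctae = as.integer(n_punctae),
    spot_sigma_px = spot_sigma_px, spot_amplitude = spot_amplitude,
    background_mean = background_mean, background_sd = background_sd,
    outside_mean = outside_mean, noise_model = noise_model,
    min_separation_px = min_separation_px, bit_depth = as.integer(bit_depth),
    seed = as.integer(seed)
  ), class = "synthetic_image_spec")
}

# signed ellipse membership: <= 1 means inside (scale shrinks the ellipse)
ellipse_dist2 <- function(row, col, ell, scale = 1) {
  dr <- row - ell$center[1L]; dc <- col - ell$center[2L]
  th <- ell$rotation
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  (u / (scale * ell$semi_axes[1L]))^2 + (v / (scale * ell$semi_axes[2L]))^2
}

ellipse_mask <- function(shape, ell) {
  rows <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  cols <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  ellipse_dist2(rows, cols, ell) <= 1
}

# rejection-sample spot centres inside a shrunken ellipse, all pairwise
# separated by > min_sep; bounded retries so impossible packings fail loudly
place_centers <- function(n, ell, min_sep, margin_px, max_tries = 2000L) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  a <- ell$semi_axes[1L]; b <- ell$semi_axes[2L]
  shrink <- max(min(1 - margin_px / a, 1 - margin_px / b), 0.05)
  pts <- matrix(NA_real_, n, 2L)
  placed <- 0L
  for (try in seq_len(max_tries * n)) {
    r <- sqrt(stats::runif(1L)); phi <- stats::runif(1L, 0, 2 * pi)
    u <- r * cos(phi) * a * shrink; v <- r * sin(phi) * b * shrink
    th <- ell$rotation
    cand <- c(ell$center[1L] + u * cos(th) - v * sin(th),
              ell$center[2L] + u * sin(th) + v * cos(th))
    ok <- placed == 0L ||
      all(sqrt(rowSums(sweep(pts[seq_len(placed), , drop = FALSE], 2L,
                             cand)^2)) > min_sep)
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
      if (placed == n) return(pts)
    }
  }
  stop("could not place ", n, " spots at min separation ", min_sep,
       " px inside the cell ellipse")
}

render_spots <- function(shape, centers, sigma, amplitude) {
  img <- matrix(0, shape[1L], shape[2L])
  if (nrow(centers) == 0L) return(img)
  half <- ceiling(5 * sigma)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1L]; c0 <- centers[i, 2L]
    rr <- max(1L, floor(r0 - half)):min(shape[1L], ceiling(r0 + half))
    cc <- max(1L, floor(c0 - half)):min(shape[2L], ceiling(c0 + half))
    d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
    img[rr, cc] <- img[rr, cc] + amplitude * exp(-d2 / (2 * sigma^2))
  }
  img
}

apply_noise_quantize <- function(expectation, spec) {
  img <- switch(spec$noise_model,
    gaussian = expectation + if (spec$background_sd > 0) {
      stats::rnorm(length(expectation), 0, spec$background_sd)
    } else 0,
    poisson = stats::rpois(length(expectation), pmax(expectation, 0))
  )
  img <- matrix(img, nrow(expectation), ncol(expectation))
  bit_max <- 2^spec$bit_depth - 1
  img <- round(pmin(pmax(img, 0), bit_max))
  img
}

#' Generate a ground-truthed synthetic punctae image
#'
#' Builds `background + spots + noise`, clipped to the dtype range, plus the
#' true cell mask and a ground-truth table of every spot. Identical
#' spec + seed gives bit-identical output.
#'
#' @param spec a [synthetic_image_spec()].
#' @return list with `image` (`plane_image`), `mask` (logical matrix, the true
#'   elliptical cell footprint) and `truth` (data.frame: `row_px`, `col_px`
#'   continuous 1-based pixel coordinates, `sigma_px`, `amplitude`).
#' @export
gen_punctae_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  with_seed(spec$seed, {
    mask <- ellipse_mask(spec$shape_px, spec$cell_ellipse)
    centers <- place_centers(spec$n_punctae, spec$cell_ellipse,
                             spec$min_separation_px,
                             margin_px = 3 * spec$spot_sigma_px)
    expectation <- matrix(spec$outside_mean, spec$shape_px[1L],
                          spec$shape_px[2L])
    expectation[mask] <- spec$background_mean
    expectation <- expectation +
      render_spots(spec$shape_px, centers, spec$spot_sigma_px,
                   spec$spot_amplitude)
    img <- apply_noise_quantize(expectation, spec)
    truth <- data.frame(
      row_px = centers[, 1L], col_px = centers[, 2L],
      sigma_px = rep(spec$spot_sigma_px, nrow(centers)),
      amplitude = rep(spec$spot_amplitude, nrow(centers))
    )
    list(image = plane_image(img, spec$pixel_size_um, spec$bit_depth),
         mask = mask, truth = truth)
  })
}

#' Generate a two-channel image pair with controlled colocalization
#'
#' Shared spots are rendered at identical centres in both channels;
#' channel-exclusive spots are separated from every other spot by more than
#' `min_separation_px`. Noise is drawn independently per channel.
#'
#' @param spec a [synthetic_image_spec()]; `n_punctae` is ignored.
#' @param n_shared spots present in both channels.
#' @param n_a_only,n_b_only spots present in only one channel.
#' @return list with `image_a`, `image_b`, `mask`, and `truth` (data.frame
#'   with `row_px`, `col_px`, `label` in shared/a_only/b_only).
#' @export
gen_two_channel <- function(spec, n_shared, n_a_only, n_b_only) {
  stopifnot(inherits(spec, "synthetic_image_spec"),
            n_shared >= 0, n_a_only >= 0, n_b_only >= 0)
  with_seed(spec$seed, {
    mask <- ellipse_mask(spec$shape_px, spec$cell_ellipse)
    n_tot <- n_shared + n_a_only + n_b_only
    centers <- place_centers(n_tot, spec$cell_ellipse,
                             spec$min_separation_px,
                             margin_px = 3 * spec$spot_sigma_px)
    label <- rep(c("shared", "a_only", "b_only"),
                 times = c(n_shared, n_a_only, n_b_only))
    base <- matrix(spec$outside_mean, spec$shape_px[1L], spec$shape_px[2L])
    base[mask] <- spec$background_mean
    render_ch <- function(keep) {
      exp_ch <- base + render_spots(
        spec$shape_px, centers[keep, , drop = FALSE],
        spec$spot_sigma_px, spec$spot_amplitude)
      plane_image(apply_noise_quantize(exp_ch, spec),
                  spec$pixel_size_um, spec$bit_depth)
    }
    img_a <- render_ch(label %in% c("shared", "a_only"))
    img_b <- render_ch(label %in% c("shared", "b_only"))
    truth <- data.frame(row_px = centers[, 1L], col_px = centers[, 2L],
                        label = label, stringsAsFactors = FALSE)
    list(image_a = img_a, image_b = img_b, mask = mask, truth = truth)
  })
}

#' Parameters of a persistent-random-walk track ensemble
#'
#' The heading evolves as an Ornstein-Uhlenbeck-style angular diffusion with
#' rotational diffusivity `1 / persistence_time_s`; chemotactic bias replaces
#' a fraction `bias_strength` of each step with drift along +x. Step length is
#' fixed at `mean_speed_um_min * dt_s / 60` so the generated per-step speed
#' equals the nominal speed exactly in the unbiased case.
#'
#' @param mean_speed_um_min nominal cell speed, um/min (>= 0). Default 6.
#' @param persistence_time_s directional persistence time, s; `Inf` keeps the
#'   initial heading forever.
#' @param bias_strength 0 (pure persistent random walk) to 1 (straight +x).
#' @param dt_s frame interval, s (5 for random migration, 15 for chemotaxis).
#' @param n_frames samples per track (>= 2).
#' @param n_tracks number of tracks.
#' @param field_um tracks start uniformly in a square of this side, um.
#' @param seed RNG seed.
#' @export
prw_params <- function(mean_speed_um_min = 6, persistence_time_s = 60,
                       bias_strength = 0, dt_s = 5, n_frames = 61,
                       n_tracks = 30, field_um = 500, seed = 1L) {
  if (mean_speed_um_min < 0) stop("mean_speed_um_min must be >= 0")
  if (bias_strength < 0 || bias_strength > 1) {
    stop("bias_strength must lie in [0, 1]")
  }
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (persistence_time_s <= 0) stop("persistence_time_s must be > 0")
  if (dt_s <= 0) stop("dt_s must be > 0")
  structure(list(
    mean_speed_um_min = mean_speed_um_min,
    persistence_time_s = persistence_time_s,
    bias_strength = bias_strength, dt_s = dt_s,
    n_frames = as.integer(n_frames), n_tracks = as.integer(n_tracks),
    field_um = field_um, seed = as.integer(seed)
  ), class = "prw_params")
}

#' Generate persistent-random-walk (optionally biased) cell tracks
#'
#' @param p a [prw_params()].
#' @return a [track_set()] with `n_tracks` tracks of `n_frames` samples each,
#'   `dt_s` taken from `p`, gradient axis +x.
#' @export
gen_tracks <- function(p) {
  stopifnot(inherits(p, "prw_params"))
  with_seed(p$seed, {
    step_len <- p$mean_speed_um_min * p$dt_s / 60
    sd_theta <- if (is.finite(p$persistence_time_s)) {
      sqrt(2 * p$dt_s / p$persistence_time_s)
    } else 0
    tracks <- lapply(seq_len(p$n_tracks), function(id) {
      theta <- stats::runif(1L, 0, 2 * pi)
      pos <- matrix(NA_real_, p$n_frames, 2L)
      pos[1L, ] <- stats::runif(2L, 0, p$field_um)
      for (k in seq_len(p$n_frames - 1L)) {
        if (sd_theta > 0) theta <- theta + stats::rnorm(1L, 0, sd_theta)
        step <- (1 - p$bias_strength) * step_len * c(cos(theta), sin(theta)) +
          p$bias_strength * step_len * c(1, 0)
        pos[k + 1L, ] <- pos[k, ] + step
      }
      track(track_id = id, frame = seq_len(p$n_frames) - 1L,
            x_um = pos[, 1L], y_um = pos[, 2L], dt_s = p$dt_s)
    })
    track_set(tracks, dt_s = p$dt_s)
  })
}

#' Specification of a synthetic adhesion intensity trace
#'
#' Assembly follows a logistic rise `A / (1 + exp(-r (t - t0)))`; past
#' `t_peak_s` the trace switches to an exponential decay matched to the
#' logistic value at the peak, so the noiseless trace is continuous.
#'
#' @param A_asm assembly amplitude (plateau), arbitrary intensity units.
#' @param r logistic rate, 1/s (> 0).
#' @param t0_s logistic midpoint (assembly t-half), s.
#' @param k_dis decay rate, 1/s (> 0).
#' @param t_peak_s decay onset, s; must be >= `t0_s`.
#' @param noise_sd_frac i.i.d. Gaussian noise SD as a fraction of `A_asm`.
#' @param dt_s sampling interval, s; default 0.75.
#' @param n_frames trace length.
#' @param seed RNG seed.
#' @export
kinetic_trace_spec <- function(A_asm = 100, r = 0.5, t0_s = 10,
                               k_dis = log(2) / 5, t_peak_s = 20,
                               noise_sd_frac = 0, dt_s = 0.75,
                               n_frames = 60L, seed = 1L) {
  if (r <= 0) stop("r must be > 0")
  if (k_dis <= 0) stop("k_dis must be > 0")
  if (t_peak_s < t0_s) stop("t_peak_s must be >= t0_s")
  if (noise_sd_frac < 0) stop("noise_sd_frac must be >= 0")
  if (dt_s <= 0) stop("dt_s must be > 0")
  structure(list(A_asm = A_asm, r = r, t0_s = t0_s, k_dis = k_dis,
                 t_peak_s = t_peak_s, noise_sd_frac = noise_sd_frac,
                 dt_s = dt_s, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "kinetic_trace_spec")
}

# noiseless piecewise model shared by the generator and tests
kinetic_model_value <- function(t, spec) {
  logi <- spec$A_asm / (1 + exp(-spec$r * (t - spec$t0_s)))
  a_dis <- spec$A_asm / (1 + exp(-spec$r * (spec$t_peak_s - spec$t0_s)))
  ifelse(t <= spec$t_peak_s, logi,
         a_dis * exp(-spec$k_dis * (t - spec$t_peak_s)))
}

#' Generate a synthetic adhesion intensity trace
#'
#' @param spec a [kinetic_trace_spec()].
#' @return an [intensity_trace()] sampled at `dt_s` starting at t = 0; not
#'   baseline-subtracted.
#' @export
gen_intensity_trace <- function(spec) {
  stopifnot(inherits(spec, "kinetic_trace_spec"))
  with_seed(spec$seed, {
    t <- (seq_len(spec$n_frames) - 1L) * spec$dt_s
    v <- kinetic_model_value(t, spec)
    if (spec$noise_sd_frac > 0) {
      v <- v + stats::rnorm(length(v), 0, spec$noise_sd_frac * spec$A_asm)
    }
    intensity_trace(t_s = t, value = v, id = "synthetic",
                    baseline_subtracted = FALSE)
  })
}

#' Simulate a shear-flow detachment assay
#'
#' Starting from `n0` adherent cells, each flow step detaches every remaining
#' cell independently with that step's probability, so the count after each
#' step is a binomial survival draw from the previous count. Counts are
#' monotone non-increasing by construction.
#'
#' @param n0 initial (post-wash reference) cell count (> 0).
#' @param p_detach_per_step per-step detachment probabilities, each in
#'   `[0, 1]`; one per flow-rate interval.
#' @param flow_rates_ul_min flow rates labelling the steps; defaults to the
#'   500-1500 ul/min ladder in 250 ul/min increments when 5 steps are given,
#'   otherwise an ascending sequence from 500.
#' @param seed RNG seed.
#' @return a [detachment_series()].
#' @export
gen_detachment_counts <- function(n0, p_detach_per_step,
                                  flow_rates_ul_min = NULL, seed = 1L) {
  if (n0 <= 0) stop("n0 must be > 0")
  if (any(p_detach_per_step < 0 | p_detach_per_step > 1)) {
    stop("each detachment probability must lie in [0, 1]")
  }
  n_steps <- length(p_detach_per_step)
  if (is.null(flow_rates_ul_min)) {
    flow_rates_ul_min <- seq(500, by = 250, length.out = n_steps)
  }
  stopifnot(length(flow_rates_ul_min) == n_steps)
  with_seed(seed, {
    counts <- integer(n_steps + 1L)
    counts[1L] <- as.integer(n0)
    for (i in seq_len(n_steps)) {
      counts[i + 1L] <- stats::rbinom(1L, counts[i],
                                      1 - p_detach_per_step[i])
    }
    detachment_series(flow_rates_ul_min, counts)
  })
}
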