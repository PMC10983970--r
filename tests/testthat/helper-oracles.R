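# Independent brute-force oracles. These deliberately avoid the package's
# vectorised/labelled implementations: plain loops, queue flood fills and
# exhaustive enumeration, so agreement is a genuine two-route check.

# threshold classification + 8-connected flood fill; returns component pixel
# counts for candidates inside the mask
oracle_components <- function(pixels, mask, lower, upper) {
  cand <- mask & pixels >= lower & pixels <= upper
  nr <- nrow(cand); nc <- ncol(cand)
  seen <- matrix(FALSE, nr, nc)
  sizes <- integer(0)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!cand[r0, c0] || seen[r0, c0]) next
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0L
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1L] + dr; cc <- p[2L] + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        if (cand[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# punctae count oracle: in-mask MFI/SD threshold, flood fill, area filter
oracle_detect_count <- function(image, mask, k_sd = 3,
                                area_min = 0.02, area_max = 0.5) {
  v <- image$pixels[mask]
  lower <- mean(v) + k_sd * stats::sd(v)
  sizes <- oracle_components(image$pixels, mask, lower, image$bit_max)
  areas <- sizes * image$pixel_size_um^2
  sum(areas >= area_min - 1e-9 & areas <= area_max + 1e-9)
}

# colocalization oracle: pixel sets collected per punctum by looping over the
# label images, overlaps from explicit set intersections, then the
# descending-overlap / ascending-id one-to-one matching applied by hand
oracle_coloc <- function(a, b) {
  sets_of <- function(ps) {
    ids <- ps$punctae$id
    lapply(ids, function(i) which(ps$label == i))
  }
  sa <- sets_of(a); sb <- sets_of(b)
  cand <- NULL
  for (i in seq_along(sa)) for (j in seq_along(sb)) {
    ov <- length(intersect(sa[[i]], sb[[j]]))
    if (ov > 0L) cand <- rbind(cand, c(i, j, ov))
  }
  n_double <- 0L
  if (!is.null(cand)) {
    cand <- cand[order(-cand[, 3L], cand[, 1L], cand[, 2L]), , drop = FALSE]
    ua <- logical(length(sa)); ub <- logical(length(sb))
    for (k in seq_len(nrow(cand))) {
      if (!ua[cand[k, 1L]] && !ub[cand[k, 2L]]) {
        ua[cand[k, 1L]] <- TRUE; ub[cand[k, 2L]] <- TRUE
        n_double <- n_double + 1L
      }
    }
  }
  list(n_double = n_double,
       n_a_only = length(sa) - n_double,
       n_b_only = length(sb) - n_double)
}

# time-averaged MSD of one track at the given lags, all overlapping pairs
oracle_msd_track <- function(tr, lags) {
  vapply(lags, function(lag) {
    n <- nrow(tr)
    acc <- 0; cnt <- 0L
    for (i in seq_len(n - lag)) {
      acc <- acc + (tr$x_um[i + lag] - tr$x_um[i])^2 +
        (tr$y_um[i + lag] - tr$y_um[i])^2
      cnt <- cnt + 1L
    }
    acc / cnt
  }, numeric(1L))
}

# brute-force white top-hat: per-pixel 3x3 erosion then dilation with
# replicate padding
oracle_tophat3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  win <- function(src, r0, c0, fun) {
    vals <- c()
    for (dr in -1:1) for (dc in -1:1) {
      rr <- min(max(r0 + dr, 1L), nr); cc <- min(max(c0 + dc, 1L), nc)
      vals <- c(vals, src[rr, cc])
    }
    fun(vals)
  }
  er <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) er[r, c] <- win(m, r, c, min)
  op <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) op[r, c] <- win(er, r, c, max)
  m - op
}

# step-by-step ROUT recipe, written out longhand: robust centre by direct
# minimisation of the Lorentzian loss on a fine grid (refined by optimise),
# RSDR as the 68.27 percentile inflated by n/(n-1), then an explicit
# rank-by-rank FDR walk flagging everything beyond the deepest significant
# rank
oracle_rout_flags <- function(x, Q = 0.01, max_frac = 0.3) {
  n <- length(x)
  center <- stats::median(x)
  s <- as.numeric(stats::quantile(abs(x - center), 0.6827)) * n / (n - 1)
  if (s <= 0) return(rep(FALSE, n))
  for (iter in 1:50) {
    loss <- function(c0) sum(log(1 + ((x - c0) / s)^2))
    grid <- seq(min(x), max(x), length.out = 400)
    c_new <- grid[which.min(vapply(grid, loss, numeric(1)))]
    c_new <- stats::optimize(loss, c(c_new - diff(range(x)) / 100,
                                     c_new + diff(range(x)) / 100))$minimum
    s_new <- as.numeric(stats::quantile(abs(x - c_new), 0.6827)) * n / (n - 1)
    if (s_new <= 0) return(rep(FALSE, n))
    if (abs(c_new - center) < 1e-10 * (1 + abs(center))) {
      center <- c_new; s <- s_new; break
    }
    center <- c_new; s <- s_new
  }
  res <- abs(x - center)
  ord <- order(res, decreasing = TRUE)
  m <- min(floor(max_frac * n), n - 2L)
  deepest <- 0L
  for (i in seq_len(m)) {
    p <- 2 * stats::pt(-res[ord[i]] / s, df = n - 1)
    if (p < Q * (n - i + 1) / n) deepest <- i
  }
  flags <- rep(FALSE, n)
  if (deepest > 0L) flags[ord[seq_len(deepest)]] <- TRUE
  flags
}

# small helper: a synthetic spec whose spots sit comfortably above noise
bright_spec <- function(n = 5L, seed = 1L, sigma = 1.5, amp_x_sd = 50,
                        bg_sd = 30, sep = NULL) {
  synthetic_image_spec(
    n_punctae = n, spot_sigma_px = sigma, spot_amplitude = amp_x_sd * bg_sd,
    background_mean = 300, background_sd = bg_sd,
    min_separation_px = if (is.null(sep)) max(4 * sigma, 2 * sigma + 1) else sep,
    seed = seed)
}
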