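#' ROUT outlier-identification parameters
#'
#' @param Q maximum desired false-discovery rate among identified outliers;
#'   default 0.01 (the "Q = 1%" setting).
#' @param max_fraction_removed never flag more than this fraction of the
#'   sample (default 0.3).
#' @export
rout_params <- function(Q = 0.01, max_fraction_removed = 0.3) {
  if (!(Q > 0 && Q < 1)) stop("Q must lie in (0, 1)")
  if (!(max_fraction_removed > 0 && max_fraction_removed <= 1)) {
    stop("max_fraction_removed must lie in (0, 1]")
  }
  structure(list(Q = Q, max_fraction_removed = max_fraction_removed),
            class = "rout_params")
}

# Robust constant-model fit with Lorentzian (Cauchy) loss, initialized at the
# median, alternating location and scale updates. The scale estimate (RSDR)
# is the 68.27th percentile of |residuals| inflated by n / (n - K), K = 1
# parameter of the constant model.
robust_constant_fit <- function(x, n_iter = 50L, tol = 1e-10) {
  n <- length(x)
  center <- stats::median(x)
  rsdr_of <- function(c0) {
    as.numeric(stats::quantile(abs(x - c0), 0.6827, type = 7)) * n / (n - 1L)
  }
  s <- rsdr_of(center)
  if (s <= 0) return(list(center = center, rsdr = 0))
  for (it in seq_len(n_iter)) {
    obj <- function(c0) sum(log1p(((x - c0) / s)^2))
    new_center <- stats::optimize(obj, range(x))$minimum
    new_s <- rsdr_of(new_center)
    if (new_s <= 0) return(list(center = new_center, rsdr = 0))
    if (abs(new_center - center) < tol * (1 + abs(center)) &&
        abs(new_s - s) < tol * (1 + s)) {
      center <- new_center; s <- new_s
      break
    }
    center <- new_center; s <- new_s
  }
  list(center = center, rsdr = s)
}

#' Identify outliers with the ROUT procedure (constant model)
#'
#' Two-stage recipe: (1) a robust fit of the constant model -- a
#' Lorentzian-loss M-estimate of the centre initialized at the median, with
#' the robust standard deviation of the residuals (RSDR) taken as the 68.27th
#' percentile of absolute residuals scaled by `n / (n - 1)`; (2) residuals
#' ranked by magnitude are tested largest-first with t statistics
#' `|res| / RSDR` on `n - 1` degrees of freedom against the rank-dependent
#' threshold `alpha_i = Q (n - i + 1) / n`, and every value at least as
#' extreme as the deepest significant rank is flagged (step-up), so the flag
#' set is always a suffix of the residual-magnitude ordering. At most
#' `max_fraction_removed` of the sample is ever flagged.
#'
#' With fewer than 3 finite values, or a sample of identical values, nothing
#' is flagged.
#'
#' @param values numeric vector.
#' @param params a [rout_params()].
#' @return Object of class `rout_result`: `kept`, `flagged` (values),
#'   `is_outlier` (logical, aligned with input), `center` (robust centre),
#'   `rsdr`, `Q`.
#' @export
rout_outliers <- function(values, params = rout_params()) {
  stopifnot(inherits(params, "rout_params"))
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite")
  n <- length(x)
  no_flag <- function(center, rsdr) {
    structure(list(kept = x, flagged = numeric(0),
                   is_outlier = rep(FALSE, n), center = center,
                   rsdr = rsdr, Q = params$Q), class = "rout_result")
  }
  if (n < 3L) {
    warning("fewer than 3 values; no outlier removal attempted")
    return(no_flag(stats::median(x), 0))
  }
  fit <- robust_constant_fit(x)
  if (fit$rsdr <= 0) return(no_flag(fit$center, fit$rsdr))
  res <- abs(x - fit$center)
  ord <- order(res, decreasing = TRUE)
  m <- min(floor(params$max_fraction_removed * n), n - 2L)
  if (m < 1L) return(no_flag(fit$center, fit$rsdr))
  tt <- res[ord[seq_len(m)]] / fit$rsdr
  p <- 2 * stats::pt(-tt, df = n - 1L)
  alpha <- params$Q * (n - seq_len(m) + 1L) / n
  sig <- which(p < alpha)
  is_out <- rep(FALSE, n)
  if (length(sig)) is_out[ord[seq_len(max(sig))]] <- TRUE
  structure(list(kept = x[!is_out], flagged = x[is_out],
                 is_outlier = is_out, center = fit$center,
                 rsdr = fit$rsdr, Q = params$Q), class = "rout_result")
}

#' @export
print.rout_result <- function(x, ...) {
  cat(sprintf(
    "<rout_result> %d of %d values flagged (Q = %g%%); center %.5g, RSDR %.5g\n",
    length(x$flagged), length(x$is_outlier), 100 * x$Q, x$center, x$rsdr))
  invisible(x)
}

#' Per-group summaries (n, mean, SEM) with optional outlier removal
#'
#' SEM is `sd / sqrt(n)`; undefined (NA) for single-value groups. With
#' `rout = TRUE` each group is passed through [rout_outliers()] first --
#' except groups with more than 50% zero values, which are never
#' outlier-filtered (zero-inflated measurements such as punctae counts in
#' localization-deficient mutants would otherwise lose their signal).
#'
#' @param groups named list of numeric vectors.
#' @param rout apply ROUT per group before summarising? Default FALSE.
#' @param params a [rout_params()].
#' @return data.frame with `group`, `n`, `mean`, `sem`, `n_outliers_removed`.
#' @export
group_summary <- function(groups, rout = FALSE, params = rout_params()) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be named")
  }
  rows <- lapply(names(groups), function(g) {
    v <- as.numeric(groups[[g]])
    if (!length(v)) stop("empty group: ", g)
    removed <- 0L
    if (rout && length(v) >= 3L && mean(v == 0) <= 0.5) {
      rr <- rout_outliers(v, params)
      removed <- length(rr$flagged)
      v <- rr$kept
    }
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
               else NA_real_,
               n_outliers_removed = removed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
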