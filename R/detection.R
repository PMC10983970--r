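#' Punctae detection parameters
#'
#' The detection threshold is `MFI + k_sd * SD` computed over in-cell pixels,
#' with the image dtype maximum as the upper limit; connected components of
#' candidate pixels are kept when their physical area lies inside
#' `[area_min_um2, area_max_um2]` (bounds inclusive).
#'
#' `k_sd = 3` is the standard setting; `k_sd = 2` is used for markers with a
#' different signal-to-noise regime (dim markers, or constructs with strongly
#' enhanced punctal localization).
#'
#' @param k_sd threshold multiplier (> 0); default 3.
#' @param area_min_um2,area_max_um2 size filter in square micrometres;
#'   defaults 0.02 and 0.5.
#' @param connectivity 8 (particle-analysis convention, default) or 4.
#' @export
detection_params <- function(k_sd = 3, area_min_um2 = 0.02,
                             area_max_um2 = 0.5, connectivity = 8L) {
  if (k_sd <= 0) stop("k_sd must be > 0")
  if (!(area_min_um2 > 0 && area_min_um2 < area_max_um2)) {
    stop("need 0 < area_min_um2 < area_max_um2")
  }
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(k_sd = k_sd, area_min_um2 = area_min_um2,
                 area_max_um2 = area_max_um2,
                 connectivity = as.integer(connectivity)),
            class = "detection_params")
}

#' Segment the cell body from a fluorescence image
#'
#' Applies a global automatic threshold (Otsu by default) to the whole frame,
#' keeps the largest connected foreground component, and fills holes. This is
#' the "auto-threshold then remove background" step of the punctae pipeline:
#' everything outside the returned mask is excluded from all downstream
#' statistics rather than zero-filled.
#'
#' @param image a [plane_image()].
#' @param method "otsu" (default). Exposed so alternative global thresholds
#'   can be slotted in; only Otsu is currently implemented.
#' @return logical matrix, the cell mask.
#' @export
segment_cell <- function(image, method = "otsu") {
  stopifnot(inherits(image, "plane_image"))
  px <- image$pixels
  if (max(px) == min(px)) stop("no foreground: image is constant")
  method <- match.arg(method, "otsu")
  thr <- EBImage::otsu(EBImage::Image(px / image$bit_max),
                       range = c(0, 1), levels = image$bit_max + 1)
  fg <- px / image$bit_max >= thr
  if (!any(fg)) stop("no foreground above automatic threshold")
  lab <- label_components(fg, connectivity = 8L)
  sizes <- tabulate(lab[lab > 0L])
  biggest <- which.max(sizes)
  mask <- lab == biggest
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  matrix(as.logical(filled > 0), nrow(px), ncol(px))
}

#' In-cell intensity statistics
#'
#' Mean fluorescence intensity (MFI) and standard deviation over mask pixels
#' only; out-of-mask pixels never enter the statistics.
#'
#' @param image a [plane_image()].
#' @param mask logical matrix, same shape.
#' @return list with `mfi`, `sd` (sample SD), `n_pixels`.
#' @export
cell_stats <- function(image, mask) {
  stopifnot(inherits(image, "plane_image"), is.logical(mask),
            identical(dim(mask), dim(image$pixels)))
  if (!any(mask)) stop("empty mask")
  v <- image$pixels[mask]
  list(mfi = mean(v),
       sd = if (length(v) > 1L) stats::sd(v) else 0,
       n_pixels = length(v))
}

#' Detect punctae inside a cell mask
#'
#' Candidate pixels are mask pixels whose intensity lies in
#' `[MFI + k_sd * SD, bit_max]` (both bounds inclusive). Connected components
#' of candidates (8-connected by default) whose area in square micrometres
#' falls within the size filter are reported as punctae. Intensities outside
#' the mask cannot influence the result.
#'
#' @param image a [plane_image()].
#' @param mask logical cell mask; computed with [segment_cell()] if `NULL`.
#' @param params a [detection_params()].
#' @return Object of class `puncta_set`: data.frame `punctae` with columns
#'   `id`, `n_pixels`, `area_um2`, `centroid_row`, `centroid_col` (continuous
#'   1-based pixel coordinates), `mean_intensity`; plus attributes
#'   `label` (labelled matrix restricted to accepted punctae), `params`,
#'   `pixel_size_um`, `stats`.
#' @export
detect_punctae <- function(image, mask = NULL, params = detection_params()) {
  stopifnot(inherits(image, "plane_image"),
            inherits(params, "detection_params"))
  if (is.null(mask)) mask <- segment_cell(image)
  st <- cell_stats(image, mask)
  lower <- st$mfi + params$k_sd * st$sd
  candidates <- mask & image$pixels >= lower & image$pixels <= image$bit_max
  lab <- label_components(candidates, params$connectivity)
  n <- max(lab)
  px_area <- image$pixel_size_um^2
  keep_lab <- integer(0)
  rows <- integer(0)
  if (n > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    # inclusive bounds evaluated on pixel counts so that e.g. a 50-px
    # component at 0.1 um/px sits exactly on the 0.5 um^2 limit
    min_px <- ceiling(params$area_min_um2 / px_area - 1e-9)
    max_px <- floor(params$area_max_um2 / px_area + 1e-9)
    keep_lab <- which(sizes >= min_px & sizes <= max_px)
  }
  if (length(keep_lab)) {
    keep_px <- matrix(lab %in% keep_lab, nrow(lab), ncol(lab))
    idx <- which(keep_px, arr.ind = TRUE)
    labv <- lab[keep_px]
    ord <- order(labv)
    idx <- idx[ord, , drop = FALSE]; labv <- labv[ord]
    new_id <- match(labv, keep_lab)
    inten <- image$pixels[cbind(idx[, 1L], idx[, 2L])]
    agg <- function(x) as.numeric(tapply(x, new_id, mean))
    punctae <- data.frame(
      id = seq_along(keep_lab),
      n_pixels = as.integer(tabulate(new_id)),
      area_um2 = as.numeric(tabulate(new_id)) * px_area,
      centroid_row = agg(idx[, 1L]),
      centroid_col = agg(idx[, 2L]),
      mean_intensity = agg(inten)
    )
    out_lab <- matrix(0L, nrow(lab), ncol(lab))
    out_lab[cbind(idx[, 1L], idx[, 2L])] <- new_id
  } else {
    punctae <- data.frame(id = integer(0), n_pixels = integer(0),
                          area_um2 = numeric(0), centroid_row = numeric(0),
                          centroid_col = numeric(0),
                          mean_intensity = numeric(0))
    out_lab <- matrix(0L, nrow(lab), ncol(lab))
  }
  structure(list(punctae = punctae, label = out_lab, params = params,
                 pixel_size_um = image$pixel_size_um, stats = st),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d punctae (k_sd = %g, area %g-%g um^2)\n",
              nrow(x$punctae), x$params$k_sd, x$params$area_min_um2,
              x$params$area_max_um2))
  if (nrow(x$punctae)) {
    cat(sprintf("  mean area %.4g um^2, mean intensity %.5g\n",
                mean(x$punctae$area_um2), mean(x$punctae$mean_intensity)))
  }
  invisible(x)
}

#' Object-based colocalization of two punctae sets
#'
#' A pair (a, b) is a colocalization candidate when the two punctae share at
#' least one pixel (an overlap-fraction criterion is available via
#' `min_overlap_frac`). Candidates are resolved to a one-to-one matching by
#' descending overlap area, ties broken by ascending (a id, b id); each
#' punctum joins at most one pair.
#'
#' @param a,b `puncta_set` objects from same-shape images.
#' @param min_overlap_frac optional minimum shared-pixel fraction of the
#'   smaller punctum required to call a pair (default 0, i.e. any overlap).
#' @return list with `n_a_only`, `n_b_only`, `n_double`, and `pairs`
#'   (data.frame `a_id`, `b_id`, `overlap_px`).
#' @export
colocalize <- function(a, b, min_overlap_frac = 0) {
  stopifnot(inherits(a, "puncta_set"), inherits(b, "puncta_set"))
  if (!identical(dim(a$label), dim(b$label))) {
    stop("puncta sets come from images of different shape")
  }
  la <- a$label; lb <- b$label
  both <- la > 0L & lb > 0L
  pairs <- data.frame(a_id = integer(0), b_id = integer(0),
                      overlap_px = integer(0))
  if (any(both)) {
    key <- paste(la[both], lb[both])
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    cand <- data.frame(a_id = as.integer(parts[, 1L]),
                       b_id = as.integer(parts[, 2L]),
                       overlap_px = as.integer(tab))
    if (min_overlap_frac > 0) {
      size_a <- a$punctae$n_pixels[match(cand$a_id, a$punctae$id)]
      size_b <- b$punctae$n_pixels[match(cand$b_id, b$punctae$id)]
      cand <- cand[cand$overlap_px >=
                     min_overlap_frac * pmin(size_a, size_b), , drop = FALSE]
    }
    cand <- cand[order(-cand$overlap_px, cand$a_id, cand$b_id), , drop = FALSE]
    used_a <- logical(nrow(a$punctae)); used_b <- logical(nrow(b$punctae))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ai <- cand$a_id[i]; bi <- cand$b_id[i]
      if (!used_a[ai] && !used_b[bi]) {
        keep[i] <- TRUE; used_a[ai] <- TRUE; used_b[bi] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  n_double <- nrow(pairs)
  list(n_a_only = nrow(a$punctae) - n_double,
       n_b_only = nrow(b$punctae) - n_double,
       n_double = n_double,
       pairs = pairs)
}
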