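#' Shear-flow detachment series
#'
#' Cell counts from a microfluidics detachment assay: the reference count
#' after the initial wash, then the count remaining at the end of each
#' flow-rate interval.
#'
#' @param flow_rates_ul_min ordered flow rates (one per interval), ul/min.
#' @param counts cell counts of length `length(flow_rates_ul_min) + 1`; the
#'   first entry is the post-wash reference N0 (> 0).
#' @export
detachment_series <- function(flow_rates_ul_min, counts) {
  counts <- as.numeric(counts)
  if (length(counts) != length(flow_rates_ul_min) + 1L) {
    stop("counts must have one entry more than flow_rates_ul_min")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (counts[1L] <= 0) stop("reference count N0 must be > 0")
  structure(list(flow_rates_ul_min = flow_rates_ul_min, counts = counts),
            class = "detachment_series")
}

#' @export
print.detachment_series <- function(x, ...) {
  cat(sprintf("<detachment_series> N0 = %g; %d flow steps (%g-%g ul/min)\n",
              x$counts[1L], length(x$flow_rates_ul_min),
              min(x$flow_rates_ul_min), max(x$flow_rates_ul_min)))
  invisible(x)
}

#' Cumulative percent of cells detached per flow interval
#'
#' `pct_i = 100 (N0 - N_i) / N0` relative to the post-wash reference count,
#' so the percentages are cumulative across the flow ladder. A count
#' exceeding N0 (cells drifting into view) produces a warning and a flag; the
#' percentage is reported clamped at 0.
#'
#' @param series a [detachment_series()].
#' @return data.frame with `flow_rate_ul_min`, `n_remaining`,
#'   `pct_detached`, `flagged`.
#' @export
percent_detached <- function(series) {
  stopifnot(inherits(series, "detachment_series"))
  n0 <- series$counts[1L]
  ni <- series$counts[-1L]
  flag <- ni > n0
  if (any(flag)) {
    warning("count exceeds reference N0 at ",
            sum(flag), " interval(s); clamped to 0% detached")
  }
  pct <- 100 * (n0 - pmin(ni, n0)) / n0
  data.frame(flow_rate_ul_min = series$flow_rates_ul_min,
             n_remaining = ni, pct_detached = pct, flagged = flag)
}

#' Cell spreading area
#'
#' @param mask logical cell mask.
#' @param pixel_size_um micrometres per pixel edge.
#' @return area in square micrometres (pixel count times pixel area).
#' @export
spreading_area <- function(mask, pixel_size_um) {
  stopifnot(is.logical(mask), pixel_size_um > 0)
  if (!any(mask)) stop("empty mask")
  sum(mask) * pixel_size_um^2
}

#' Rear/front intensity ratio of a polarized cell
#'
#' The cell is split by the line through its centroid perpendicular to the
#' migration axis; the front is the half in the direction of motion. The
#' ratio is mean in-mask intensity (rear) over mean in-mask intensity
#' (front). Used to test for rear-ward actin accumulation (a hallmark of
#' cortical-contractility-driven amoeboid movement).
#'
#' @param image a [plane_image()] of the cytoskeletal marker.
#' @param mask logical cell mask.
#' @param axis length-2 migration direction vector (need not be unit); the
#'   zero vector (stationary cell) is an error.
#' @param mode "halves" (default) or "thirds" (front/rear thirds along the
#'   axis, middle excluded).
#' @return rear/front mean-intensity ratio.
#' @export
rear_front_ratio <- function(image, mask, axis, mode = c("halves", "thirds")) {
  stopifnot(inherits(image, "plane_image"), is.logical(mask),
            identical(dim(mask), dim(image$pixels)))
  mode <- match.arg(mode)
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm < 1e-12) {
    stop("migration axis undefined (stationary cell)")
  }
  ax <- axis / nrm
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  # axis is (x, y) = (col, row); project pixel offsets from the centroid
  cr <- mean(idx[, 1L]); cc <- mean(idx[, 2L])
  proj <- (idx[, 2L] - cc) * ax[1L] + (idx[, 1L] - cr) * ax[2L]
  vals <- image$pixels[idx]
  if (mode == "halves") {
    # pixels exactly on the dividing line belong to neither half, keeping
    # the ratio exactly reciprocal under axis reversal
    front <- proj > 0; rear <- proj < 0
  } else {
    q <- stats::quantile(proj, c(1 / 3, 2 / 3))
    rear <- proj <= q[1L]; front <- proj >= q[2L]
  }
  if (!any(front) || !any(rear)) stop("empty front or rear region")
  mean(vals[rear]) / mean(vals[front])
}
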