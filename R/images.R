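#' Plane image with physical pixel size
#'
#' Wraps a 2-D grid of non-negative integer intensities together with the
#' dtype maximum (e.g. 65535 for 16-bit cameras) and the physical pixel edge
#' length in micrometres. All quantification downstream (areas, speeds,
#' mean square displacements) is reported in physical units derived from
#' `pixel_size_um`.
#'
#' @param pixels numeric matrix of intensities, all in `[0, bit_max]`.
#' @param pixel_size_um micrometres per pixel edge (> 0). Default 0.1.
#' @param bit_depth 8 or 16; sets `bit_max` to `2^bit_depth - 1`.
#' @return An object of class `plane_image` with fields `pixels`, `bit_max`,
#'   `pixel_size_um`.
#' @export
plane_image <- function(pixels, pixel_size_um = 0.1, bit_depth = 16L) {
  stopifnot(is.matrix(pixels))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  bit_max <- 2^bit_depth - 1
  px <- pixels
  storage.mode(px) <- "double"
  if (any(!is.finite(px))) stop("pixels must be finite")
  if (any(px < 0) || any(px > bit_max)) {
    stop("pixels must lie in [0, ", bit_max, "]")
  }
  structure(
    list(pixels = px, bit_max = bit_max, pixel_size_um = pixel_size_um),
    class = "plane_image"
  )
}

#' @export
print.plane_image <- function(x, ...) {
  cat(sprintf(
    "<plane_image> %d x %d px, %.4g um/px, bit max %d, range [%g, %g]\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, as.integer(x$bit_max),
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.plane_image <- function(x) dim(x$pixels)

#' Ordered stack of frames with a uniform frame interval
#'
#' @param frames list of same-shape `plane_image` objects, or a list of
#'   matrices (converted with shared `pixel_size_um`/`bit_depth`).
#' @param frame_interval_s seconds between consecutive frames (> 0);
#'   default 0.75, the acquisition cadence used for adhesion-lifetime imaging.
#' @param pixel_size_um,bit_depth used when `frames` are bare matrices.
#' @return Object of class `image_stack`: fields `frames` (list of
#'   `plane_image`), `frame_interval_s`.
#' @export
image_stack <- function(frames, frame_interval_s = 0.75,
                        pixel_size_um = 0.1, bit_depth = 16L) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  frames <- lapply(frames, function(f) {
    if (inherits(f, "plane_image")) f
    else plane_image(f, pixel_size_um = pixel_size_um, bit_depth = bit_depth)
  })
  d0 <- dim(frames[[1L]]$pixels)
  b0 <- frames[[1L]]$bit_max
  ok <- vapply(frames, function(f) {
    identical(dim(f$pixels), d0) && identical(f$bit_max, b0)
  }, logical(1L))
  if (!all(ok)) stop("all frames must share shape and bit depth")
  structure(list(frames = frames, frame_interval_s = frame_interval_s),
            class = "image_stack")
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]]$pixels)
  cat(sprintf("<image_stack> %d frames of %d x %d px, dt = %g s\n",
              length(x$frames), d[1L], d[2L], x$frame_interval_s))
  invisible(x)
}

#' Read a single-plane or multi-frame TIFF
#'
#' Integer sample values are preserved exactly (the file is read `as.is`).
#'
#' @param path TIFF file.
#' @param pixel_size_um physical pixel size to attach (TIFF tags are not
#'   trusted; supply from acquisition metadata or config).
#' @param frame_interval_s frame interval when the file holds a stack.
#' @return `plane_image` for single-plane files, `image_stack` otherwise.
#' @export
read_image <- function(path, pixel_size_um = 0.1, frame_interval_s = 0.75) {
  pl <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  bit <- if (max(vapply(pl, max, numeric(1L))) > 255) 16L else 8L
  mats <- lapply(pl, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1L]  # first channel of RGB reads
    m
  })
  if (length(mats) == 1L) {
    plane_image(mats[[1L]], pixel_size_um = pixel_size_um, bit_depth = bit)
  } else {
    image_stack(mats, frame_interval_s = frame_interval_s,
                pixel_size_um = pixel_size_um, bit_depth = bit)
  }
}

#' Write a `plane_image`, `image_stack`, or logical mask as TIFF
#'
#' Masks are written as 8-bit 0/255 images.
#'
#' @param x `plane_image`, `image_stack`, or logical matrix.
#' @param path output file.
#' @export
write_image <- function(x, path) {
  if (is.logical(x) && is.matrix(x)) {
    tiff::writeTIFF((x * 255) / 255, path, bits.per.sample = 8L)
    return(invisible(path))
  }
  if (inherits(x, "plane_image")) x <- list(x) else
    if (inherits(x, "image_stack")) x <- x$frames else
      stop("unsupported image type")
  bits <- if (x[[1L]]$bit_max > 255) 16L else 8L
  planes <- lapply(x, function(f) f$pixels / f$bit_max)
  tiff::writeTIFF(planes, path, bits.per.sample = bits)
  invisible(path)
}

# 8-connected labelling. EBImage::bwlabel is 4-connected; particle analysis in
# the field's toolchain treats diagonal neighbours as connected, so 4-labels
# that touch diagonally are merged with a union-find pass.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask != 0)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (connectivity == 4L || n <= 1L) return(lab)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- nrow(lab); nc <- ncol(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # diagonal adjacencies between distinct 4-connected labels
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),
    cbind(as.vector(lab[-1L, -nc]), as.vector(lab[-nr, -1L]))
  )
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1L))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[out > 0L] <- relab[out[out > 0L]]
  out
}

# Run expr under a local RNG seed without touching the caller's random state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
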