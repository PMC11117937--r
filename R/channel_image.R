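#' Known fluorescence channels
#'
#' Channel names used throughout the package: intrinsic NADH and Fp
#' (FAD-containing flavoprotein) autofluorescence, MitoSOX red (mitochondrial
#' superoxide), and the green/red channels of the ratiometric lipid
#' peroxidation sensor.
#' @export
ORI_CHANNELS <- c("nadh", "fp", "mitosox", "lipid_green", "lipid_red")

#' Construct a single-channel field-of-view image
#'
#' A `channel_image` holds one grayscale field of view (FOV) for one named
#' fluorescence channel, in arbitrary intensity units (a.u.), together with
#' the pixel size and a FOV identifier. All downstream quantification
#' consumes this container.
#'
#' @param pixels Numeric matrix of nonnegative, finite intensities (a.u.).
#' @param channel One of [ORI_CHANNELS].
#' @param pixel_size_um Pixel edge length in micrometres. The default matches
#'   a 20x widefield configuration (0.293 um/px).
#' @param fov_id Character identifier of the field of view.
#' @return An object of class `channel_image`.
#' @examples
#' img <- channel_image(matrix(100, 64, 64), "nadh")
#' dim(img$pixels)
#' @export
channel_image <- function(pixels, channel, pixel_size_um = 0.293,
                          fov_id = "fov") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("pixel values must be finite", call. = FALSE)
  }
  if (any(pixels < 0)) {
    stop("pixel values must be >= 0 (arbitrary units)", call. = FALSE)
  }
  channel <- match.arg(channel, ORI_CHANNELS)
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1,
            pixel_size_um > 0)
  structure(
    list(pixels = pixels, channel = channel,
         pixel_size_um = pixel_size_um, fov_id = as.character(fov_id)),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %d x %d px (%.3f um/px), fov '%s'\n",
              x$channel, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_um, x$fov_id))
  cat(sprintf("  intensity range [%.4g, %.4g] a.u.\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_channel_image <- function(x) inherits(x, "channel_image")

# Normalise a background-ROI specification to linear pixel indices.
# Accepted forms: logical matrix (same dims), integer vector of linear
# indices, or list(x0, x1, y0, y1) rectangle in row/column coordinates.
as_roi_indices <- function(roi, dims) {
  if (is.logical(roi) && is.matrix(roi)) {
    if (!all(dim(roi) == dims)) {
      stop("ROI mask dimensions do not match the image", call. = FALSE)
    }
    return(which(roi))
  }
  if (is.numeric(roi) && is.null(dim(roi))) {
    idx <- as.integer(roi)
    if (length(idx) == 0 || any(idx < 1) || any(idx > prod(dims))) {
      stop("ROI indices fall outside the image bounds", call. = FALSE)
    }
    return(idx)
  }
  if (is.list(roi) && all(c("x0", "x1", "y0", "y1") %in% names(roi))) {
    if (roi$x0 < 1 || roi$x1 > dims[1] || roi$y0 < 1 || roi$y1 > dims[2] ||
        roi$x0 > roi$x1 || roi$y0 > roi$y1) {
      stop("ROI rectangle falls outside the image bounds", call. = FALSE)
    }
    rows <- roi$x0:roi$x1
    cols <- roi$y0:roi$y1
    return(as.integer(outer(rows, (cols - 1) * dims[1], `+`)))
  }
  stop("unsupported ROI specification", call. = FALSE)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
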