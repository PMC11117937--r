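#' SNR threshold policy
#'
#' Signal-to-noise thresholds used to retain pixels after background
#' subtraction, where noise is the standard deviation of the cell-free
#' background. Defaults are 7.5 for the ORI channels (NADH, Fp, and the
#' lipid-sensor channels) and 5 for MitoSOX.
#'
#' @param ori_snr Positive SNR threshold for ORI channels.
#' @param mitosox_snr Positive SNR threshold for MitoSOX.
#' @return A `threshold_policy` list.
#' @export
threshold_policy <- function(ori_snr = 7.5, mitosox_snr = 5) {
  stopifnot(is.numeric(ori_snr), length(ori_snr) == 1,
            is.numeric(mitosox_snr), length(mitosox_snr) == 1)
  if (ori_snr <= 0 || mitosox_snr <= 0) {
    stop("SNR thresholds must be positive", call. = FALSE)
  }
  structure(list(ori_snr = ori_snr, mitosox_snr = mitosox_snr),
            class = "threshold_policy")
}

snr_for_channel <- function(channel, policy) {
  if (channel == "mitosox") policy$mitosox_snr else policy$ori_snr
}

#' Estimate background level and noise from a cell-free region
#'
#' Computes the sample mean and sample standard deviation (n-1 denominator)
#' of the pixels in a cell-free region of interest. The standard deviation
#' is the "noise" used by SNR thresholding. At least 100 pixels are required
#' for estimator stability, and a zero standard deviation (constant region)
#' is rejected because SNR thresholding would be undefined.
#'
#' @param img A [channel_image].
#' @param roi Cell-free region: logical matrix, linear pixel indices, or a
#'   rectangle `list(x0, x1, y0, y1)` (row/column ranges, inclusive). If
#'   `NULL`, the lowest intensity decile of the image is used as an automatic
#'   fallback, with a warning.
#' @return A `background_estimate` with fields `mean`, `sd`, `n_pixels`,
#'   `roi` (the linear indices used) and `channel`.
#' @examples
#' img <- channel_image(matrix(rnorm(256^2, 100, 8), 256, 256) + 20, "nadh")
#' bg <- estimate_background(img, list(x0 = 1, x1 = 32, y0 = 1, y1 = 256))
#' c(bg$mean, bg$sd)
#' @export
estimate_background <- function(img, roi = NULL) {
  stopifnot(is_channel_image(img))
  if (is.null(roi)) {
    warning("no background ROI supplied; falling back to the lowest ",
            "intensity decile of the image", call. = FALSE)
    cutoff <- stats::quantile(img$pixels, 0.1, names = FALSE)
    idx <- which(img$pixels <= cutoff)
  } else {
    idx <- as_roi_indices(roi, dim(img$pixels))
  }
  if (length(idx) < 100) {
    stop("background ROI has ", length(idx),
         " pixels; at least 100 are required", call. = FALSE)
  }
  v <- img$pixels[idx]
  s <- stats::sd(v)
  if (s <= 0) {
    stop("degenerate background: standard deviation is zero, so an SNR ",
         "threshold cannot be formed", call. = FALSE)
  }
  structure(list(mean = mean(v), sd = s, n_pixels = length(idx),
                 roi = idx, channel = img$channel),
            class = "background_estimate")
}

#' Subtract the background level from an image
#'
#' Subtracts the background mean from every pixel and clips negative values
#' to zero: sub-background pixels can never pass an SNR threshold, and
#' clipping guarantees the redox ratio stays inside (0, 1). The background
#' noise (SD) is carried on the result for downstream thresholding. The
#' operation is deliberately not idempotent; subtracting twice shifts the
#' image by twice the background mean.
#'
#' @param img A [channel_image].
#' @param bg A `background_estimate` from [estimate_background()], normally
#'   for the same channel of the same FOV.
#' @return A [channel_image] with attribute `bg_sd` (background noise) and
#'   `bg_mean`.
#' @export
subtract_background <- function(img, bg) {
  stopifnot(is_channel_image(img), inherits(bg, "background_estimate"))
  if (!identical(bg$channel, img$channel)) {
    warning("background estimate is from channel '", bg$channel,
            "' but image is '", img$channel, "'", call. = FALSE)
  }
  out <- channel_image(pmax(img$pixels - bg$mean, 0), img$channel,
                       img$pixel_size_um, img$fov_id)
  attr(out, "bg_sd") <- bg$sd
  attr(out, "bg_mean") <- bg$mean
  out
}

#' Threshold a background-subtracted image at a signal-to-noise ratio
#'
#' A pixel is retained iff its corrected value is at least `snr * bg_sd`
#' (the comparison is `>=`, i.e. a pixel exactly at the threshold is
#' retained). No morphological cleanup is applied.
#'
#' @param img A background-subtracted [channel_image] (or plain numeric
#'   matrix of corrected values).
#' @param bg_sd Positive background noise (SD); defaults to the `bg_sd`
#'   attribute left by [subtract_background()].
#' @param snr Positive SNR threshold.
#' @return Logical matrix, `TRUE` for retained pixels.
#' @export
threshold_mask <- function(img, bg_sd = NULL, snr = 7.5) {
  px <- if (is_channel_image(img)) img$pixels else img
  if (is.null(bg_sd)) bg_sd <- attr(img, "bg_sd")
  if (is.null(bg_sd) || !is.numeric(bg_sd) || bg_sd <= 0) {
    stop("`bg_sd` must be a positive background noise estimate",
         call. = FALSE)
  }
  if (!is.numeric(snr) || length(snr) != 1 || snr <= 0) {
    stop("`snr` must be a positive scalar", call. = FALSE)
  }
  px >= snr * bg_sd
}

#' Pixel-wise redox-ratio image
#'
#' Computes the optical redox ratio Fp/(NADH + Fp) pixel by pixel from
#' background-subtracted NADH and Fp images, on the intersection of the two
#' channel masks. Outside the joint mask the ratio is undefined (`NA`). On
#' the joint mask both channels are strictly positive (they passed a
#' positive SNR threshold), so every defined ratio lies in (0, 1).
#'
#' @param nadh,fp Background-subtracted [channel_image]s (or matrices) of
#'   identical dimensions.
#' @param nadh_mask,fp_mask Logical masks from [threshold_mask()].
#' @return List with `ratio` (numeric matrix, `NA` off-mask) and `mask`
#'   (the joint logical mask).
#' @export
redox_ratio_image <- function(nadh, fp, nadh_mask, fp_mask) {
  n <- if (is_channel_image(nadh)) nadh$pixels else nadh
  f <- if (is_channel_image(fp)) fp$pixels else fp
  if (!all(dim(n) == dim(f)) || !all(dim(n) == dim(nadh_mask)) ||
      !all(dim(n) == dim(fp_mask))) {
    stop("NADH/Fp images and masks must share dimensions (co-registered)",
         call. = FALSE)
  }
  mask <- nadh_mask & fp_mask
  ratio <- matrix(NA_real_, nrow(n), ncol(n))
  ratio[mask] <- f[mask] / (n[mask] + f[mask])
  list(ratio = ratio, mask = mask)
}

index_row <- function(index, values) {
  data.frame(index = index, mean = mean(values), sd = stats::sd(values),
             n_pixels = length(values), stringsAsFactors = FALSE)
}

#' Quantify one field of view
#'
#' Runs the full per-FOV routine: estimate background per channel, subtract
#' it, threshold at the policy SNR (7.5 for ORI channels, 5 for MitoSOX),
#' build the pixel-wise redox-ratio image on the intersection of the NADH
#' and Fp masks, and report masked means and SDs per index. The redox-ratio
#' mean is the mean of pixel-wise ratios, not the ratio of channel means
#' (the latter is available as the `ratio_of_means` diagnostic). Indices
#' whose mask is empty are reported as absent, with a warning.
#'
#' @param images Named list of [channel_image]s; `nadh` and `fp` are
#'   required for the ORI indices, `mitosox` is optional (cells may detach
#'   between imaging rounds).
#' @param background_rois A single ROI spec applied to every channel, or a
#'   named list of per-channel ROI specs (see [estimate_background()]).
#' @param policy A [threshold_policy()].
#' @param fov_id FOV identifier; defaults to the id of the first image.
#' @param keep_images If `TRUE`, attach corrected images, masks and the
#'   ratio image to the result (for export or inspection).
#' @return A `fov_quant`: list with `fov_id`, `indices` (data.frame with
#'   columns index/mean/sd/n_pixels), `ratio_of_means` diagnostic, and
#'   optionally `images`.
#' @examples
#' sc <- generate_scene(scene_params(n_macrophages = 4, n_rbc = 1, seed = 7))
#' q <- quantify_fov(sc$channels, background_roi(sc))
#' q$indices
#' @export
quantify_fov <- function(images, background_rois, policy = threshold_policy(),
                         fov_id = NULL, keep_images = FALSE) {
  stopifnot(is.list(images), length(images) > 0)
  nm <- vapply(images, function(i) i$channel, character(1))
  names(images) <- nm
  if (!all(c("nadh", "fp") %in% nm)) {
    stop("`images` must contain at least the 'nadh' and 'fp' channels",
         call. = FALSE)
  }
  dims <- dim(images[["nadh"]]$pixels)
  for (im in images) {
    if (!all(dim(im$pixels) == dims)) {
      stop("all channels of one FOV must share dimensions", call. = FALSE)
    }
  }
  if (is.null(fov_id)) fov_id <- images[[1]]$fov_id
  roi_for <- function(ch) {
    if (is.list(background_rois) && !is.null(names(background_rois)) &&
        ch %in% names(background_rois)) {
      background_rois[[ch]]
    } else background_rois
  }

  corrected <- list()
  masks <- list()
  for (ch in nm) {
    bg <- estimate_background(images[[ch]], roi_for(ch))
    corrected[[ch]] <- subtract_background(images[[ch]], bg)
    masks[[ch]] <- threshold_mask(corrected[[ch]],
                                  snr = snr_for_channel(ch, policy))
  }

  rows <- list()
  absent <- character(0)
  for (ch in intersect(c("nadh", "fp", "mitosox"), nm)) {
    v <- corrected[[ch]]$pixels[masks[[ch]]]
    if (length(v) > 0) rows[[ch]] <- index_row(ch, v) else absent <- c(absent, ch)
  }
  rr <- redox_ratio_image(corrected[["nadh"]], corrected[["fp"]],
                          masks[["nadh"]], masks[["fp"]])
  ratio_of_means <- NA_real_
  if (any(rr$mask)) {
    rows[["redox_ratio"]] <- index_row("redox_ratio", rr$ratio[rr$mask])
    fm <- mean(corrected[["fp"]]$pixels[rr$mask])
    nmn <- mean(corrected[["nadh"]]$pixels[rr$mask])
    ratio_of_means <- fm / (nmn + fm)
  } else {
    absent <- c(absent, "redox_ratio")
  }
  if (length(absent) > 0) {
    warning("FOV '", fov_id, "': empty mask, index absent: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  idx <- if (length(rows)) do.call(rbind, rows) else
    data.frame(index = character(0), mean = numeric(0), sd = numeric(0),
               n_pixels = integer(0))
  rownames(idx) <- NULL
  out <- structure(list(fov_id = fov_id, indices = idx,
                        ratio_of_means = ratio_of_means),
                   class = "fov_quant")
  if (keep_images) {
    out$images <- list(corrected = corrected, masks = masks, ratio = rr)
  }
  out
}

#' @export
print.fov_quant <- function(x, ...) {
  cat(sprintf("<fov_quant> fov '%s'\n", x$fov_id))
  print(x$indices, row.names = FALSE)
  invisible(x)
}

#' Aggregate field-of-view quantifications into a sample summary
#'
#' Averages FOV-level index means, unweighted by pixel count, into a single
#' per-sample value (a patient's tracheal-aspirate sample, or a culture
#' dish), with the across-FOV sample SD (n-1) when at least two FOVs carry
#' the index. FOVs lacking an index (empty mask) are excluded from that
#' index only.
#'
#' @param fovs List of `fov_quant` objects (at least one).
#' @param sample_id Sample identifier (patient or dish).
#' @param group Preparation group: `"A"` (loose cells), `"B"` (DTT-released)
#'   or `"cell_line"`.
#' @return A `sample_summary`: list with `sample_id`, `group`, and `indices`
#'   (data.frame index/mean/sd/n_fovs; `sd` is `NA` when `n_fovs < 2`).
#' @export
summarize_sample <- function(fovs, sample_id, group = c("A", "B", "cell_line")) {
  group <- match.arg(group)
  if (inherits(fovs, "fov_quant")) fovs <- list(fovs)
  if (length(fovs) == 0) stop("at least one FOV is required", call. = FALSE)
  stopifnot(all(vapply(fovs, inherits, logical(1), "fov_quant")))
  all_idx <- unique(unlist(lapply(fovs, function(f) f$indices$index)))
  rows <- lapply(all_idx, function(ix) {
    vals <- unlist(lapply(fovs, function(f) {
      m <- f$indices$mean[f$indices$index == ix]
      if (length(m)) m else NULL
    }))
    data.frame(index = ix, mean = mean(vals),
               sd = if (length(vals) >= 2) stats::sd(vals) else NA_real_,
               n_fovs = length(vals), stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, rows)
  rownames(idx) <- NULL
  structure(list(sample_id = as.character(sample_id), group = group,
                 indices = idx),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary> sample '%s', group %s\n", x$sample_id, x$group))
  print(x$indices, row.names = FALSE)
  invisible(x)
}

#' Flatten sample summaries into a tidy table
#'
#' @param summaries A `sample_summary` or list of them.
#' @return data.frame with columns `sample_id`, `group`, `index`, `mean`,
#'   `sd`, `n_fovs`, one row per (sample, index).
#' @export
summaries_df <- function(summaries) {
  if (inherits(summaries, "sample_summary")) summaries <- list(summaries)
  out <- do.call(rbind, lapply(summaries, function(s) {
    cbind(data.frame(sample_id = s$sample_id, group = s$group,
                     stringsAsFactors = FALSE),
          s$indices)
  }))
  rownames(out) <- NULL
  out
}
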