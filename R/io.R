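#' Read a single-plane grayscale TIFF as a channel image
#'
#' Intensities are read as stored (8/16-bit integer counts or float values)
#' and never rescaled: arbitrary units in, arbitrary units out. RGB and
#' multi-page TIFFs are rejected.
#'
#' @param path TIFF file path.
#' @param channel Channel name (one of [ORI_CHANNELS]).
#' @param pixel_size_um Pixel size metadata (um).
#' @param fov_id FOV identifier; defaults to the file name sans extension.
#' @return A [channel_image].
#' @export
read_channel_tiff <- function(path, channel, pixel_size_um = 0.293,
                              fov_id = NULL) {
  if (!file.exists(path)) {
    stop("TIFF file not found: ", path, call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != 1) {
    stop("multi-page TIFF (", length(pages), " pages): ", path,
         "; supply one single-plane grayscale image per channel",
         call. = FALSE)
  }
  px <- pages[[1]]
  if (length(dim(px)) == 3) {
    stop("RGB/multi-sample TIFF (", dim(px)[3], " samples per pixel): ", path,
         "; supply grayscale images", call. = FALSE)
  }
  if (is.null(fov_id)) {
    fov_id <- sub("\\.[^.]*$", "", basename(path))
  }
  channel_image(px * 1.0, channel, pixel_size_um, fov_id)
}

#' Write a channel image to TIFF
#'
#' `bits = 16` writes 16-bit unsigned integers (values must lie in
#' [0, 65535]; they are rounded); `bits = 32` writes float32, used for
#' redox-ratio image export.
#'
#' @param img A [channel_image] or numeric matrix.
#' @param path Output path.
#' @param bits 16 (integer) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(img, path, bits = 16) {
  px <- if (is_channel_image(img)) img$pixels else img
  if (bits == 16) {
    px <- round(px)
    if (any(px < 0 | px > 65535, na.rm = TRUE)) {
      stop("16-bit export requires values in [0, 65535]", call. = FALSE)
    }
    px[is.na(px)] <- 0
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16)
  } else if (bits == 32) {
    px[is.na(px)] <- 0
    tiff::writeTIFF(px, path, bits.per.sample = 32)
  } else {
    stop("bits must be 16 or 32", call. = FALSE)
  }
  invisible(path)
}

#' Write a synthetic scene to disk
#'
#' One 16-bit grayscale TIFF per channel named `{scene_id}_{channel}.tif`,
#' the ground-truth label image as `{scene_id}_labels.tif`, and the
#' per-cell truth table as `{scene_id}_truth.csv` (the synthetic ground
#' truth has no real-data counterpart and is labelled as such in the CSV
#' header comment).
#'
#' @param scene A `redox_scene` from [generate_scene()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "redox_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(scene$channels)) {
    p <- file.path(dir, sprintf("%s_%s.tif", scene$scene_id, ch))
    write_channel_tiff(scene$channels[[ch]], p, bits = 16)
    paths[ch] <- p
  }
  lp <- file.path(dir, sprintf("%s_labels.tif", scene$scene_id))
  tiff::writeTIFF(scene$truth$labels / 65535, lp, bits.per.sample = 16)
  paths["labels"] <- lp
  tp <- file.path(dir, sprintf("%s_truth.csv", scene$scene_id))
  con <- file(tp, "w")
  writeLines("# synthetic ground truth (simulated scene; no real data)", con)
  utils::write.csv(scene$truth$cells, con, row.names = FALSE)
  close(con)
  paths["truth"] <- tp
  invisible(paths)
}

default_config <- function() {
  list(ori_snr = 7.5, mitosox_snr = 5, pixel_size_um = 0.293,
       replicate_unit = "fov", out_dir = ".", seed = 1L)
}

#' Validate a quantification run configuration
#'
#' Reads a YAML or JSON configuration (or takes a list), fills defaults
#' (ORI SNR 7.5, MitoSOX SNR 5), and checks every invariant before any
#' computation: thresholds positive, referenced files existing, background
#' ROI well-formed. All failures are reported together.
#'
#' @param cfg Path to a `.yaml`/`.yml`/`.json` file, or a list. Expected
#'   fields: `fovs` (list; each with `id`, `channels` = named file map, and
#'   optionally `background_roi` = rectangle list x0/x1/y0/y1 or mask
#'   path), optional `sample_id`, `group`, `ori_snr`, `mitosox_snr`,
#'   `pixel_size_um`, `out_dir`, `seed`, `replicate_unit`.
#' @return Validated configuration list with class `run_config` and a
#'   `policy` element.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) {
    if (!file.exists(cfg)) stop("config file not found: ", cfg, call. = FALSE)
    cfg_path <- cfg
    cfg <- if (grepl("\\.json$", cfg, ignore.case = TRUE)) {
      jsonlite::read_json(cfg, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(cfg)
    }
    cfg$config_path <- cfg_path
  }
  stopifnot(is.list(cfg))
  defaults <- default_config()
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  problems <- character(0)
  if (!is.numeric(cfg$ori_snr) || cfg$ori_snr <= 0) {
    problems <- c(problems, "ori_snr must be a positive number")
  }
  if (!is.numeric(cfg$mitosox_snr) || cfg$mitosox_snr <= 0) {
    problems <- c(problems, "mitosox_snr must be a positive number")
  }
  if (!is.numeric(cfg$pixel_size_um) || cfg$pixel_size_um <= 0) {
    problems <- c(problems, "pixel_size_um must be positive")
  }
  if (is.null(cfg$fovs) || length(cfg$fovs) == 0) {
    problems <- c(problems, "at least one FOV must be declared under `fovs`")
  } else {
    for (i in seq_along(cfg$fovs)) {
      fov <- cfg$fovs[[i]]
      if (is.null(fov$channels) || length(fov$channels) == 0) {
        problems <- c(problems, sprintf("fov %d: no channel file map", i))
        next
      }
      bad_ch <- setdiff(names(fov$channels), ORI_CHANNELS)
      if (length(bad_ch)) {
        problems <- c(problems, sprintf("fov %d: unknown channel(s) %s", i,
                                        paste(bad_ch, collapse = ", ")))
      }
      for (ch in names(fov$channels)) {
        f <- fov$channels[[ch]]
        if (!file.exists(f)) {
          problems <- c(problems,
                        sprintf("fov %d channel %s: file not found: %s",
                                i, ch, f))
        }
      }
      roi <- fov$background_roi
      if (!is.null(roi) && is.list(roi)) {
        need <- c("x0", "x1", "y0", "y1")
        if (!all(need %in% names(roi))) {
          problems <- c(problems,
                        sprintf("fov %d: background_roi rectangle needs x0/x1/y0/y1", i))
        } else if (any(unlist(roi[need]) < 1) || roi$x0 > roi$x1 ||
                   roi$y0 > roi$y1) {
          problems <- c(problems,
                        sprintf("fov %d: malformed background_roi rectangle", i))
        }
      }
      if (!is.null(roi) && is.character(roi) && !file.exists(roi)) {
        problems <- c(problems,
                      sprintf("fov %d: background mask file not found: %s",
                              i, roi))
      }
    }
  }
  if (!cfg$replicate_unit %in% c("fov", "dish")) {
    problems <- c(problems, "replicate_unit must be 'fov' or 'dish'")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  cfg$policy <- threshold_policy(cfg$ori_snr, cfg$mitosox_snr)
  class(cfg) <- "run_config"
  cfg
}

results_header <- function(cfg = NULL) {
  ver <- as.character(utils::packageVersion("redoximg"))
  hash <- if (!is.null(cfg$config_path) && file.exists(cfg$config_path)) {
    unname(tools::md5sum(cfg$config_path))
  } else "none"
  sprintf("# redoximg %s config_md5=%s", ver, hash)
}

#' Write a results table as CSV with a provenance header
#'
#' Writes a data.frame with a leading comment row carrying the package
#' version and the MD5 of the configuration file, numeric columns pinned to
#' 6 significant digits so that identical runs produce byte-identical
#' files.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param cfg Optional `run_config` (for the config hash).
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(df, path, cfg = NULL) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  con <- file(path, "w")
  writeLines(results_header(cfg), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

load_roi_spec <- function(roi, dims) {
  if (is.null(roi)) return(NULL)
  if (is.character(roi)) {
    m <- tiff::readTIFF(roi, as.is = TRUE)
    return(m > 0)
  }
  roi  # rectangle list; resolved by as_roi_indices at use time
}

#' Run a full quantification from a validated configuration
#'
#' Reads every FOV's channel TIFFs, quantifies them (background
#' subtraction, SNR thresholding, redox-ratio image, masked means), and
#' aggregates to the sample level. FOVs without an explicit background ROI
#' fall back to the lowest intensity decile with a warning.
#'
#' @param cfg A `run_config` from [validate_config()] (or something
#'   coercible by it).
#' @param write If `TRUE`, write `fov_results.csv` and
#'   `sample_results.csv` under `cfg$out_dir`.
#' @return List with `fovs` (list of `fov_quant`), `sample`
#'   (`sample_summary`), `fov_table`, `sample_table` (tidy data.frames).
#' @export
run_quantification <- function(cfg, write = TRUE) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  fovs <- list()
  for (fov in cfg$fovs) {
    images <- list()
    for (ch in names(fov$channels)) {
      images[[ch]] <- read_channel_tiff(fov$channels[[ch]], ch,
                                        cfg$pixel_size_um,
                                        fov_id = fov$id)
    }
    roi <- load_roi_spec(fov$background_roi, dim(images[[1]]$pixels))
    fovs[[length(fovs) + 1]] <- quantify_fov(images, roi,
                                             policy = cfg$policy,
                                             fov_id = fov$id)
  }
  sample_id <- if (!is.null(cfg$sample_id)) cfg$sample_id else "sample"
  group <- if (!is.null(cfg$group)) cfg$group else "cell_line"
  smry <- summarize_sample(fovs, sample_id, group)
  fov_table <- do.call(rbind, lapply(fovs, function(f) {
    cbind(data.frame(sample_id = sample_id, group = group,
                     fov_id = f$fov_id, stringsAsFactors = FALSE),
          f$indices)
  }))
  rownames(fov_table) <- NULL
  sample_table <- summaries_df(smry)
  if (write) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_csv(fov_table, file.path(cfg$out_dir, "fov_results.csv"),
                      cfg)
    write_results_csv(sample_table,
                      file.path(cfg$out_dir, "sample_results.csv"), cfg)
  }
  list(fovs = fovs, sample = smry, fov_table = fov_table,
       sample_table = sample_table)
}
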