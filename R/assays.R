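#' Fit a linear dose-response trend for one imaging index
#'
#' Ordinary least squares of per-replicate (dish or FOV) index means on
#' oxidant dose, with the two-sided t-test of the slope. Used to quantify
#' the linear NADH decrease, Fp increase and redox-ratio increase under
#' serial oxidant addition.
#'
#' @param points data.frame with columns `dose` and `value` (one row per
#'   replicate measurement), or two numeric vectors via `dose`/`value`.
#' @param index Index label (`nadh`, `fp`, `redox_ratio`, `mitosox`).
#' @return A `dose_response_fit`: `regression_result` plus `index`.
#' @examples
#' fit_dose_response(data.frame(dose = 0:3, value = 2 * (0:3) + 1), "fp")
#' @export
fit_dose_response <- function(points, index = "nadh") {
  stopifnot(is.data.frame(points), all(c("dose", "value") %in% names(points)))
  if (length(unique(points$dose)) < 3) {
    stop("need >= 3 distinct doses", call. = FALSE)
  }
  if (stats::sd(points$dose) == 0) {
    stop("all doses identical: no design variance", call. = FALSE)
  }
  r <- linregress(points$dose, points$value, x_name = "dose", y_name = index)
  r$index <- index
  r$n_points <- r$n
  class(r) <- c("dose_response_fit", class(r))
  r
}

summary_index_mean <- function(summary, index) {
  stopifnot(inherits(summary, "sample_summary"))
  m <- summary$indices$mean[summary$indices$index == index]
  if (length(m) != 1) {
    stop("index '", index, "' missing from sample '", summary$sample_id, "'",
         call. = FALSE)
  }
  m
}

#' Redox-titration dynamic ranges (delta NADH, delta Fp)
#'
#' Computes the dynamic ranges between the two metabolic-modulation
#' extremes of one preparation:
#' `delta_nadh = NADH(reduced) - NADH(oxidized)` and
#' `delta_fp = Fp(oxidized) - Fp(reduced)`. Both are positive when the
#' physiology is as expected (NADH builds up under complex I/III
#' inhibition, Fp rises under uncoupling); negative values are allowed and
#' flagged as inverted. Swapping the two extremes negates both deltas.
#'
#' @param oxidized,reduced `sample_summary` objects for the uncoupled
#'   (FCCP) and inhibited (rotenone + antimycin A) states of the same
#'   preparation; both must carry `nadh` and `fp`.
#' @return A `titration_result`: list with `delta_nadh`, `delta_fp`,
#'   `inverted` flags, and the two summaries.
#' @export
compute_titration <- function(oxidized, reduced) {
  dn <- summary_index_mean(reduced, "nadh") - summary_index_mean(oxidized, "nadh")
  df <- summary_index_mean(oxidized, "fp") - summary_index_mean(reduced, "fp")
  inverted <- c(nadh = dn < 0, fp = df < 0)
  if (any(inverted)) {
    warning("negative dynamic range (physiologically inverted): ",
            paste(names(inverted)[inverted], collapse = ", "), call. = FALSE)
  }
  structure(list(delta_nadh = dn, delta_fp = df, inverted = inverted,
                 oxidized = oxidized, reduced = reduced),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf("<titration> delta NADH = %.4g a.u., delta Fp = %.4g a.u.%s\n",
              x$delta_nadh, x$delta_fp,
              if (any(x$inverted)) " [inverted]" else ""))
  invisible(x)
}

#' Percent change of a treated titration relative to control
#'
#' `100 * (treated - control) / control` for each dynamic range, the form
#' used to report e.g. an oxidant-induced contraction of the NADH dynamic
#' range.
#'
#' @param control,treated `titration_result` objects.
#' @return Named numeric vector `c(delta_nadh_pct, delta_fp_pct)`.
#' @export
titration_percent_change <- function(control, treated) {
  stopifnot(inherits(control, "titration_result"),
            inherits(treated, "titration_result"))
  c(delta_nadh_pct = 100 * (treated$delta_nadh - control$delta_nadh) /
      control$delta_nadh,
    delta_fp_pct = 100 * (treated$delta_fp - control$delta_fp) /
      control$delta_fp)
}

#' Ratiometric lipid peroxidation index for one field of view
#'
#' Quantifies the green and red channels of the lipid peroxidation sensor
#' with the same background-subtraction and SNR-threshold machinery as the
#' ORI channels (ORI threshold), and reports the green/red ratio of masked
#' channel means. The index rises when green rises and/or red falls
#' (more peroxidation), and is invariant to a common multiplicative gain on
#' both channels.
#'
#' @param green,red [channel_image]s of the sensor channels, same FOV.
#' @param background_rois ROI spec or named list (`lipid_green`,
#'   `lipid_red`), as in [quantify_fov()].
#' @param policy A [threshold_policy()].
#' @return A `lipid_perox_result`: list with `green_mean`, `red_mean`,
#'   `index` (green/red), pixel counts, and `fov_id`; `NULL` fields and a
#'   warning when a mask is empty.
#' @export
lipid_peroxidation_index <- function(green, red, background_rois,
                                     policy = threshold_policy()) {
  stopifnot(is_channel_image(green), is_channel_image(red))
  if (green$channel != "lipid_green" || red$channel != "lipid_red") {
    stop("expected 'lipid_green' and 'lipid_red' channel images",
         call. = FALSE)
  }
  if (!all(dim(green$pixels) == dim(red$pixels))) {
    stop("green and red images must be the same FOV (same dimensions)",
         call. = FALSE)
  }
  roi_for <- function(ch) {
    if (is.list(background_rois) && !is.null(names(background_rois)) &&
        ch %in% names(background_rois)) background_rois[[ch]] else background_rois
  }
  vals <- list()
  for (im in list(green, red)) {
    bg <- estimate_background(im, roi_for(im$channel))
    corr <- subtract_background(im, bg)
    mask <- threshold_mask(corr, snr = policy$ori_snr)
    vals[[im$channel]] <- corr$pixels[mask]
  }
  if (length(vals$lipid_green) == 0 || length(vals$lipid_red) == 0) {
    warning("FOV '", green$fov_id,
            "': empty lipid-sensor mask; index absent", call. = FALSE)
    return(structure(list(fov_id = green$fov_id, green_mean = NA_real_,
                          red_mean = NA_real_, index = NA_real_,
                          n_pixels_green = length(vals$lipid_green),
                          n_pixels_red = length(vals$lipid_red)),
                     class = "lipid_perox_result"))
  }
  gm <- mean(vals$lipid_green)
  rm_ <- mean(vals$lipid_red)
  structure(list(fov_id = green$fov_id, green_mean = gm, red_mean = rm_,
                 index = gm / rm_,
                 n_pixels_green = length(vals$lipid_green),
                 n_pixels_red = length(vals$lipid_red)),
            class = "lipid_perox_result")
}

#' @export
print.lipid_perox_result <- function(x, ...) {
  cat(sprintf("<lipid peroxidation> fov '%s': green %.4g, red %.4g, green/red = %.4g\n",
              x$fov_id, x$green_mean, x$red_mean, x$index))
  invisible(x)
}

#' Aggregate per-FOV lipid peroxidation results
#'
#' Unweighted mean and SD (n-1) across FOVs of the green mean, red mean and
#' green/red index, excluding FOVs with absent values.
#'
#' @param results List of `lipid_perox_result`.
#' @return data.frame with one row per quantity (`green`, `red`, `index`).
#' @export
summarize_lipid <- function(results) {
  stopifnot(length(results) >= 1)
  grab <- function(field) {
    v <- vapply(results, function(r) r[[field]], numeric(1))
    v[is.finite(v)]
  }
  rows <- lapply(c(green = "green_mean", red = "red_mean", index = "index"),
                 grab)
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    v <- rows[[nm]]
    data.frame(quantity = nm, mean = mean(v),
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               n_fovs = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare treatment conditions against a control
#'
#' One-way ANOVA across conditions followed by Dunnett-adjusted many-to-one
#' comparisons against a named reference condition (e.g. caffeine dose 0
#' without oxidant challenge). When a challenge column is supplied (e.g.
#' with/without oxidant), the Dunnett family is formed within the baseline
#' challenge level, and a paired or unpaired t-test contrasts the two
#' challenge levels at each condition.
#'
#' @param data data.frame with columns `condition`, `value`, and optionally
#'   the challenge column.
#' @param reference Control condition label (must exist in `condition`).
#' @param challenge_col Optional name of a two-level challenge column.
#' @param challenge_baseline Baseline level of the challenge column
#'   (defaults to the first sorted level).
#' @param paired Whether the per-condition challenge contrast is paired
#'   (replicates matched by order).
#' @param ndraws,seed Monte-Carlo settings passed to [dunnett()].
#' @return List with `anova` (`redox_test`), `dunnett` (data.frame), and
#'   `challenge` (data.frame of per-condition t-tests, or `NULL`).
#' @export
compare_conditions <- function(data, reference, challenge_col = NULL,
                               challenge_baseline = NULL, paired = FALSE,
                               ndraws = 1e5, seed = 1L) {
  stopifnot(is.data.frame(data), all(c("condition", "value") %in% names(data)))
  base_rows <- data
  challenge <- NULL
  if (!is.null(challenge_col)) {
    stopifnot(challenge_col %in% names(data))
    lv <- sort(unique(as.character(data[[challenge_col]])))
    if (length(lv) != 2) {
      stop("challenge column must have exactly two levels", call. = FALSE)
    }
    if (is.null(challenge_baseline)) challenge_baseline <- lv[1]
    base_rows <- data[as.character(data[[challenge_col]]) == challenge_baseline, ]
  }
  conds <- unique(as.character(base_rows$condition))
  if (!reference %in% conds) {
    stop("reference condition '", reference, "' not present", call. = FALSE)
  }
  groups <- lapply(conds, function(cn) base_rows$value[base_rows$condition == cn])
  names(groups) <- conds
  small <- lengths(groups) < 2
  if (any(small)) {
    stop("condition(s) with fewer than 2 replicates: ",
         paste(conds[small], collapse = ", "), call. = FALSE)
  }
  av <- anova_oneway(groups)
  dn <- dunnett(groups, control_index = which(conds == reference),
                ndraws = ndraws, seed = seed)
  if (!is.null(challenge_col)) {
    other <- setdiff(sort(unique(as.character(data[[challenge_col]]))),
                     challenge_baseline)
    rows <- lapply(unique(as.character(data$condition)), function(cn) {
      x <- data$value[data$condition == cn &
                        as.character(data[[challenge_col]]) == other]
      y <- data$value[data$condition == cn &
                        as.character(data[[challenge_col]]) == challenge_baseline]
      if (length(x) < 2 || length(y) < 2) return(NULL)
      tt <- t_test(x, y, paired = paired)
      data.frame(condition = cn, estimate = tt$estimate,
                 statistic = tt$statistic, p = tt$p, stars = tt$stars,
                 degenerate = tt$degenerate, stringsAsFactors = FALSE)
    })
    challenge <- do.call(rbind, rows)
    rownames(challenge) <- NULL
  }
  list(anova = av, dunnett = dn, challenge = challenge)
}
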