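#' Parameters for a synthetic fluorescence scene
#'
#' Describes one simulated field of view: macrophage-like bright elliptical
#' cells with NADH/Fp/MitoSOX signal, red-blood-cell-like objects with no
#' mitochondrial signal in any of those channels, and additive homoscedastic
#' Gaussian background of known mean and SD (the "noise" the quantification
#' pipeline must estimate). Default intensity levels are chosen so that
#' quantified FOV means land in realistic ranges for ex vivo macrophages
#' (Fp a few hundred a.u., NADH several hundred a.u.).
#'
#' @param image_height_px,image_width_px Scene dimensions (>= 32).
#' @param pixel_size_um Pixel edge length (um).
#' @param n_macrophages,n_rbc Object counts.
#' @param cell_radius_px Length-2 range of ellipse semi-axes (px).
#' @param nadh_level,fp_level,mitosox_level Mean per-cell intensity above
#'   background (a.u.) for macrophages.
#' @param lipid_green_level,lipid_red_level Per-cell levels for the lipid
#'   peroxidation sensor channels (used only when those channels are
#'   requested).
#' @param intracell_cv Coefficient of variation of the multiplicative
#'   lognormal within-cell texture.
#' @param bg_mean Background mean (a.u.).
#' @param bg_sd Background SD (a.u., > 0).
#' @param border_px Width of the guaranteed cell-free margin used as the
#'   background ROI.
#' @param channels Channels to render (subset of [ORI_CHANNELS]).
#' @param seed Integer seed; identical parameters (including seed) yield
#'   bit-identical scenes.
#' @return A `scene_params` list.
#' @export
scene_params <- function(image_height_px = 512, image_width_px = 512,
                         pixel_size_um = 0.293,
                         n_macrophages = 15, n_rbc = 3,
                         cell_radius_px = c(10, 18),
                         nadh_level = 600, fp_level = 350,
                         mitosox_level = 300,
                         lipid_green_level = 300, lipid_red_level = 300,
                         intracell_cv = 0.2,
                         bg_mean = 100, bg_sd = 8,
                         border_px = 32,
                         channels = c("nadh", "fp", "mitosox"),
                         seed = 1L) {
  stopifnot(image_height_px >= 32, image_width_px >= 32,
            pixel_size_um > 0, n_macrophages >= 0, n_rbc >= 0,
            length(cell_radius_px) == 2, all(cell_radius_px > 0),
            cell_radius_px[1] <= cell_radius_px[2],
            nadh_level >= 0, fp_level >= 0, mitosox_level >= 0,
            lipid_green_level >= 0, lipid_red_level >= 0,
            intracell_cv >= 0, bg_mean >= 0, bg_sd > 0, border_px >= 0)
  channels <- match.arg(channels, ORI_CHANNELS, several.ok = TRUE)
  structure(
    list(image_height_px = as.integer(image_height_px),
         image_width_px = as.integer(image_width_px),
         pixel_size_um = pixel_size_um,
         n_macrophages = as.integer(n_macrophages),
         n_rbc = as.integer(n_rbc),
         cell_radius_px = cell_radius_px,
         nadh_level = nadh_level, fp_level = fp_level,
         mitosox_level = mitosox_level,
         lipid_green_level = lipid_green_level,
         lipid_red_level = lipid_red_level,
         intracell_cv = intracell_cv,
         bg_mean = bg_mean, bg_sd = bg_sd,
         border_px = as.integer(border_px),
         channels = channels, seed = as.integer(seed)),
    class = "scene_params")
}

level_for_channel <- function(params, ch, type) {
  if (type == "rbc") return(0)
  switch(ch,
         nadh = params$nadh_level, fp = params$fp_level,
         mitosox = params$mitosox_level,
         lipid_green = params$lipid_green_level,
         lipid_red = params$lipid_red_level)
}

# Place elliptical cells fully inside the image, outside the border margin.
# Overlap is permitted; each pixel belongs to the first-placed cell.
place_cells <- function(params) {
  h <- params$image_height_px
  w <- params$image_width_px
  n <- params$n_macrophages + params$n_rbc
  labels <- matrix(0L, h, w)
  cells <- data.frame(cell = integer(0), type = character(0),
                      cx = numeric(0), cy = numeric(0),
                      rx = numeric(0), ry = numeric(0))
  if (n == 0) return(list(labels = labels, cells = cells))
  rmax <- params$cell_radius_px[2]
  lo <- params$border_px + rmax + 1
  hi_r <- h - params$border_px - rmax
  hi_c <- w - params$border_px - rmax
  if (lo > hi_r || lo > hi_c) {
    stop("cell placement failed: no interior room for radius ", rmax,
         " with a ", params$border_px, " px cell-free border", call. = FALSE)
  }
  types <- c(rep("macrophage", params$n_macrophages), rep("rbc", params$n_rbc))
  row_idx <- matrix(rep(seq_len(h), w), h, w)
  col_idx <- matrix(rep(seq_len(w), each = h), h, w)
  for (k in seq_len(n)) {
    cx <- stats::runif(1, lo, hi_r)
    cy <- stats::runif(1, lo, hi_c)
    rx <- stats::runif(1, params$cell_radius_px[1], params$cell_radius_px[2])
    ry <- stats::runif(1, params$cell_radius_px[1], params$cell_radius_px[2])
    inside <- ((row_idx - cx) / rx)^2 + ((col_idx - cy) / ry)^2 <= 1
    take <- inside & labels == 0L
    labels[take] <- k
    cells <- rbind(cells, data.frame(cell = k, type = types[k],
                                     cx = cx, cy = cy, rx = rx, ry = ry))
  }
  list(labels = labels, cells = cells)
}

#' Generate a synthetic multi-channel field of view with ground truth
#'
#' Every pixel is `bg_mean + N(0, bg_sd)`, plus, inside a macrophage, the
#' channel level multiplied by a lognormal within-cell texture factor with
#' the configured CV (mean 1). RBC-type objects contribute nothing above
#' background in the NADH, Fp and MitoSOX channels (no mitochondria). The
#' border strip of width `border_px` is guaranteed cell-free and is the
#' designated background ROI (see [background_roi()]).
#'
#' Geometry (placement) is driven by `params$seed`; texture and noise by
#' `noise_seed` (defaults to `params$seed`), so scenes with identical
#' geometry but fresh noise can be produced for dose series and titrations.
#'
#' @param params A [scene_params()].
#' @param noise_seed Seed for texture and background noise.
#' @return A `redox_scene`: list with `channels` (named list of
#'   [channel_image]), `truth` (list with `labels` matrix and `cells`
#'   data.frame holding per-cell type and true per-channel means above
#'   background), `params`, and `scene_id`.
#' @examples
#' sc <- generate_scene(scene_params(n_macrophages = 2, seed = 1))
#' names(sc$channels)
#' @export
generate_scene <- function(params, noise_seed = params$seed) {
  stopifnot(inherits(params, "scene_params"))
  placement <- with_seed(params$seed, place_cells(params))
  h <- params$image_height_px
  w <- params$image_width_px
  npx <- h * w
  labels <- placement$labels
  cells <- placement$cells

  truth_cells <- cells
  for (ch in c("nadh", "fp", "mitosox")) {
    truth_cells[[ch]] <- if (nrow(cells)) {
      vapply(seq_len(nrow(cells)),
             function(k) level_for_channel(params, ch, cells$type[k]),
             numeric(1))
    } else numeric(0)
  }

  cv <- params$intracell_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -0.5 * log(1 + cv^2)  # lognormal with mean exactly 1

  channels <- with_seed(noise_seed, {
    out <- list()
    for (ch in params$channels) {
      px <- matrix(params$bg_mean + stats::rnorm(npx, 0, params$bg_sd), h, w)
      for (k in seq_len(nrow(cells))) {
        lvl <- level_for_channel(params, ch, cells$type[k])
        idx <- which(labels == k)
        if (lvl > 0 && length(idx) > 0) {
          tex <- if (cv > 0) stats::rlnorm(length(idx), meanlog, sdlog) else 1
          px[idx] <- px[idx] + lvl * tex
        }
      }
      out[[ch]] <- channel_image(pmax(px, 0), ch, params$pixel_size_um,
                                 fov_id = sprintf("scene%d", params$seed))
    }
    out
  })

  structure(list(channels = channels,
                 truth = list(labels = labels, cells = truth_cells),
                 params = params,
                 scene_id = sprintf("scene%d", params$seed)),
            class = "redox_scene")
}

#' @export
print.redox_scene <- function(x, ...) {
  cat(sprintf("<redox_scene> '%s': %d x %d px, %d macrophage(s), %d RBC(s), channels: %s\n",
              x$scene_id, x$params$image_height_px, x$params$image_width_px,
              x$params$n_macrophages, x$params$n_rbc,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Background ROI of a synthetic scene
#'
#' Returns the guaranteed cell-free border strip of a generated scene as a
#' logical mask, suitable for [estimate_background()] / [quantify_fov()].
#'
#' @param scene A `redox_scene`.
#' @return Logical matrix, `TRUE` on the border strip.
#' @export
background_roi <- function(scene) {
  stopifnot(inherits(scene, "redox_scene"))
  b <- scene$params$border_px
  h <- scene$params$image_height_px
  w <- scene$params$image_width_px
  m <- matrix(FALSE, h, w)
  if (b > 0) {
    m[c(seq_len(b), (h - b + 1):h), ] <- TRUE
    m[, c(seq_len(b), (w - b + 1):w)] <- TRUE
  }
  m
}

#' Linear dose model for oxidant challenge
#'
#' Expected per-cell channel means above background as linear functions of
#' oxidant dose: NADH decreases (negative slope) and Fp increases (positive
#' slope) as progressive oxidant additions shift mitochondria to a more
#' oxidized state. Expected levels are clamped at zero (physical
#' nonnegativity).
#'
#' @param nadh_intercept,nadh_slope NADH line (slope must be negative).
#' @param fp_intercept,fp_slope Fp line (slope must be positive).
#' @return A `dose_model` list with function `level(channel, dose)`.
#' @export
dose_model <- function(nadh_intercept = 600, nadh_slope = -100,
                       fp_intercept = 300, fp_slope = 50) {
  stopifnot(nadh_slope < 0, fp_slope > 0,
            nadh_intercept >= 0, fp_intercept >= 0)
  structure(list(nadh_intercept = nadh_intercept, nadh_slope = nadh_slope,
                 fp_intercept = fp_intercept, fp_slope = fp_slope),
            class = "dose_model")
}

dose_level <- function(model, channel, dose) {
  v <- switch(channel,
              nadh = model$nadh_intercept + model$nadh_slope * dose,
              fp = model$fp_intercept + model$fp_slope * dose)
  pmax(v, 0)
}

#' Generate a serial-addition oxidant dose series
#'
#' One scene per dose, all sharing the cell geometry of `base` (same
#' placement seed) with fresh noise and texture per dose. Per-cell expected
#' NADH and Fp follow the linear [dose_model()], clamped at zero.
#'
#' @param base A [scene_params()] (its `nadh_level`/`fp_level` are replaced
#'   by the dose model's values at each dose).
#' @param model A [dose_model()].
#' @param doses Nonnegative doses, sorted ascending (e.g. mM of oxidant).
#' @return List of elements `list(dose, scene)`, one per dose.
#' @export
generate_dose_series <- function(base, model, doses) {
  stopifnot(inherits(base, "scene_params"), inherits(model, "dose_model"))
  if (length(doses) == 0) stop("empty dose list", call. = FALSE)
  if (any(doses < 0)) stop("doses must be nonnegative", call. = FALSE)
  if (is.unsorted(doses)) {
    stop("doses must be sorted ascending (serial addition)", call. = FALSE)
  }
  lapply(seq_along(doses), function(i) {
    d <- doses[i]
    p <- base
    p$nadh_level <- dose_level(model, "nadh", d)
    p$fp_level <- dose_level(model, "fp", d)
    sc <- generate_scene(p, noise_seed = base$seed + 1000L * i)
    sc$scene_id <- sprintf("%s_dose%g", sc$scene_id, d)
    list(dose = d, scene = sc)
  })
}

#' Generate a redox-titration scene pair (oxidized vs reduced extreme)
#'
#' Two scenes with identical geometry representing the two metabolic
#' modulation extremes: the uncoupled state (FCCP; NADH fully oxidized to
#' NAD+, low NADH and high Fp) and the inhibited state (rotenone +
#' antimycin A; NADH buildup, high NADH and low Fp). The preconditions
#' `reduced_nadh >= oxidized_nadh` and `oxidized_fp >= reduced_fp` enforce
#' the physiological ordering.
#'
#' @param base A [scene_params()].
#' @param oxidized_nadh,oxidized_fp Per-cell levels in the uncoupled state.
#' @param reduced_nadh,reduced_fp Per-cell levels in the inhibited state.
#' @return List with `oxidized` and `reduced` scenes (identical label
#'   images, fresh noise each).
#' @export
generate_titration_pair <- function(base, oxidized_nadh = 300,
                                    oxidized_fp = 500,
                                    reduced_nadh = 700, reduced_fp = 250) {
  stopifnot(inherits(base, "scene_params"))
  if (reduced_nadh < oxidized_nadh || oxidized_fp < reduced_fp) {
    stop("inverted titration extremes: require reduced_nadh >= oxidized_nadh ",
         "and oxidized_fp >= reduced_fp", call. = FALSE)
  }
  p_ox <- base
  p_ox$nadh_level <- oxidized_nadh
  p_ox$fp_level <- oxidized_fp
  p_red <- base
  p_red$nadh_level <- reduced_nadh
  p_red$fp_level <- reduced_fp
  ox <- generate_scene(p_ox, noise_seed = base$seed + 101L)
  red <- generate_scene(p_red, noise_seed = base$seed + 202L)
  ox$scene_id <- paste0(ox$scene_id, "_oxidized")
  red$scene_id <- paste0(red$scene_id, "_reduced")
  list(oxidized = ox, reduced = red)
}

#' Cohort effect specification for [generate_cohort()]
#'
#' Linear relations between clinical covariates and the "true" imaging
#' indices, plus noise levels and the between-preparation (A vs B)
#' relation. Defaults emulate a ventilated-preterm cohort: NADH rises with
#' gestational age and falls with mean airway pressure; Fp co-varies with
#' NADH; group B (DTT-released) indices equal group A up to a configurable
#' linear map plus noise.
#'
#' @param nadh_base,fp_base,mitosox_base Index levels (a.u.) at the
#'   reference covariate values.
#' @param ga_nadh_slope a.u. of NADH per week of gestational age.
#' @param map_nadh_slope a.u. of NADH per cmH2O of mean airway pressure.
#' @param fp_per_nadh Fp a.u. per a.u. of (NADH - nadh_base).
#' @param noise_sd Between-patient index noise SD (a.u.).
#' @param fov_sd Within-sample between-FOV SD (a.u.).
#' @param n_fovs FOVs simulated per sample.
#' @param ab_slope,ab_offset,ab_noise_sd Group B = ab_slope * A + ab_offset
#'   + N(0, ab_noise_sd).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(nadh_base = 600, fp_base = 350, mitosox_base = 300,
                        ga_nadh_slope = 40, map_nadh_slope = -20,
                        fp_per_nadh = 0.4, noise_sd = 60,
                        fov_sd = 50, n_fovs = 5L,
                        ab_slope = 1, ab_offset = 0, ab_noise_sd = 20) {
  stopifnot(noise_sd >= 0, fov_sd >= 0, n_fovs >= 1, ab_noise_sd >= 0)
  structure(list(nadh_base = nadh_base, fp_base = fp_base,
                 mitosox_base = mitosox_base,
                 ga_nadh_slope = ga_nadh_slope,
                 map_nadh_slope = map_nadh_slope,
                 fp_per_nadh = fp_per_nadh, noise_sd = noise_sd,
                 fov_sd = fov_sd, n_fovs = as.integer(n_fovs),
                 ab_slope = ab_slope, ab_offset = ab_offset,
                 ab_noise_sd = ab_noise_sd),
            class = "effect_spec")
}

#' Generate a synthetic clinical cohort with paired imaging indices
#'
#' Simulates `n_patients` ventilated infants: gestational age (GA),
#' postmenstrual age at sampling (PMA = GA + chronologic age), FiO2 (%),
#' ventilator mean airway pressure (MAP), and per-patient "true" imaging
#' indices (NADH, Fp, redox ratio, MitoSOX) following the linear relations
#' in `spec` with additive Gaussian noise. Both preparations are produced:
#' group A (loose cells) and group B (DTT-released), with
#' `B = ab_slope * A + ab_offset + noise` per index. Each sample summary
#' carries `n_fovs` simulated FOV means.
#'
#' @param n_patients Number of patients (>= 3).
#' @param spec An [effect_spec()].
#' @param seed Integer seed.
#' @param ga_range,age_range,fio2_range,map_range Uniform sampling ranges
#'   for GA (weeks), chronologic age (weeks), FiO2 (%), MAP (cmH2O).
#' @return List with `clinical` (data.frame patient_id/ga_weeks/pma_weeks/
#'   fio2_pct/map/rss), `summaries` (tidy data.frame as [summaries_df()]),
#'   and `truth` (per-patient true group-A index values).
#' @export
generate_cohort <- function(n_patients = 17, spec = effect_spec(), seed = 1L,
                            ga_range = c(23.4, 38.3), age_range = c(9, 35),
                            fio2_range = c(21, 100), map_range = c(9, 29)) {
  stopifnot(inherits(spec, "effect_spec"))
  if (n_patients < 3) stop("n_patients must be >= 3", call. = FALSE)
  with_seed(seed, {
    ids <- sprintf("p-%d", seq_len(n_patients))
    ga <- stats::runif(n_patients, ga_range[1], ga_range[2])
    pma <- ga + stats::runif(n_patients, age_range[1], age_range[2])
    fio2 <- stats::runif(n_patients, fio2_range[1], fio2_range[2])
    map <- stats::runif(n_patients, map_range[1], map_range[2])
    clinical <- data.frame(patient_id = ids, ga_weeks = ga, pma_weeks = pma,
                           fio2_pct = fio2, map = map,
                           rss = round_half_up(fio2 * map / 100, 1),
                           stringsAsFactors = FALSE)

    ga_ref <- mean(ga_range)
    map_ref <- mean(map_range)
    nadh_a <- spec$nadh_base + spec$ga_nadh_slope * (ga - ga_ref) +
      spec$map_nadh_slope * (map - map_ref) +
      stats::rnorm(n_patients, 0, spec$noise_sd)
    nadh_a <- pmax(nadh_a, 1)
    fp_a <- pmax(spec$fp_base + spec$fp_per_nadh * (nadh_a - spec$nadh_base) +
                   stats::rnorm(n_patients, 0, spec$noise_sd / 2), 1)
    mito_a <- pmax(spec$mitosox_base + stats::rnorm(n_patients, 0, spec$noise_sd),
                   1)
    truth <- data.frame(patient_id = ids, nadh = nadh_a, fp = fp_a,
                        mitosox = mito_a,
                        redox_ratio = fp_a / (nadh_a + fp_a),
                        stringsAsFactors = FALSE)

    make_group <- function(vals, grp) {
      rows <- list()
      for (i in seq_len(n_patients)) {
        for (ix in c("nadh", "fp", "mitosox", "redox_ratio")) {
          mu <- vals[[ix]][i]
          fsd <- if (ix == "redox_ratio") spec$fov_sd * 1e-4 else spec$fov_sd
          fov_means <- mu + stats::rnorm(spec$n_fovs, 0, fsd)
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = ids[i], group = grp, index = ix,
            mean = mean(fov_means),
            sd = if (spec$n_fovs >= 2) stats::sd(fov_means) else NA_real_,
            n_fovs = spec$n_fovs, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    }

    vals_b <- truth
    for (ix in c("nadh", "fp", "mitosox")) {
      vals_b[[ix]] <- pmax(spec$ab_slope * truth[[ix]] + spec$ab_offset +
                             stats::rnorm(n_patients, 0, spec$ab_noise_sd), 1)
    }
    vals_b$redox_ratio <- vals_b$fp / (vals_b$nadh + vals_b$fp)

    summaries <- rbind(make_group(truth, "A"), make_group(vals_b, "B"))
    list(clinical = clinical, summaries = summaries, truth = truth)
  })
}
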