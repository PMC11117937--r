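# Independent per-pixel reference implementation of the FOV quantification,
# written as plain scalar loops over explicit sums. Used only as an oracle
# against quantify_fov(); deliberately shares no code with the package path.

ref_mean <- function(v) sum(v) / length(v)
ref_sd <- function(v) {
  m <- ref_mean(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

ref_quantify <- function(pixels, roi_idx, ori_snr = 7.5, mitosox_snr = 5) {
  corrected <- list()
  masks <- list()
  for (ch in names(pixels)) {
    px <- pixels[[ch]]
    bgv <- px[roi_idx]
    bg_mean <- ref_mean(bgv)
    bg_sd <- ref_sd(bgv)
    snr <- if (ch == "mitosox") mitosox_snr else ori_snr
    corr <- matrix(0, nrow(px), ncol(px))
    mask <- matrix(FALSE, nrow(px), ncol(px))
    for (i in seq_len(nrow(px))) {
      for (j in seq_len(ncol(px))) {
        v <- px[i, j] - bg_mean
        if (v < 0) v <- 0
        corr[i, j] <- v
        if (v >= snr * bg_sd) mask[i, j] <- TRUE
      }
    }
    corrected[[ch]] <- corr
    masks[[ch]] <- mask
  }
  out <- list()
  for (ch in names(pixels)) {
    v <- corrected[[ch]][masks[[ch]]]
    if (length(v) > 0) {
      out[[ch]] <- c(mean = ref_mean(v), sd = ref_sd(v), n = length(v))
    }
  }
  if (all(c("nadh", "fp") %in% names(pixels))) {
    ratios <- c()
    for (i in seq_len(nrow(pixels$nadh))) {
      for (j in seq_len(ncol(pixels$nadh))) {
        if (masks$nadh[i, j] && masks$fp[i, j]) {
          f <- corrected$fp[i, j]
          n <- corrected$nadh[i, j]
          ratios <- c(ratios, f / (n + f))
        }
      }
    }
    if (length(ratios) > 0) {
      out$redox_ratio <- c(mean = ref_mean(ratios), sd = ref_sd(ratios),
                           n = length(ratios))
    }
  }
  out
}

# Small scene parameterisations reused across tests.
tiny_params <- function(seed, ...) {
  scene_params(image_height_px = 64, image_width_px = 64, border_px = 8,
               n_macrophages = 3, n_rbc = 1, cell_radius_px = c(4, 7),
               seed = seed, ...)
}

recovery_params <- function(seed, ...) {
  scene_params(image_height_px = 256, image_width_px = 256,
               n_macrophages = 8, cell_radius_px = c(8, 14), n_rbc = 1,
               nadh_level = 600, fp_level = 300, intracell_cv = 0.1,
               bg_mean = 100, bg_sd = 15, seed = seed, ...)
}

# Closed-form OLS via the normal equations, independent of stats::lm.
ref_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx * sx)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  ssr <- sum((y - yhat)^2)
  sst <- sum((y - sy / n)^2)
  se <- sqrt(ssr / (n - 2) / sum((x - sx / n)^2))
  tstat <- slope / se
  list(slope = slope, intercept = intercept, r_squared = 1 - ssr / sst,
       slope_p = 2 * stats::pt(-abs(tstat), n - 2))
}
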