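# Half-up rounding for display (round() rounds half to even, which does not
# reproduce printed clinical scores like 35% x 17 cmH2O -> 6.0).
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Respiratory severity score
#'
#' RSS = (FiO2% / 100) x mean airway pressure. Computed multiply-first
#' (`fio2 * map / 100`) so that the 1-decimal display rounding of products
#' of printed table values is exact.
#'
#' @param fio2_pct Fraction of inspired oxygen, in percent (21-100).
#' @param map Ventilator mean airway pressure (cmH2O, > 0).
#' @param digits Display rounding (`NULL` for full precision).
#' @return Numeric RSS.
#' @export
rss_score <- function(fio2_pct, map, digits = NULL) {
  v <- fio2_pct * map / 100
  if (!is.null(digits)) v <- round_half_up(v, digits)
  v
}

validate_clinical_row <- function(row) {
  problems <- character(0)
  if (!is.finite(row$ga_weeks) || row$ga_weeks <= 0) {
    problems <- c(problems, "ga_weeks must be a positive number")
  }
  if (!is.finite(row$pma_weeks) || row$pma_weeks <= 0) {
    problems <- c(problems, "pma_weeks must be a positive number")
  } else if (is.finite(row$ga_weeks) && row$pma_weeks < row$ga_weeks) {
    problems <- c(problems, "pma_weeks < ga_weeks (PMA = GA + chronologic age)")
  }
  if (!is.finite(row$fio2_pct) || row$fio2_pct < 21 || row$fio2_pct > 100) {
    problems <- c(problems, "fio2_pct must lie in [21, 100]")
  }
  if (!is.finite(row$map) || row$map <= 0) {
    problems <- c(problems, "map must be positive")
  }
  problems
}

#' Load and validate a clinical table
#'
#' Reads a CSV with columns `patient_id, ga_weeks, pma_weeks, fio2_pct, map`
#' and optional `rss`. Every row is validated (positive GA/MAP, PMA >= GA,
#' FiO2 in [21, 100]); all violations are reported together. RSS is always
#' recomputed from FiO2 and MAP; a provided `rss` column is cross-checked
#' against the recomputed value at 1-decimal rounding and any mismatch is
#' an error.
#'
#' @param path CSV path (comment lines starting with `#` are ignored), or a
#'   data.frame with the same columns.
#' @return data.frame of validated records with `rss` (full precision) and
#'   `rss_display` (1-decimal half-up) columns.
#' @examples
#' tab <- load_clinical(system.file("extdata", "clinical_table.csv",
#'                                  package = "redoximg"))
#' head(tab)
#' @export
load_clinical <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("patient_id", "ga_weeks", "pma_weeks", "fio2_pct", "map")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("clinical table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  errs <- character(0)
  for (i in seq_len(nrow(df))) {
    p <- validate_clinical_row(df[i, ])
    if (length(p)) {
      errs <- c(errs, sprintf("row %d (%s): %s", i, df$patient_id[i],
                              paste(p, collapse = "; ")))
    }
  }
  if (length(errs)) {
    stop("invalid clinical records:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  rss_full <- rss_score(df$fio2_pct, df$map)
  rss_disp <- round_half_up(rss_full, 1)
  if ("rss" %in% names(df)) {
    bad <- which(abs(df$rss - rss_disp) > 1e-9)
    if (length(bad)) {
      stop("provided RSS disagrees with recomputed FiO2 x MAP / 100 for: ",
           paste(df$patient_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  df$rss <- rss_full
  df$rss_display <- rss_disp
  df
}

index_table <- function(summaries, group, index) {
  stopifnot(is.data.frame(summaries))
  rows <- summaries[summaries$index == index, , drop = FALSE]
  if (group %in% c("A", "B", "cell_line")) {
    rows <- rows[rows$group == group, , drop = FALSE]
    stats::setNames(rows$mean, rows$sample_id)
  } else if (group == "averaged") {
    av <- average_preparations(summaries)
    rows <- av[av$index == index, , drop = FALSE]
    stats::setNames(rows$mean, rows$sample_id)
  } else {
    stop("unknown group '", group, "'", call. = FALSE)
  }
}

clinical_or_index <- function(name, records, summaries, group) {
  clin_vars <- c("ga_weeks", "pma_weeks", "fio2_pct", "map", "rss")
  if (name %in% clin_vars) {
    stats::setNames(records[[name]], records$patient_id)
  } else {
    index_table(summaries, group, name)
  }
}

#' Correlate an imaging index with a clinical covariate or another index
#'
#' Simple linear regression of `y` on `x`, paired by patient id, for one
#' preparation group (`"A"`, `"B"`) or the A/B-averaged indices
#' (`"averaged"`). Patients missing either variable are dropped with a
#' message (samples can be excluded, e.g. for abnormally high fluorescence
#' background). Variables are named by clinical column (`ga_weeks`,
#' `pma_weeks`, `fio2_pct`, `map`, `rss`) or imaging index (`nadh`, `fp`,
#' `redox_ratio`, `mitosox`).
#'
#' @param records Validated clinical data.frame from [load_clinical()].
#' @param summaries Tidy sample-summary data.frame (see [summaries_df()]).
#' @param x,y Variable names as above.
#' @param group `"A"`, `"B"` or `"averaged"`.
#' @return A `regression_result` (see [linregress()]).
#' @export
correlate <- function(records, summaries, x, y, group = "A") {
  xv <- clinical_or_index(x, records, summaries, group)
  yv <- clinical_or_index(y, records, summaries, group)
  ids <- intersect(names(xv), names(yv))
  dropped <- length(union(names(xv), names(yv))) - length(ids)
  if (dropped > 0) {
    message(dropped, " patient(s) lacked one of '", x, "'/'", y,
            "' and were dropped")
  }
  if (length(ids) < 3) {
    stop("fewer than 3 complete pairs for ", x, " vs ", y, call. = FALSE)
  }
  linregress(unname(xv[ids]), unname(yv[ids]), x_name = x, y_name = y)
}

#' Compare the two cell-preparation groups (loose vs DTT-released)
#'
#' For each imaging index present in both groups: a paired t-test across
#' patients having both preparations, per-patient percent differences
#' `delta_pct = 100 * (B - A) / A` (direction pinned: swapping A and B is
#' not a sign flip), and an OLS regression of B on A with slope and
#' intercept. Patients present in only one group are excluded from pairing
#' but retained in that group's own outputs.
#'
#' @param summaries Tidy sample-summary data.frame with groups `"A"` and
#'   `"B"` (see [summaries_df()] or [generate_cohort()]).
#' @return List with `paired_tests` (data.frame per index), `deltas`
#'   (data.frame patient_id/index/delta_pct), and `regressions` (data.frame
#'   per index: slope, intercept, r_squared, slope_p, n).
#' @export
compare_preparations <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  idxs <- intersect(unique(summaries$index[summaries$group == "A"]),
                    unique(summaries$index[summaries$group == "B"]))
  if (length(idxs) == 0) stop("no index present in both groups", call. = FALSE)
  tests <- list()
  deltas <- list()
  regs <- list()
  for (ix in idxs) {
    a <- index_table(summaries, "A", ix)
    b <- index_table(summaries, "B", ix)
    ids <- intersect(names(a), names(b))
    if (length(ids) < 3) {
      stop("fewer than 3 patients present in both groups for '", ix, "'",
           call. = FALSE)
    }
    av <- unname(a[ids])
    bv <- unname(b[ids])
    tt <- t_test(bv, av, paired = TRUE)
    tests[[ix]] <- data.frame(index = ix, statistic = tt$statistic,
                              df = tt$df, p = tt$p, degenerate = tt$degenerate,
                              n_pairs = length(ids), stringsAsFactors = FALSE)
    ok <- av > 0
    deltas[[ix]] <- data.frame(patient_id = ids[ok], index = ix,
                               delta_pct = 100 * (bv[ok] - av[ok]) / av[ok],
                               stringsAsFactors = FALSE)
    r <- if (stats::sd(av) == 0) NULL else
      linregress(av, bv, x_name = paste0(ix, "_A"), y_name = paste0(ix, "_B"))
    if (!is.null(r)) {
      regs[[ix]] <- cbind(data.frame(index = ix, stringsAsFactors = FALSE),
                          as.data.frame(r)[c("slope", "intercept",
                                             "r_squared", "slope_p", "n")])
    }
  }
  out <- list(paired_tests = do.call(rbind, tests),
              deltas = do.call(rbind, deltas),
              regressions = if (length(regs)) do.call(rbind, regs) else NULL)
  rownames(out$paired_tests) <- NULL
  rownames(out$deltas) <- NULL
  if (!is.null(out$regressions)) rownames(out$regressions) <- NULL
  out
}

#' Average the two preparations into one value per patient
#'
#' Arithmetic mean of the group A and group B index values per patient;
#' when only one preparation exists the single value is passed through and
#' flagged (`averaged = FALSE`).
#'
#' @param summaries Tidy sample-summary data.frame with groups `"A"`/`"B"`.
#' @return Tidy data.frame with `sample_id`, `group = "averaged"`, `index`,
#'   `mean`, `averaged` flag, and `n_groups`.
#' @export
average_preparations <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  rows <- list()
  for (ix in unique(summaries$index)) {
    a <- index_table(summaries[summaries$group == "A", , drop = FALSE], "A", ix)
    b <- index_table(summaries[summaries$group == "B", , drop = FALSE], "B", ix)
    ids <- union(names(a), names(b))
    for (id in ids) {
      has_a <- id %in% names(a)
      has_b <- id %in% names(b)
      m <- mean(c(if (has_a) a[[id]], if (has_b) b[[id]]))
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = id, group = "averaged", index = ix, mean = m,
        averaged = has_a && has_b, n_groups = has_a + has_b,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!out$averaged)) {
    message(sum(!out$averaged),
            " (patient, index) value(s) had a single preparation and were ",
            "passed through unaveraged")
  }
  out
}

#' Regression table across clinical covariates and imaging indices
#'
#' Convenience wrapper running [correlate()] over a grid of x/y pairs and
#' returning a tidy table. No multiple-testing correction is applied across
#' this family (matching common practice for exploratory clinical
#' correlation panels); a Benjamini-Hochberg adjusted column is emitted
#' alongside as a clearly-labelled diagnostic.
#'
#' @param records Validated clinical data.frame.
#' @param summaries Tidy sample-summary data.frame.
#' @param xs,ys Character vectors of variable names.
#' @param group `"A"`, `"B"` or `"averaged"`.
#' @return data.frame with one row per (x, y) pair, including `slope_p`
#'   (uncorrected) and `bh_adjusted_p` (diagnostic only).
#' @export
correlation_table <- function(records, summaries,
                              xs = c("ga_weeks", "map"),
                              ys = c("nadh", "fp", "redox_ratio", "mitosox"),
                              group = "averaged") {
  rows <- list()
  for (x in xs) for (y in ys) {
    r <- tryCatch(correlate(records, summaries, x, y, group),
                  error = function(e) NULL)
    if (!is.null(r)) rows[[length(rows) + 1]] <- as.data.frame(r)
  }
  out <- do.call(rbind, rows)
  out$stars <- p_stars(out$slope_p)
  out$bh_adjusted_p <- stats::p.adjust(out$slope_p, method = "BH")
  rownames(out) <- NULL
  out
}
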