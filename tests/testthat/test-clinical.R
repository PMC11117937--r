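clinical_path <- function() {
  system.file("extdata", "clinical_table.csv", package = "redoximg")
}

test_that("RSS recomputation reproduces every printed cohort value", {
  raw <- read.csv(clinical_path(), comment.char = "#")
  recomputed <- rss_score(raw$fio2_pct, raw$map, digits = 1)
  expect_identical(nrow(raw), 17L)
  expect_equal(recomputed, raw$rss, tolerance = 1e-12)
  # the half-up edge case: 35% x 17 cmH2O prints 6.0, not 5.9
  expect_equal(rss_score(35, 17, digits = 1), 6.0)
  tab <- load_clinical(clinical_path())
  expect_equal(tab$rss_display, raw$rss, tolerance = 1e-12)
})

test_that("clinical validation aggregates per-row violations", {
  bad <- data.frame(patient_id = c("x1", "x2", "x3"),
                    ga_weeks = c(30, 28, 25),
                    pma_weeks = c(25, 40, 50),   # x1: PMA < GA
                    fio2_pct = c(30, 15, 40),    # x2: FiO2 below 21
                    map = c(10, 12, 0))          # x3: MAP not positive
  err <- tryCatch(load_clinical(bad), error = function(e) conditionMessage(e))
  expect_match(err, "x1.*pma_weeks < ga_weeks")
  expect_match(err, "x2.*fio2_pct")
  expect_match(err, "x3.*map must be positive")
  expect_error(load_clinical(data.frame(patient_id = "a")), "lacks column")
  mismatch <- data.frame(patient_id = "y", ga_weeks = 25, pma_weeks = 40,
                         fio2_pct = 50, map = 10, rss = 9.9)
  expect_error(load_clinical(mismatch), "disagrees")
})

test_that("correlation is exact on a line and invariant to ordering and scale", {
  co <- generate_cohort(n_patients = 12, seed = 31)
  rec <- co$clinical
  smry <- co$summaries
  # exact line: y built directly from x
  smry_line <- smry
  ga <- setNames(rec$ga_weeks, rec$patient_id)
  sel <- smry_line$index == "nadh" & smry_line$group == "A"
  smry_line$mean[sel] <- 5 * ga[smry_line$sample_id[sel]] + 7
  r <- correlate(rec, smry_line, "ga_weeks", "nadh", "A")
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  expect_equal(r$slope, 5, tolerance = 1e-10)

  r0 <- correlate(rec, smry, "ga_weeks", "nadh", "A")
  perm <- rec[sample(nrow(rec)), ]
  r1 <- correlate(perm, smry, "ga_weeks", "nadh", "A")
  expect_equal(r0$slope, r1$slope, tolerance = 1e-12)
  expect_equal(r0$r_squared, r1$r_squared, tolerance = 1e-12)

  rec2 <- rec
  rec2$ga_weeks <- rec2$ga_weeks * 7  # weeks -> days
  r2 <- correlate(rec2, smry, "ga_weeks", "nadh", "A")
  expect_equal(r2$r_squared, r0$r_squared, tolerance = 1e-12)
  expect_equal(r2$slope, r0$slope / 7, tolerance = 1e-12)
})

test_that("permuted outcomes give uniform slope p-values", {
  co <- generate_cohort(n_patients = 17, seed = 33)
  x <- co$clinical$ga_weeks
  y <- co$truth$nadh
  set.seed(34)
  pvals <- replicate(200, linregress(x, sample(y))$slope_p)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("preparation comparison handles identity, attenuation and missingness", {
  co <- generate_cohort(n_patients = 10, seed = 41)
  base <- co$summaries[co$summaries$group == "A", ]

  # B identical to A: degenerate paired test, zero deltas, slope 1
  bb <- base
  bb$group <- "B"
  cp <- compare_preparations(rbind(base, bb))
  expect_true(all(cp$paired_tests$degenerate))
  expect_true(all(cp$paired_tests$p == 1))
  expect_true(all(cp$deltas$delta_pct == 0))
  expect_equal(cp$regressions$slope,
               rep(1, nrow(cp$regressions)), tolerance = 1e-10)
  expect_equal(cp$regressions$intercept,
               rep(0, nrow(cp$regressions)), tolerance = 1e-8)

  # B = 0.9 A + noise: attenuated slope recovered
  slopes <- vapply(1:20, function(s) {
    cs <- generate_cohort(n_patients = 14,
                          spec = effect_spec(ab_slope = 0.9, ab_offset = 0,
                                             ab_noise_sd = 10),
                          seed = 500 + s)
    cp2 <- compare_preparations(cs$summaries)
    cp2$regressions$slope[cp2$regressions$index == "nadh"]
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.9), 2 * se)

  # a patient missing from B is excluded from pairing
  miss <- rbind(base, bb[bb$sample_id != "p-1", ])
  cp3 <- compare_preparations(miss)
  expect_false("p-1" %in% cp3$deltas$patient_id)
  expect_true(all(cp3$paired_tests$n_pairs == 9))
})

test_that("delta percent direction (B - A) / A is pinned, not symmetric", {
  smry <- rbind(
    data.frame(sample_id = "p", group = "A",
               index = c("nadh", "fp", "mitosox"), mean = c(100, 200, 50),
               sd = NA, n_fovs = 5),
    data.frame(sample_id = "q", group = "A",
               index = c("nadh", "fp", "mitosox"), mean = c(120, 180, 60),
               sd = NA, n_fovs = 5),
    data.frame(sample_id = "r", group = "A",
               index = c("nadh", "fp", "mitosox"), mean = c(90, 210, 40),
               sd = NA, n_fovs = 5))
  smry_b <- smry
  smry_b$group <- "B"
  smry_b$mean <- smry$mean * 1.5
  cp <- compare_preparations(rbind(smry, smry_b))
  expect_true(all(abs(cp$deltas$delta_pct - 50) < 1e-10))
  swapped <- rbind(smry, smry_b)
  swapped$group <- ifelse(swapped$group == "A", "B", "A")
  cp_sw <- compare_preparations(swapped)
  # swapping is not a sign flip: (A - B)/B = -33.3%, not -50%
  expect_true(all(abs(cp_sw$deltas$delta_pct + 100 / 3) < 1e-10))
})

test_that("averaging preparations is consistent with regression on means", {
  co <- generate_cohort(n_patients = 8, seed = 51)
  av <- average_preparations(co$summaries)
  expect_true(all(av$averaged))
  a <- co$summaries[co$summaries$group == "A" & co$summaries$index == "nadh", ]
  b <- co$summaries[co$summaries$group == "B" & co$summaries$index == "nadh", ]
  man <- (setNames(a$mean, a$sample_id)[av$sample_id[av$index == "nadh"]] +
            setNames(b$mean, b$sample_id)[av$sample_id[av$index == "nadh"]]) / 2
  expect_equal(unname(man), av$mean[av$index == "nadh"], tolerance = 1e-12)

  # single-preparation passthrough is flagged
  partial <- co$summaries[!(co$summaries$group == "B" &
                              co$summaries$sample_id == "p-1"), ]
  expect_message(av2 <- average_preparations(partial), "single preparation")
  p1 <- av2[av2$sample_id == "p-1" & av2$index == "nadh", ]
  expect_false(p1$averaged)
  expect_equal(p1$mean, a$mean[a$sample_id == "p-1"], tolerance = 1e-12)

  # regressing on precomputed averages equals correlate(group = "averaged")
  r1 <- correlate(co$clinical, co$summaries, "ga_weeks", "nadh", "averaged")
  avn <- av[av$index == "nadh", ]
  r2 <- linregress(setNames(co$clinical$ga_weeks, co$clinical$patient_id)[avn$sample_id],
                   avn$mean)
  expect_equal(r1$slope, r2$slope, tolerance = 1e-12)
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-12)
})

test_that("correlation tables carry uncorrected and BH-diagnostic p-values", {
  co <- generate_cohort(n_patients = 12, seed = 61)
  tab <- correlation_table(co$clinical, co$summaries, xs = c("ga_weeks", "map"),
                           ys = c("nadh", "fp"), group = "averaged")
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$bh_adjusted_p >= tab$slope_p - 1e-12))
})
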