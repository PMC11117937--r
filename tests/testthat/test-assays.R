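test_that("dose-response fitting is exact on a line and validates input", {
  pts <- data.frame(dose = c(0, 1, 2, 3), value = 2 * c(0, 1, 2, 3) + 1)
  fit <- fit_dose_response(pts, "fp")
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_identical(fit$index, "fp")
  expect_error(fit_dose_response(data.frame(dose = c(1, 1, 1),
                                            value = c(1, 2, 3))),
               "distinct")
  expect_error(fit_dose_response(data.frame(dose = c(0, 1), value = c(1, 2))),
               "distinct")
})

test_that("oxidant series recovers slope signs: NADH down, Fp and ratio up", {
  base <- scene_params(image_height_px = 128, image_width_px = 128,
                       n_macrophages = 6, cell_radius_px = c(6, 10),
                       border_px = 16, seed = 5)
  model <- dose_model(nadh_intercept = 600, nadh_slope = -100,
                      fp_intercept = 300, fp_slope = 50)
  doses <- seq(0, 3.6, length.out = 6)
  series <- generate_dose_series(base, model, doses)
  rows <- lapply(series, function(el) {
    q <- quantify_fov(el$scene$channels, background_roi(el$scene))
    data.frame(dose = el$dose,
               nadh = q$indices$mean[q$indices$index == "nadh"],
               fp = q$indices$mean[q$indices$index == "fp"],
               ratio = q$indices$mean[q$indices$index == "redox_ratio"])
  })
  tab <- do.call(rbind, rows)
  f_n <- fit_dose_response(data.frame(dose = tab$dose, value = tab$nadh), "nadh")
  f_f <- fit_dose_response(data.frame(dose = tab$dose, value = tab$fp), "fp")
  f_r <- fit_dose_response(data.frame(dose = tab$dose, value = tab$ratio),
                           "redox_ratio")
  expect_lt(f_n$slope, 0)
  expect_gt(f_f$slope, 0)
  expect_gt(f_r$slope, 0)
  expect_equal(f_n$slope, -100, tolerance = 0.1)
})

test_that("titration deltas follow the pinned sign convention", {
  mk <- function(nadh, fp) {
    structure(list(sample_id = "s", group = "cell_line",
                   indices = data.frame(index = c("nadh", "fp"),
                                        mean = c(nadh, fp),
                                        sd = NA_real_, n_fovs = 3L)),
              class = "sample_summary")
  }
  same <- compute_titration(mk(400, 300), mk(400, 300))
  expect_equal(same$delta_nadh, 0)
  expect_equal(same$delta_fp, 0)

  tr <- compute_titration(oxidized = mk(300, 500), reduced = mk(700, 250))
  expect_equal(tr$delta_nadh, 400)
  expect_equal(tr$delta_fp, 250)
  # swapping the extremes negates both deltas
  expect_warning(sw <- compute_titration(oxidized = mk(700, 250),
                                         reduced = mk(300, 500)),
                 "inverted")
  expect_equal(sw$delta_nadh, -tr$delta_nadh)
  expect_equal(sw$delta_fp, -tr$delta_fp)

  noin <- mk(400, 300)
  noin$indices <- noin$indices[noin$indices$index == "fp", ]
  expect_error(compute_titration(noin, mk(1, 1)), "missing")
})

test_that("titration on synthetic scenes recovers the generated dynamic range", {
  quant_pair <- function(seed) {
    base <- scene_params(image_height_px = 128, image_width_px = 128,
                         n_macrophages = 6, cell_radius_px = c(6, 10),
                         border_px = 16, seed = seed)
    pair <- generate_titration_pair(base, oxidized_nadh = 300,
                                    oxidized_fp = 500,
                                    reduced_nadh = 700, reduced_fp = 250)
    s_ox <- summarize_sample(
      quantify_fov(pair$oxidized$channels, background_roi(pair$oxidized)),
      "d", "cell_line")
    s_red <- summarize_sample(
      quantify_fov(pair$reduced$channels, background_roi(pair$reduced)),
      "d", "cell_line")
    compute_titration(s_ox, s_red)
  }
  res <- lapply(1:8, quant_pair)
  dn <- vapply(res, function(r) r$delta_nadh, numeric(1))
  se <- sd(dn) / sqrt(length(dn))
  expect_lt(abs(mean(dn) - 400), 3 * se)
})

test_that("percent change between titrations uses the control baseline", {
  mkt <- function(dn, df) {
    structure(list(delta_nadh = dn, delta_fp = df,
                   inverted = c(nadh = FALSE, fp = FALSE)),
              class = "titration_result")
  }
  pc <- titration_percent_change(mkt(400, 100), mkt(288, 376))
  expect_equal(unname(pc["delta_nadh_pct"]), -28)
  expect_equal(unname(pc["delta_fp_pct"]), 276)
})

test_that("lipid peroxidation index behaves ratiometrically", {
  p <- scene_params(image_height_px = 128, image_width_px = 128,
                    n_macrophages = 5, cell_radius_px = c(6, 10),
                    border_px = 16, channels = c("lipid_green", "lipid_red"),
                    lipid_green_level = 300, lipid_red_level = 300, seed = 17)
  sc <- generate_scene(p)
  roi <- background_roi(sc)
  res <- lipid_peroxidation_index(sc$channels$lipid_green,
                                  sc$channels$lipid_red, roi)
  expect_equal(res$index, 1, tolerance = 0.05)

  # common multiplicative gain cancels in the ratio
  gain <- lapply(sc$channels, function(im) {
    channel_image(im$pixels * 3, im$channel, im$pixel_size_um, im$fov_id)
  })
  res_g <- lipid_peroxidation_index(gain$lipid_green, gain$lipid_red, roi)
  expect_equal(res_g$index, res$index, tolerance = 1e-10)

  # oxidized scene: green up, red down -> higher index, directionally
  p_ox <- p
  p_ox$lipid_green_level <- 600
  p_ox$lipid_red_level <- 150
  sc_ox <- generate_scene(p_ox, noise_seed = 18)
  res_ox <- lipid_peroxidation_index(sc_ox$channels$lipid_green,
                                     sc_ox$channels$lipid_red,
                                     background_roi(sc_ox))
  expect_gt(res_ox$green_mean, res$green_mean)
  expect_lt(res_ox$red_mean, res$red_mean)
  expect_gt(res_ox$index, res$index)
  expect_equal(res_ox$index, 4 * res$index, tolerance = 0.1)

  agg <- summarize_lipid(list(res, res_ox))
  expect_identical(agg$n_fovs, rep(2L, 3))
})

test_that("condition comparisons run ANOVA plus Dunnett plus challenge contrasts", {
  set.seed(22)
  conds <- c("0", "25", "50", "1000")
  dat <- expand.grid(condition = conds, rep = 1:4, h2o2 = c("no", "yes"),
                     stringsAsFactors = FALSE)
  dat$value <- rnorm(nrow(dat), 100, 5) +
    ifelse(dat$condition == "1000" & dat$h2o2 == "no", 40, 0) +
    ifelse(dat$h2o2 == "yes", 25, 0)
  res <- compare_conditions(dat, reference = "0", challenge_col = "h2o2",
                            challenge_baseline = "no", ndraws = 1e4)
  expect_s3_class(res$dunnett, "data.frame")
  expect_equal(nrow(res$dunnett), 3)
  hit <- res$dunnett$adjusted_p[grepl("^1000", res$dunnett$contrast)]
  expect_lt(hit, 0.05)
  expect_true(all(res$challenge$p < 0.05))

  expect_error(compare_conditions(dat, reference = "nope"), "not present")
  one_rep <- rbind(dat, data.frame(condition = "2000", rep = 1, h2o2 = "no",
                                   value = 1))
  expect_error(compare_conditions(one_rep, reference = "0",
                                  challenge_col = "h2o2"), "2000")
})

test_that("a strongly shifted group is detected without flagging null groups", {
  set.seed(23)
  detected <- logical(60)
  null_hit <- logical(60)
  for (i in 1:60) {
    g <- list(ctrl = rnorm(4), a = rnorm(4), b = rnorm(4), shifted = rnorm(4, 5))
    d <- dunnett(g, control_index = 1, ndraws = 1e4, seed = i)
    detected[i] <- d$adjusted_p[3] < 0.05
    null_hit[i] <- any(d$adjusted_p[1:2] < 0.05)
  }
  expect_gte(mean(detected), 0.95)
  expect_lte(mean(null_hit), 0.15)
})

test_that("identical groups give a degenerate p of 1, not NaN", {
  tt <- t_test(c(3, 3, 3), c(3, 3, 3))
  expect_true(tt$degenerate)
  expect_equal(tt$p, 1)
})
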