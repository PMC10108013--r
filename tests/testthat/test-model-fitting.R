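test_that("AICc matches the least-squares form with variance counted", {
  # n log(RSS/n) + 2k + 2k(k+1)/(n-k-1), k = n_params + 1
  expect_equal(aicc(RSS = 10, n_points = 10, n_params = 2), 10)
  # doubling RSS adds n log 2
  expect_equal(aicc(20, 10, 2) - aicc(10, 10, 2), 10 * log(2))
  # strictly increasing in k at fixed RSS, n
  a <- vapply(1:4, function(k) aicc(10, 48, k), numeric(1))
  expect_true(all(diff(a) > 0))
  # correction term vanishes as n grows: AICc -> AIC
  aic <- function(RSS, n, p) n * log(RSS / n) + 2 * (p + 1)
  expect_equal(aicc(1e6, 1e6, 2), aic(1e6, 1e6, 2), tolerance = 1e-5)
  expect_error(aicc(10, 4, 2), "exceed")
  expect_error(aicc(-1, 10, 2), ">= 0")
})

test_that("noiseless curves are recovered essentially exactly", {
  lad <- build_ladder("LAP")
  cv2 <- noiseless_curve("M2", c(Vmax = 100, Km = 10), lad)
  f2 <- fit_model(cv2, "M2")
  expect_true(f2$converged)
  expect_equal(unname(f2$estimates), c(100, 10), tolerance = 1e-6)

  p4 <- c(Vmax_HA = 50, Km_HA = 2, Vmax_LA = 500, Km_LA = 300)
  f4 <- fit_model(noiseless_curve("M4", p4, lad), "M4")
  expect_equal(unname(f4$estimates), unname(p4), tolerance = 1e-4)

  # strictly linear data: closed-form first-order fit, zero residual
  lin <- response_curve("s", "LAP", S = lad$concentrations,
                        V = 0.1 * 1000 * lad$concentrations)
  f1 <- fit_model(lin, "M1")
  expect_equal(unname(f1$estimates), 0.1, tolerance = 1e-12)
  expect_equal(f1$RSS, 0, tolerance = 1e-12)

  # eligibility: each model needs n_params + 2 distinct levels
  tiny <- response_curve("s", "BG", S = c(300, 150, 75, 37.5, 18.75),
                         V = eval_model("M2", c(Vmax = 50, Km = 20),
                                        c(300, 150, 75, 37.5, 18.75)))
  expect_error(fit_model(tiny, "M4"), "levels")
  expect_s3_class(fit_model(tiny, "M2"), "kinetic_fit")
})

test_that("selection takes the lowest AICc, ties to the simpler model", {
  mk <- function(model, aic) {
    f <- eeanet:::new_kinetic_fit(
      model, setNames(rep(1, model_spec(model)$n_params),
                      model_spec(model)$parameter_names),
      RSS = 1, n_points = 48, converged = TRUE, n_starts = 1L)
    f$AICc <- aic
    f
  }
  expect_identical(select_model(list(mk("M2", 12), mk("M4", 10)))$model_id, "M4")
  expect_identical(select_model(list(mk("M2", 10), mk("M4", 10)))$model_id, "M2")
  expect_identical(select_model(list(mk("M2", 10)))$model_id, "M2")
  bad <- mk("M4", 5); bad$converged <- FALSE
  expect_identical(select_model(list(mk("M2", 10), bad))$model_id, "M2")
  expect_error(select_model(list(bad)), "converged")
})

test_that("residual sums of squares respect model nesting", {
  set.seed(101)
  lad <- build_ladder("BG")
  for (i in 1:10) {
    cv <- simulate_response_curve("M4", draw_m4_params(), ladder = lad,
                                  noise_cv = 0.05, seed = 300 + i)
    fits <- fit_all(cv)
    slack <- function(r) r * (1 + 1e-6) + 1e-9
    expect_lte(fits$M4$RSS, slack(fits$M3$RSS))
    expect_lte(fits$M3$RSS, slack(fits$M2$RSS))
    expect_lte(fits$M3$RSS, slack(fits$M1$RSS))
  }
})

test_that("M4 systems keep the affinity ordering after noisy refits", {
  set.seed(77)
  for (i in 1:10) {
    cv <- simulate_response_curve("M4", draw_m4_params(),
                                  noise_cv = 0.05, seed = 400 + i)
    f <- fit_model(cv, "M4")
    expect_lte(f$estimates[["Km_HA"]], f$estimates[["Km_LA"]])
  }
})

test_that("cell-specific Vmax follows the unit algebra", {
  # 1 nM/h over 1e9 cells/L = 1 amol/cell/h
  expect_equal(specific_vmax(100, 1e9), 100)
  expect_equal(specific_vmax(0, 5e8), 0)
  expect_equal(specific_vmax(10, 2e9), specific_vmax(10, 1e9) / 2)
  expect_error(specific_vmax(10, 0), "> 0")
})

test_that("paired HA/LA comparison uses the exact signed-rank null", {
  # n = 5, all LA > HA: the most extreme of 2^5 sign assignments
  expect_equal(compare_ha_la(c(1, 2, 3, 4, 5), c(1.5, 2.6, 3.7, 4.8, 5.9))$p_value, 2 / 32)
  # near-balanced differences sit near the null median
  ha <- c(10, 20, 30, 40, 50, 60)
  la <- ha + c(-3.1, 3, -2.2, 2, -1.5, 1)
  expect_gt(compare_ha_la(ha, la)$p_value, 0.5)
  # zero differences are dropped before ranking
  r <- compare_ha_la(c(1, 2, 3, 4, 5, 7), c(3.1, 4.2, 5.3, 6.4, 7.5, 7))
  expect_identical(r$n, 5L)
  expect_error(compare_ha_la(1:4, 1:4 + 1), ">= 5")
  expect_error(compare_ha_la(1:6, 1:6), "zero")
})

test_that("parameter sets map fits onto the HA/LA summary with flags", {
  lad <- build_ladder("BG")
  cv <- noiseless_curve("M4", c(Vmax_HA = 20, Km_HA = 1,
                                Vmax_LA = 200, Km_LA = 100), lad)
  cv$bacterial_abundance <- 1e9
  ps <- kinetic_parameters(fit_model(cv, "M4"), cv)
  expect_equal(ps$sp_Vmax_HA_amol_cell_h, 20, tolerance = 1e-4)
  expect_equal(ps$sp_Vmax_LA_amol_cell_h, 200, tolerance = 1e-4)
  expect_false(ps$Km_LA_extrapolated)
  # LA Km beyond the assayed ladder is reported and flagged, not censored
  cv2 <- noiseless_curve("M4", c(Vmax_HA = 20, Km_HA = 1,
                                 Vmax_LA = 400, Km_LA = 900), lad)
  ps2 <- kinetic_parameters(fit_model(cv2, "M4"), cv2)
  expect_true(ps2$Km_LA_extrapolated)
  expect_gt(ps2$Km_LA_uM, 300)
  # single-system fit fills only its own columns
  cvm2 <- noiseless_curve("M2", c(Vmax = 80, Km = 30), lad)
  ps3 <- kinetic_parameters(fit_model(cvm2, "M2"), cvm2)
  expect_identical(ps3$selected_model, "M2")
  expect_true(is.na(ps3$Vmax_LA_nM_h) && is.na(ps3$Tt_LA_per_h))
})
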