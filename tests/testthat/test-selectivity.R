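test_that("ddG and predicted configuration follow the lower binding energy", {
  p1 <- delta_delta_g(data.frame(substrate_id = "3F", ez = "E",
                                 delta_g_R = -7.68, delta_g_S = -9.66))
  expect_equal(p1$ddg, 1.98)
  expect_equal(p1$predicted_config, "S")
  p2 <- delta_delta_g(data.frame(substrate_id = "2F", ez = "Z",
                                 delta_g_R = -6.24, delta_g_S = -4.60))
  expect_equal(p2$ddg, 1.64)
  expect_equal(p2$predicted_config, "R")
  tie <- delta_delta_g(data.frame(substrate_id = "X", ez = "E",
                                  delta_g_R = -5, delta_g_S = -5))
  expect_equal(tie$ddg, 0)
  expect_equal(tie$predicted_config, "none")
})

test_that("TST conversion between ddG and E is exact and invertible", {
  expect_equal(e_from_ddg(0), 1)
  expect_equal(e_from_ddg(1.0, 303.15),
               exp(1 / (1.98720425e-3 * 303.15)), tolerance = 1e-12)
  expect_equal(e_from_ddg(1.0, 303.15), 5.259, tolerance = 1e-3)
  expect_equal(ddg_from_e(1), 0)
  expect_equal(ddg_from_e(9, 298.15), 1.302, tolerance = 1e-3)
  set.seed(5)
  x <- runif(20, 0, 5)
  for (temp in c(288, 298.15, 303.15, 310)) {
    expect_equal(ddg_from_e(e_from_ddg(x, temp), temp), x, tolerance = 1e-10)
  }
  # monotone in both arguments
  expect_true(all(diff(e_from_ddg(seq(0, 4, 0.5))) > 0))
  expect_error(e_from_ddg(-0.1), ">= 0")
  expect_error(ddg_from_e(0.5), ">= 1")
})

test_that("capping is a reporting convention over raw values", {
  ct <- cap_e(c(5, 200, 374))
  expect_equal(ct$e_capped, c(5, 200, 200))
  expect_equal(ct$capped, c(FALSE, FALSE, TRUE))
  # with the cap disabled nothing is capped
  ct2 <- cap_e(c(5, 1e6), cap = Inf)
  expect_equal(ct2$e_capped, c(5, 1e6))
  expect_false(any(ct2$capped))
})

test_that("Chen-Sih E from (conversion, ee) reproduces the reference entries", {
  expect_equal(e_from_conversion_ee(0.50, 0.65), 9.06, tolerance = 2e-3)
  expect_equal(round(e_from_conversion_ee(0.34, 0.93)), 44)
  expect_equal(round(e_from_conversion_ee(0.48, 0.96)), 146)
  expect_equal(round(e_from_conversion_ee(0.52, 0.64)), 9)
  expect_equal(round(e_from_conversion_ee(0.32, 0.54)), 4)
  # analytic limit c -> 0: E -> (1 + ee) / (1 - ee)
  ee <- 0.6
  expect_equal(e_from_conversion_ee(1e-6, ee), (1 + ee) / (1 - ee),
               tolerance = 1e-4)
  # no selectivity
  expect_equal(e_from_conversion_ee(0.3, 0), 1)
  # perfect product ee at finite conversion: infinite selectivity sentinel
  expect_equal(e_from_conversion_ee(0.4, 1), Inf)
  expect_error(e_from_conversion_ee(0.6, 0.9), "Infeasible")
  expect_error(e_from_conversion_ee(1.2, 0.5), "conversion")
})

test_that("E is strictly increasing in product ee at fixed conversion", {
  for (c_ in c(0.1, 0.3, 0.45)) {
    ee <- seq(0, 0.95, 0.05)
    ev <- e_from_conversion_ee(c_, ee)
    expect_true(all(diff(ev) > 0))
    expect_true(all(ev >= 1))
  }
})

test_that("ee_from_conversion_e inverts the relation and matches a bisection oracle", {
  expect_equal(ee_from_conversion_e(0.3, 1), 0)
  expect_equal(ee_from_conversion_e(0.45, 112), 0.958, tolerance = 1e-3)
  expect_equal(ee_from_conversion_e(0.45, 112), bisect_ee(0.45, 112),
               tolerance = 1e-8)
  set.seed(11)
  for (i in 1:15) {
    # draw a feasible (conversion, ee) point, compute its E, then invert
    c_ <- runif(1, 0.05, 0.7)
    ee_true <- runif(1, 0.05, 0.95) * min(1, 1 / c_ - 1)
    e <- e_from_conversion_ee(c_, ee_true)
    ee <- ee_from_conversion_e(c_, e)
    expect_equal(ee, ee_true, tolerance = 1e-7)
    expect_equal(ee, bisect_ee(c_, e), tolerance = 1e-7)
    expect_equal(e_from_conversion_ee(c_, ee), e, tolerance = 1e-8)
  }
  # conversions too high for a representable root are an explicit error
  expect_error(ee_from_conversion_e(0.64, 256), "No feasible")
})

test_that("selectivity prediction recovers the reference docking table", {
  pred <- predict_selectivity(reference_docking())
  pred <- pred[order(pred$substrate_id, pred$ez), ]
  expect_equal(pred$ddg, c(1.87, 1.64, 1.98, 1.51, 2.65, 0.92))
  expect_equal(pred$predicted_config, c("S", "R", "S", "R", "S", "R"))
  expect_true(all(pred$e_raw >= 1))
  g <- glance(pred)
  expect_equal(g$n_pairs, 6)
  expect_equal(g$n_unpaired, 0)
  # a lone record yields no pairs, with a warning
  expect_warning(
    lone <- predict_selectivity(data.frame(substrate_id = "2F", ez = "E",
                                           rs = "R", delta_g = -7.3)),
    "unpaired"
  )
  expect_equal(nrow(lone), 0)
})

test_that("experimental analysis recomputes reference E-values and flags infeasible rows", {
  ana <- analyze_resolution(reference_observations())
  expect_equal(ana$e_rounded, c(118, 9, 146, 9, 44, 4))
  expect_true(all(ana$feasible))
  expect_false(any(ana$capped))
  expect_equal(ana$ddg_exp, ddg_from_e(ana$e_raw, 303.15), tolerance = 1e-12)
  # infeasible and degenerate rows are flagged, not fatal
  extra <- data.frame(substrate_id = c("X", "Y"), ez = "E",
                      conversion = c(0.6, 0.3), ee_product = c(0.9, 0),
                      preferred_config = "S")
  ana2 <- analyze_resolution(extra)
  expect_equal(ana2$feasible, c(FALSE, TRUE))
  expect_true(is.na(ana2$e_raw[1]))
  expect_equal(ana2$e_raw[2], 1)
})

test_that("prediction-experiment comparison counts concordance", {
  pred <- predict_selectivity(reference_docking())
  obs <- reference_observations()
  cmp <- compare_predictions(pred, obs)
  g <- glance(cmp)
  expect_equal(g$n_matched, 6)
  expect_equal(g$n_concordant, 6)
  expect_equal(g$concordance, 1)
  # one flipped experimental preference becomes discordant
  flipped <- obs
  flipped$preferred_config[1] <- setdiff(c("R", "S"), obs$preferred_config[1])
  g2 <- glance(compare_predictions(pred, flipped))
  expect_equal(g2$n_concordant, 5)
  # disjoint keys are reported, not dropped
  alien <- obs
  alien$substrate_id <- paste0("Q", alien$substrate_id)
  expect_warning(cmp3 <- compare_predictions(pred, alien), "one side only")
  expect_equal(sum(glance(cmp3)$n_matched), 0)
})
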