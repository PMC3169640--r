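env <- .env310
ci <- etc_complex("CI")

test_that("one-percent variations: Vmf proportionality, multi-fold redox constants, bisection self-check", {
  p <- reference_truth()$CI
  vV <- variation_for_one_percent(ci, p, "Vmf", env)
  expect_equal(vV$fold, 0.99)

  # at the substrate-rich assay reference the redox ratios are enormous, so
  # the redox-state constants need multi-fold increases
  for (nm in c("k_D", "k_A")) {
    v <- variation_for_one_percent(ci, p, nm, env)
    expect_true(v$bounded)
    expect_gt(v$fold, 100)
    # self-check: re-evaluating the flux at the returned value gives the
    # targeted decrease
    st <- assay_reference_state(ci)
    p2 <- chemios:::.set_param(p, nm, v$value)
    drop <- 1 - isolated_activity(st, ci, p2, env) /
      isolated_activity(st, ci, p, env)
    expect_equal(drop, 0.01, tolerance = 1e-4)
  }
  # saturation constants need only modest increases
  vK <- variation_for_one_percent(ci, p, "Km_D", env)
  expect_lt(vK$fold, 2)
})

test_that("a single-complex pathway has unit control and a near-straight threshold curve", {
  p <- reference_truth()$CI
  model <- etc_network(
    list(list(spec = ci, params = p)),
    clamps = c(Q = 50, QH2 = 50),
    drive = drive_spec("NADH", "NAD", k = 10 * p$Vmf / 100),
    env = env)
  totals <- c(NADH = 100, NAD = 0)
  co <- fcc(model, totals, "CI", "Vmf")
  expect_equal(co$fcc, 1, tolerance = 0.02)
  cv <- threshold_curve(model, totals, "CI", "Vmf", n_grid = 40)
  expect_equal(max(abs(cv$flux_drop_pct - cv$activity_drop_pct)), 0,
               tolerance = 1.5)
  expect_equal(attr(cv, "area"), 0.5, tolerance = 0.02)
})

test_that("control coefficients are consistent across parameters and satisfy the summation theorem", {
  rn <- reference_network()
  ft <- fcc_table(rn$model, rn$totals)
  expect_true(all(ft$sum > 0.99 & ft$sum < 1.01))
  for (cn in c("CI", "CIII", "CIV")) {
    expect_lt(max(ft[[cn]]) - min(ft[[cn]]), 0.01)
  }
  # the ordering the pathway is calibrated to: CIII and CIV share control,
  # complex I is in excess
  expect_lt(max(ft$CI), 0.06)
  expect_gt(min(ft$CIII), 0.4)
  expect_gt(min(ft$CIV), 0.4)
})

test_that("threshold curves coincide across kinetic parameters but not for the slippage efficiency", {
  rn <- reference_network()
  base <- steady_state(rn$model, rn$totals)
  cv_ref <- threshold_curve(rn$model, rn$totals, "CI", "Vmf", n_grid = 25,
                            max_drop = 96, base = base)
  for (nm in c("Km_D", "Km_A")) {
    cv <- threshold_curve(rn$model, rn$totals, "CI", nm, n_grid = 25,
                          max_drop = 96, base = base)
    n <- min(nrow(cv), nrow(cv_ref))
    expect_lt(max(abs(cv$flux_drop_pct[1:n] - cv_ref$flux_drop_pct[1:n])),
              0.5)
  }
  # redox-state constants are buffered by ratio re-poising: their curves
  # lie at or below the Vmf curve
  cv_k <- threshold_curve(rn$model, rn$totals, "CI", "k_A", n_grid = 25,
                          max_drop = 96, base = base)
  n <- min(nrow(cv_k), nrow(cv_ref))
  expect_true(all(cv_k$flux_drop_pct[1:n] <=
                  cv_ref$flux_drop_pct[1:n] + 0.5))
  cv_eff <- threshold_curve(rn$model, rn$totals, "CI", "eff", n_grid = 25,
                            max_drop = 96, base = base)
  n <- min(nrow(cv_eff), nrow(cv_ref))
  expect_gt(max(abs(cv_eff$flux_drop_pct[1:n] -
                    cv_ref$flux_drop_pct[1:n])), 2)
  # curves pass through the origin and live in the unit square
  expect_equal(cv_ref$activity_drop_pct[1], 0)
  expect_equal(cv_ref$flux_drop_pct[1], 0, tolerance = 1e-6)
  expect_true(all(cv_ref$flux_drop_pct >= -1e-6 &
                  cv_ref$flux_drop_pct <= 100))
})

test_that("profile perturbations: saturation stays local, redox-state propagates, areas order CI above the others", {
  rn <- reference_network()
  prof0 <- threshold_profile(rn$model, rn$totals, n_grid = 30)
  a0 <- stats::setNames(prof0$areas$area, prof0$areas$complex)
  expect_gt(a0[["CI"]], a0[["CIII"]])
  expect_gt(a0[["CI"]], a0[["CIV"]])

  # 10x increase of complex I's donor saturation constant: its own curve
  # moves, the other two stay put
  profK <- threshold_profile(rn$model, rn$totals, n_grid = 30,
                             perturb = list(complex = "CI", param = "Km_D",
                                            value = 50))
  for (cn in c("CIII", "CIV")) {
    d <- max(abs(profK$curves[[cn]]$flux_drop_pct -
                 prof0$curves[[cn]]$flux_drop_pct))
    expect_lt(d, 1)
  }
  # strong redox-state perturbation of complex I reshapes the whole profile
  profk <- threshold_profile(rn$model, rn$totals, n_grid = 30,
                             perturb = list(complex = "CI", param = "k_A",
                                            value = 30))
  d_all <- vapply(c("CI", "CIII", "CIV"), function(cn)
    max(abs(profk$curves[[cn]]$flux_drop_pct -
            prof0$curves[[cn]]$flux_drop_pct)), numeric(1))
  expect_gt(sum(d_all > 1), 1)
})
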