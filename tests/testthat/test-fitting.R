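env <- .env310
ci <- etc_complex("CI")

mk_curve <- function(t, y, sp = "NADH", sid = "c1") {
  tibble::tibble(time_s = t, species = sp, conc_uM = y, series_id = sid)
}

test_that("initial velocity: flat curves, window contracts, truncation bias", {
  t <- 0:100
  expect_equal(initial_velocity(mk_curve(t, rep(7, 101))), 0)
  expect_error(initial_velocity(mk_curve(0:1, c(1, 2))), "3 samples")

  # convex (exponential) decay: the plain window slope underestimates the
  # instantaneous rate, and halving the window moves it toward the truth
  k <- 0.05
  y <- 100 * exp(-k * t)
  v_true <- 100 * k
  v_w <- initial_velocity(mk_curve(t, y), window = 40, method = "linear")
  v_h <- initial_velocity(mk_curve(t, y), window = 20, method = "linear")
  expect_lt(v_w, v_true)
  expect_lt(abs(v_h - v_true), abs(v_w - v_true))

  # the quadratic default is much less biased on the same window
  v_l20 <- initial_velocity(mk_curve(t, y), window = 20, method = "linear")
  v_q20 <- initial_velocity(mk_curve(t, y), window = 20)
  expect_lt(abs(v_q20 - v_true), abs(v_l20 - v_true) / 4)
})

test_that("initial velocity tracks the generator's true initial flux on noiseless curves", {
  p <- reference_truth()$CI
  for (D0 in c(5, 25, 100)) {
    J0 <- flux(carrier_state(D0, 0, 100, 0), ci, p, env)$J
    dep <- D0 / J0        # crude depletion scale
    times <- seq(0, 0.05 * dep, length.out = 25)
    cv <- simulate_assay(ci, p, D0, 100, times, env)
    v0 <- initial_velocity(cv[cv$species == "NADH", ])
    expect_equal(v0, J0, tolerance = 0.01)
  }
})

test_that("saturation fit recovers a clean hyperbolic design exactly", {
  Vmax <- 0.8; Km <- 12
  S <- c(1, 3, 6, 12, 30, 60, 120, 240)
  curves <- lapply(seq_along(S), function(i) {
    v <- Vmax * S[i] / (Km + S[i])
    mk_curve(0:20, S[i] - v * (0:20) * 0.001 * S[i] / S[i],
             sid = paste0("s", i))
  })
  # build noise-free linear windows at exactly the hyperbolic rates
  curves <- lapply(seq_along(S), function(i) {
    v <- Vmax * S[i] / (Km + S[i])
    mk_curve(seq(0, 5, 0.5), S[i] - v * seq(0, 5, 0.5),
             sid = paste0("s", i))
  })
  meta <- tibble::tibble(series_id = paste0("s", seq_along(S)),
                         targeted = S, actual = S, D0 = S, A0 = 1e6,
                         total_monitored = S)
  set <- assay_set(curves, meta, "CI", "donor", 1e6, "NADH")
  ft <- fit_saturation(set, window = 5)
  expect_equal(ft$Vmax, Vmax, tolerance = 1e-3)
  expect_equal(ft$Km, Km, tolerance = 1e-3)
  expect_error(fit_saturation(assay_set(curves[1:3], meta[1:3, ], "CI",
                                        "donor", 1e6, "NADH")),
               "at least 4")
})

test_that("curve residual: zero on identity, closed form for a constant offset, species check", {
  obs <- mk_curve(0:9, 10 - 0:9 * 0.5)
  expect_identical(curve_residual(obs, obs, total = 10), 0)
  sim <- obs
  sim$conc_uM <- sim$conc_uM + 0.25
  expect_equal(curve_residual(obs, sim, total = 10), 10 * (0.25 / 10)^2)
  bad <- obs; bad$species <- "Q"
  expect_error(curve_residual(obs, bad), "different species")
})

test_that("the two-stage pipeline recovers all five parameters from noiseless data", {
  sets <- noiseless_ci_sets()
  fit <- fit_etc_complex(sets$donor, sets$acceptor, ci, env, thin = 3)
  truth <- c(Vmf = 0.4, Km_D = 5, Km_A = 20, k_D = 0.03, k_A = 0.3)
  est <- stats::setNames(fit$estimates$estimate, fit$estimates$param)
  expect_lt(max(abs(est / truth[names(est)] - 1)), 0.01)
  # reported Vmf is the mean of the two per-set corrected maxima
  expect_equal(est[["Vmf"]], mean(fit$vmax_sets))
  # combined residual equals the sum over the fitted curves
  expect_equal(fit$combined_residual, sum(fit$per_curve_residuals),
               tolerance = 1e-8)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)
})

test_that("single-curve redox-constant fits are degenerate in the symmetric regime; combined fitting removes the valley", {
  # symmetric regime: equal constants and equal pool totals make the curve
  # invariant under exchanging (k_D, k_A) and nearly flat along one
  # direction; curves at other compositions break the symmetry
  truth <- kinetic_params(Vmf = 0.4, Km_D = 5, Km_A = 20,
                          k_D = 0.1, k_A = 0.1)
  mkset <- function(D0s) {
    curves <- list(); meta <- NULL
    for (D0 in D0s) {
      cv <- simulate_assay(ci, truth, D0, 100, seq(0, 1800, 2), env,
                           series_id = paste0("d", D0))
      dtr <- cv[cv$species == "NADH", ]
      t_end <- dtr$time_s[which(dtr$conc_uM <= 0.01 * D0)[1]]
      if (is.na(t_end)) t_end <- 1800
      curves[[length(curves) + 1]] <- dtr[dtr$time_s <= t_end, ]
      meta <- rbind(meta,
                    data.frame(series_id = paste0("d", D0), targeted = D0,
                               actual = D0, D0 = D0, A0 = 100,
                               total_monitored = D0))
    }
    assay_set(curves, tibble::as_tibble(meta), "CI", "donor", 100, "NADH")
  }
  set3 <- mkset(c(20, 50, 100))
  fixed <- list(Vmf = 0.4, Km_D = 5, Km_A = 20)
  obj1 <- chemios:::.k_objective(list(set3), list(list(set = 1, curve = 3)),
                                 fixed, ci, env, thin = 2)
  objC <- chemios:::.k_objective(list(set3),
                                 lapply(1:3, function(i)
                                   list(set = 1, curve = i)),
                                 fixed, ci, env, thin = 2)
  hess <- function(f, x, h = 0.05) {
    H <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      ei <- c(0, 0); ei[i] <- h
      ej <- c(0, 0); ej[j] <- h
      H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                  f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
    }
    (H + t(H)) / 2
  }
  x0 <- log10(c(0.1, 0.1))
  k1 <- kappa(hess(obj1, x0), exact = TRUE)
  kC <- kappa(hess(objC, x0), exact = TRUE)
  expect_gt(k1, 100)
  expect_gt(k1 / kC, 10)
})
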