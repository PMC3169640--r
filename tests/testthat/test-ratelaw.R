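env <- .env310
ci <- etc_complex("CI")

test_that("redox potential span reduces to the midpoint at unit ratios and follows the Nernst term", {
  st <- carrier_state(50, 50, 50, 50)
  expect_equal(redox_potential_span(st, ci, env), 359.49)

  # q = 0: output independent of the membrane potential
  env_m <- thermo_env(dPsi = 120, dpH = 0.5, membrane_intact = TRUE)
  expect_equal(redox_potential_span(st, ci, env_m),
               redox_potential_span(st, ci, env))
  # q = -1 complex picks up -dPsi
  ciii <- etc_complex("CIII")
  expect_equal(redox_potential_span(st, ciii, env_m),
               redox_potential_span(st, ciii, env) - 120)

  # doubling Dred shifts dE by the closed-form log term
  st2 <- carrier_state(100, 50, 50, 50)
  shift <- 1000 * rt_energy(env) * log(2) / (ci$n_e * env$F)
  expect_equal(redox_potential_span(st2, ci, env),
               redox_potential_span(st, ci, env) + shift, tolerance = 1e-12)

  expect_error(redox_potential_span(carrier_state(0, 1, 1, 1), ci, env),
               "strictly positive")
})

test_that("total force combines the redox and proton-pumping terms", {
  # reference system: TF is exactly the redox force
  expect_equal(total_force(359.49, ci, env),
               ci$n_e * env$F * 359.49 / 1000)
  # balance point: n_e dE = n_H dp gives zero force
  env_m <- thermo_env(dPsi = 150, dpH = 0, membrane_intact = TRUE)
  dE_bal <- ci$n_H * 150 / ci$n_e
  expect_equal(total_force(dE_bal, ci, env_m), 0, tolerance = 1e-9)
  # CI at dE0 with a 150 mV (pure electrical) proton-motive force
  expect_equal(total_force(359.49, ci, env_m),
               2 * 96485 * 0.35949 - 4 * 96485 * 0.150)
})

test_that("force function is zero at equilibrium, monotone, saturating, and branch-consistent", {
  expect_identical(force_function(0, env), 0)
  expect_equal(force_function(1e9, env), 1)
  x <- seq(-5, 5, length.out = 201) * rt_energy(env)
  ft <- force_function(x, env)
  expect_true(all(diff(ft) > 0))
  expect_true(all(ft <= 1 & ft > -1))
  # continuity across the branch switch
  epsF <- 1e-9 * rt_energy(env)
  expect_lt(abs(force_function(epsF, env) - force_function(-epsF, env)),
            1e-8)

  # forward (J+) and reverse (J-) expressions of the net flux agree at
  # |TF| = RT once Vmr is tied to Vmf by the reference equilibrium
  p <- ci_params()
  keq <- exp(ci$n_e * env$F * ci$dE0 / 1000 / rt_energy(env))
  vmr <- vmr_from_equilibrium(p, ci, env)
  for (s in c(1, -1)) {
    st <- state_at_force(ci, s * 1, env)
    r <- redox_ratios(st)
    FRf <- (r[["r_D"]] / (r[["r_D"]] + p$k_D)) *
      (r[["r_A"]] / (r[["r_A"]] + p$k_A))
    FRr <- (p$k_D / (r[["r_D"]] + p$k_D)) *
      (p$k_A / (r[["r_A"]] + p$k_A))
    J_fwd_form <- p$Vmf * FRf * (1 - exp(-s))
    J_rev_form <- vmr * FRr * (exp(s) - 1)
    expect_equal(J_fwd_form, J_rev_form, tolerance = 1e-12)
  }
})

test_that("redox state function has the documented limits, bounds and symmetry", {
  st <- carrier_state(30, 70, 80, 20)
  p0 <- ci_params(k_D = 0, k_A = 0)
  expect_equal(redox_state_function(st, p0), 1)

  p <- ci_params(k_D = 0.7, k_A = 2.5)
  big <- carrier_state(100, 1e-7, 100, 1e-7)
  expect_equal(redox_state_function(big, p), 1, tolerance = 1e-5)

  # half-saturated on both sides: r_D = k_D, r_A = k_A gives 1/4
  st_half <- carrier_state(0.7, 1, 2.5, 1)
  expect_equal(redox_state_function(st_half, p), 0.25, tolerance = 1e-9)

  # symmetric in the (ratio, constant) pairs
  st_a <- carrier_state(3, 1, 5, 1)
  st_b <- carrier_state(5, 1, 3, 1)
  expect_equal(redox_state_function(st_a, ci_params(k_D = 2, k_A = 9)),
               redox_state_function(st_b, ci_params(k_D = 9, k_A = 2)))

  # monotone nondecreasing in each ratio, never non-finite
  vals <- vapply(10^seq(-9, 9), function(r)
    redox_state_function(carrier_state(r, 1, 1, 1), p), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(is.finite(vals)))
})

test_that("saturation function: parallel factorization, bounds, and the sequential schemes match a binding-state oracle", {
  p <- ci_params(Km_D = 5, Km_A = 20)
  expect_equal(saturation_function(5, 2e6, p), 0.5, tolerance = 1e-5)
  expect_equal(saturation_function(1e9, 1e9, p), 1, tolerance = 1e-6)
  grid <- expand.grid(D = c(0, 0.5, 5, 60, 500), A = c(0, 1, 20, 300))
  fs <- mapply(function(D, A) saturation_function(D, A, p),
               grid$D, grid$A)
  expect_true(all(fs >= 0 & fs < 1))

  p_ord <- ci_params(mechanism = "ordered_sequential")
  p_rnd <- ci_params(mechanism = "random_sequential")
  for (i in seq_len(nrow(grid))) {
    D <- grid$D[i]; A <- grid$A[i]
    expect_equal(saturation_function(D, A, p_ord),
                 binding_scheme_oracle("ordered", D, A, 5, 20, 5, 20),
                 tolerance = 1e-10)
    expect_equal(saturation_function(D, A, p_rnd),
                 binding_scheme_oracle("random", D, A, 5, 20, 5, 20),
                 tolerance = 1e-10)
  }
  # the three mechanisms genuinely differ away from saturation
  expect_false(isTRUE(all.equal(saturation_function(5, 20, p),
                                saturation_function(5, 20, p_ord))))
  expect_false(isTRUE(all.equal(saturation_function(5, 20, p_ord),
                                saturation_function(5, 20, p_rnd))))
})

test_that("Vmr from the reference equilibrium is consistent and round-trips", {
  p_sym <- kinetic_params(Vmf = 2, Km_D = 5, Km_A = 5, k_D = 4, k_A = 0.25)
  spec0 <- complex_spec("X0", n_e = 2, n_H = 0, q = 0, dE0 = 0,
                        donor = c(red = "Dr", ox = "Do"),
                        acceptor = c(ox = "Ao", red = "Ar"))
  expect_equal(vmr_from_equilibrium(p_sym, spec0, env), 2)

  p <- ci_params()
  vmr <- vmr_from_equilibrium(p, ci, env)
  keq <- exp(ci$n_e * env$F * ci$dE0 / 1000 / rt_energy(env))
  expect_equal(vmr, p$Vmf / (p$k_D * p$k_A * keq), tolerance = 1e-12)
  # round trip: Vmr -> Keq -> Vmr
  keq_back <- p$Vmf / (vmr * p$k_D * p$k_A)
  expect_equal(rt_energy(env) * log(keq_back) / (ci$n_e * env$F) * 1000,
               ci$dE0, tolerance = 1e-9)
  expect_error(
    vmr_from_equilibrium(list(Vmf = 0, k_D = 1, k_A = 1), ci, env),
    "positive")
})

test_that("a supplied Vmr inconsistent with the reference equilibrium warns but is used", {
  p <- ci_params()
  vmr <- vmr_from_equilibrium(p, ci, env)
  p_bad <- ci_params(Vmr = vmr * 2)
  st <- carrier_state(50, 50, 50, 50)
  expect_warning(flux(st, ci, p_bad, env), "non-reference")
})

test_that("flux vanishes exactly at equilibrium and carries the sign of the force", {
  p <- ci_params()
  st_eq <- state_at_force(ci, 0, env)
  res <- flux(st_eq, ci, p, env)
  expect_equal(res$J, 0, tolerance = 1e-18)
  expect_equal(res$TF, 0, tolerance = 1e-6)

  for (x in c(-3, -0.5, 0.5, 3, 20)) {
    res <- flux(state_at_force(ci, x, env), ci, p, env)
    expect_equal(sign(res$J), sign(x))
    expect_equal(sign(res$direction), sign(x))
  }
  # continuity across the branch switch at TF = 0
  J_up <- flux(state_at_force(ci, 1e-9, env), ci, p, env)$J
  J_dn <- flux(state_at_force(ci, -1e-9, env), ci, p, env)$J
  expect_lt(abs(J_up - J_dn), 1e-12)
})

test_that("with unit redox constants the flux is proportional to the mass-action state dependence", {
  p1 <- ci_params(k_D = 1, k_A = 1)
  states <- random_states(50, seed = 4)
  keq <- exp(ci$n_e * env$F * ci$dE0 / 1000 / rt_energy(env))
  Js <- vapply(states, function(st) flux(st, ci, p1, env)$J, numeric(1))
  ma <- vapply(states, function(st)
    st$Dred * st$Aox - st$Dox * st$Ared / keq, numeric(1))
  ratio <- Js / ma
  expect_lt(max(abs(ratio / ratio[1] - 1)), 1e-8)
})

test_that("slip force scales the force, fixes the equilibrium point, and weakens the flux monotonically", {
  expect_identical(slip_force(12345, 1), 12345)
  expect_identical(slip_force(0, 0.3), 0)
  expect_error(slip_force(1, 1.2), "0, 1")

  p <- ci_params()
  st <- state_at_force(ci, 2, env)   # TF = 2 RT
  effs <- seq(0.05, 1, by = 0.05)
  Js <- vapply(effs, function(e)
    flux(st, ci, ci_params(eff = e), env)$J, numeric(1))
  expect_true(all(diff(Js) >= -1e-15))
  # direct evaluation of the slip-transformed law at eff = 0.5, TF = 2 RT
  FS <- saturation_function(100, 100, p)
  FR <- redox_state_function(st, p)
  expect_equal(flux(st, ci, ci_params(eff = 0.5), env)$J,
               p$Vmf * FS * FR * (1 - exp(-0.5 * 2)), tolerance = 1e-10)
})

test_that("transform_flux applies one exponential pair per force with the documented lam extremes", {
  rt <- rt_energy(env)
  base <- transform_flux(2, 1, list(), env)
  expect_equal(base$J, 1)
  id <- transform_flux(2, 1, list(list(force = 0, lam = 0.3)), env)
  expect_equal(id$J_fwd, 2); expect_equal(id$J_rev, 1)

  # lam = 1: forward flux untouched, reverse bears the whole force
  tr <- transform_flux(2, 1, list(list(force = -3 * rt, lam = 1)), env)
  expect_equal(tr$J_fwd, 2)
  expect_equal(tr$J_rev, 1 * exp(3))

  # two forces with equal lam compose like their sum
  two <- transform_flux(2, 1, list(list(force = 1.2 * rt, lam = 0.4),
                                   list(force = -0.7 * rt, lam = 0.4)), env)
  one <- transform_flux(2, 1, list(list(force = 0.5 * rt, lam = 0.4)), env)
  expect_equal(two$J, one$J, tolerance = 1e-12)
  expect_error(transform_flux(1, 1, list(list(force = 1, lam = 2)), env),
               "lam")
})

test_that("cycle oracle: detailed balance, the exponential flux ratio, and time rescaling", {
  rt <- rt_energy(env)
  rates <- c(a12 = 2, a21 = 3, a23 = 1.5, a32 = 0.8, a31 = 4, a13 = 1)
  eq <- cycle_oracle(rates, force = 0, env)
  expect_equal(eq$J_net, 0, tolerance = 1e-15)

  for (f in c(-8, -2, 0.5, 3, 10) * rt) {
    co <- cycle_oracle(rates, force = f, env)
    expect_equal(log(co$J_fwd / co$J_rev), f / rt, tolerance = 1e-10)
  }
  co1 <- cycle_oracle(rates, env = env)
  co5 <- cycle_oracle(rates * 5, env = env)
  expect_equal(co5$J_net, 5 * co1$J_net, tolerance = 1e-12)
  expect_error(cycle_oracle(c(rates[-6], a13 = -1)), "positive")
})

test_that("flux agrees with the cycle-oracle net flux under matched rate constants", {
  p <- ci_params()
  vmr <- vmr_from_equilibrium(p, ci, env)
  states <- random_states(1000, seed = 99)
  for (st in states) {
    r <- redox_ratios(st)
    co <- cycle_oracle(c(a12 = r[["r_D"]], a21 = p$k_D, a23 = p$Vmf,
                         a32 = vmr, a31 = r[["r_A"]], a13 = p$k_A),
                       env = env)
    res <- flux(st, ci, p, env)
    # the oracle cycle carries the same force, and its net/forward ratio
    # must reproduce the force factor of the rate law
    expect_equal(co$force, res$TF, tolerance = 1e-8)
    expect_equal(co$J_net / co$J_fwd,
                 res$J / (p$Vmf * res$F_S * res$F_R),
                 tolerance = 1e-8)
  }
})

test_that("factor bounds hold pointwise on random grids", {
  p <- ci_params()
  states <- random_states(300, seed = 12)
  for (st in states) {
    res <- flux(st, ci, p, env)
    expect_true(res$F_S >= 0 && res$F_S < 1)
    expect_true(res$F_R > 0 && res$F_R <= 1)
    expect_true(res$F_T <= 1 && res$F_T > -1)
    if (res$TF >= 0) expect_true(res$F_T >= 0)
  }
})
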