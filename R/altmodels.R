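#' Korzeniewski-style linear force-flux rate equation
#'
#' Flux proportional to the total thermodynamic force (Onsager's linear
#' force-to-flux relation, valid near equilibrium): `J = c * TF`.
#'
#' @param state A [carrier_state()].
#' @param spec A [complex_spec()].
#' @param p List with nonnegative linear coefficient `c`
#'   (uM/s per J/mol).
#' @param env A [thermo_env()].
#' @param eps Ratio-seeding fraction.
#' @return Flux, uM/s.
#' @export
korzeniewski_flux <- function(state, spec, p, env = thermo_env(),
                              eps = 1e-9) {
  stopifnot(p$c >= 0)
  r <- redox_ratios(state, eps)
  TF <- spec$n_e * env$F * spec$dE0 / 1000 +
    rt_energy(env) * log(r[["r_D"]] * r[["r_A"]])
  if (env$membrane_intact) {
    TF <- TF + spec$n_e * spec$q * env$F * env$dPsi / 1000 -
      spec$n_H * pmf_energy(env)
  }
  p$c * TF
}

#' Beard-style mass-action rate equation
#'
#' The overall reaction treated as an elementary mass-action step scaled by
#' a single activity parameter `X`, with the reverse term tied to the
#' equilibrium constant so the flux obeys the same exponential force-flux
#' relation and vanishes at zero force:
#' `J = X * (Dred * Aox - Dox * Ared / Keq)`.
#'
#' @inheritParams korzeniewski_flux
#' @param p List with nonnegative activity scale `X` (1/(uM s)).
#' @return Flux, uM/s.
#' @export
beard_flux <- function(state, spec, p, env = thermo_env(), eps = 1e-9) {
  stopifnot(p$X >= 0)
  keq <- exp(spec$n_e * env$F * spec$dE0 / 1000 / rt_energy(env))
  p$X * (state$Dred * state$Aox - state$Dox * state$Ared / keq)
}

# Closed-system progress curve under an arbitrary flux function over the
# four carrier species (donor pair, acceptor pair).
.simulate_generic <- function(flux_fun, spec, D0, A0, times,
                              rtol = 1e-8, atol = 1e-10) {
  rhs <- function(t, y, parms) {
    st <- carrier_state(Dred = max(y[1], 0), Dox = max(y[2], 0),
                        Aox = max(y[3], 0), Ared = max(y[4], 0))
    J <- flux_fun(st)
    list(c(-spec$nu_D, spec$nu_D, -spec$nu_A, spec$nu_A) * J)
  }
  y0 <- c(D0, 0, A0, 0)
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol,
                        atol = atol)
  tibble::tibble(time_s = sol[, 1], Dred = sol[, 2], Dox = sol[, 3],
                 Aox = sol[, 4], Ared = sol[, 5])
}

.obs_resid <- function(sim, obs_t, obs_y, total) {
  y <- stats::approx(sim$time_s, sim$Dred, xout = obs_t, rule = 2,
                     ties = "ordered")$y
  sum(((obs_y - y) / total)^2)
}

#' Three-way rate-equation comparison on one progress curve
#'
#' Least-squares fits of the linear (Korzeniewski-form), mass-action
#' (Beard-form) and chemiosmotic rate equations to a single closed-assay
#' progress curve of the reduced-donor trace, each over its own free
#' parameters (one, one, and three — `Vmf`, `k_D`, `k_A` with the
#' saturation constants held at their known values). The chemiosmotic
#' family nests the mass-action model (`k_D = k_A = 1`) and approaches the
#' linear model's zero-order behavior as the constants vanish, so its best
#' residual is bounded by both alternatives'.
#'
#' @param curve Progress-curve tibble of the reduced-donor species.
#' @param spec A [complex_spec()].
#' @param D0,A0 Actual initial concentrations of the assay, uM.
#' @param Km Named list/vector with the saturation constants `Km_D`,
#'   `Km_A` used by the chemiosmotic fit.
#' @param env A [thermo_env()].
#' @param thin Keep every `thin`-th observation.
#' @return Tibble of class `model_comparison`: one row per model with the
#'   fitted parameters (list column), the residual, and the fitted
#'   trajectory (list column).
#' @export
compare_models <- function(curve, spec, D0, A0, Km, env = thermo_env(),
                           thin = 1) {
  obs <- curve[seq(1, nrow(curve), by = thin), ]
  obs_t <- obs$time_s
  obs_y <- obs$conc_uM
  total <- D0
  keq <- exp(spec$n_e * env$F * spec$dE0 / 1000 / rt_energy(env))
  v0 <- initial_velocity(obs)

  fit_1par <- function(make_fluxfun, scale0) {
    f <- function(log_s) {
      sim <- tryCatch(
        .simulate_generic(make_fluxfun(exp(log_s)), spec, D0, A0, obs_t),
        error = function(e) NULL)
      if (is.null(sim)) return(1e6)
      .obs_resid(sim, obs_t, obs_y, total)
    }
    o <- stats::optim(log(scale0), f, method = "Brent",
                      lower = log(scale0) - 12, upper = log(scale0) + 12)
    list(par = exp(o$par), value = o$value)
  }

  # linear force-flux: scale from matching the initial velocity
  st0 <- carrier_state(D0, 0, A0, 0)
  TF0 <- spec$n_e * env$F * spec$dE0 / 1000 +
    rt_energy(env) * log(prod(redox_ratios(st0)))
  korz <- fit_1par(function(cc) function(st)
    korzeniewski_flux(st, spec, list(c = cc), env), v0 / TF0)

  beard <- fit_1par(function(X) function(st)
    beard_flux(st, spec, list(X = X), env), v0 / (D0 * A0))

  chem_obj <- function(par) {
    p <- kinetic_params(Vmf = exp(par[1]), Km_D = Km[["Km_D"]],
                        Km_A = Km[["Km_A"]],
                        k_D = exp(par[2]), k_A = exp(par[3]))
    sim <- tryCatch(
      simulate_assay(spec, p, D0, A0, obs_t, env),
      error = function(e) NULL)
    if (is.null(sim)) return(1e6)
    sim <- sim[sim$species == spec$donor[["red"]], ]
    y <- stats::approx(sim$time_s, sim$conc_uM, xout = obs_t, rule = 2,
                       ties = "ordered")$y
    sum(((obs_y - y) / total)^2)
  }
  FS0 <- (D0 / (Km[["Km_D"]] + D0)) * (A0 / (Km[["Km_A"]] + A0))
  vstart <- log(v0 / FS0)
  starts <- list(c(vstart, 0, 0), c(vstart, log(0.03), log(0.3)),
                 c(vstart, -7, -7), c(vstart, log(3), log(1)))
  chem_fits <- lapply(starts, function(s)
    stats::optim(s, chem_obj, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-10)))
  chem <- chem_fits[[which.min(vapply(chem_fits, `[[`, numeric(1),
                                      "value"))]]

  sim_of <- function(fluxfun) .simulate_generic(fluxfun, spec, D0, A0, obs_t)
  out <- tibble::tibble(
    model = c("korzeniewski", "beard", "chemiosmotic"),
    residual = c(korz$value, beard$value, chem$value),
    params = list(list(c = korz$par), list(X = beard$par),
                  list(Vmf = exp(chem$par[1]), k_D = exp(chem$par[2]),
                       k_A = exp(chem$par[3]))),
    trajectory = list(
      sim_of(function(st) korzeniewski_flux(st, spec, list(c = korz$par),
                                            env)),
      sim_of(function(st) beard_flux(st, spec, list(X = beard$par), env)),
      {
        p <- kinetic_params(Vmf = exp(chem$par[1]), Km_D = Km[["Km_D"]],
                            Km_A = Km[["Km_A"]], k_D = exp(chem$par[2]),
                            k_A = exp(chem$par[3]))
        s <- simulate_assay(spec, p, D0, A0, obs_t, env)
        s[s$species == spec$donor[["red"]], ]
      })
  )
  structure(out, class = c("model_comparison", class(tibble::tibble())))
}
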