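#' Redox potential span across a complex
#'
#' Potential difference (acceptor minus donor pair) seen by one electron:
#' the standard midpoint span, the concentration (Nernst) term in the redox
#' ratios, and — when the electron itself crosses the membrane — the
#' electrical potential weighted by the crossing switch `q`. At unit redox
#' ratios with zero membrane potential this reduces to `dE0`.
#'
#' @param state A [carrier_state()]; concentrations must be strictly
#'   positive unless `eps > 0`, in which case product species are seeded at
#'   `eps` times their pool total.
#' @param spec A [complex_spec()].
#' @param env A [thermo_env()].
#' @param eps Seeding fraction passed to [redox_ratios()]; `0` enforces
#'   strictly positive concentrations.
#' @return Potential difference in millivolts.
#' @export
redox_potential_span <- function(state, spec, env, eps = 0) {
  if (eps == 0) {
    conc <- unlist(state[c("Dred", "Dox", "Aox", "Ared")])
    if (any(conc <= 0)) {
      stop("all carrier concentrations must be strictly positive", call. = FALSE)
    }
  }
  r <- redox_ratios(state, eps = max(eps, 0))
  rt <- rt_energy(env)
  nernst_mV <- 1000 * rt * log(r[["r_D"]] * r[["r_A"]]) / (spec$n_e * env$F)
  spec$dE0 + nernst_mV + spec$q * env$dPsi
}

#' Energy to pump one proton across the membrane
#'
#' The per-proton cost of translocation against the proton-motive force:
#' `F * dPsi + ln(10) * R * T * dpH`, in J/mol. Zero in the reference
#' (membrane-fragmented) system.
#'
#' @param env A [thermo_env()].
#' @return J/mol per proton.
#' @export
pmf_energy <- function(env) {
  if (!env$membrane_intact) return(0)
  env$F * env$dPsi / 1000 + log(10) * rt_energy(env) * env$dpH
}

#' Total thermodynamic force of the transduction reaction
#'
#' The redox force `n_e * F * dE` minus the opposing proton translocation
#' cost `n_H` times the per-proton pmf energy. With `membrane_intact =
#' FALSE` the pure redox force is returned.
#'
#' @param dE Redox potential span, millivolts (see
#'   [redox_potential_span()]).
#' @inheritParams redox_potential_span
#' @return Force in J/mol; positive drives net donor oxidation.
#' @export
total_force <- function(dE, spec, env) {
  spec$n_e * env$F * dE / 1000 - spec$n_H * pmf_energy(env)
}

#' Thermodynamic force function
#'
#' Dimensionless modulation of the flux by the total force `TF`. The
#' forward-flux form `1 - exp(-TF/RT)` is used for `TF >= 0` and the
#' reverse-flux form `exp(TF/RT) - 1` for `TF < 0`; each is the numerically
#' stable expression in its own direction, they agree at `TF = 0`, and the
#' value is zero exactly at equilibrium.
#'
#' @param TF Thermodynamic force, J/mol (vectorized).
#' @param env A [thermo_env()].
#' @return Dimensionless value in (-1, 1]; 0 at `TF = 0`, increasing in
#'   `TF`, saturating at 1 as `TF` grows.
#' @export
force_function <- function(TF, env) {
  x <- TF / rt_energy(env)
  ifelse(x >= 0, 1 - exp(-x), expm1(x))
}

.f_redox <- function(r_D, r_A, k_D, k_A) {
  (r_D / (r_D + k_D)) * (r_A / (r_A + k_A))
}

#' Redox state function
#'
#' Hyperbolic modulation of the flux by the donor and acceptor redox ratios:
#' `F_R = r_D/(r_D + k_D) * r_A/(r_A + k_A)`. The two (ratio, constant)
#' pairs enter symmetrically; the value lies in (0, 1], equals 1 whenever
#' both constants are zero (zero-order limit), and tends to 1 as both ratios
#' grow.
#'
#' @param state A [carrier_state()].
#' @param params A [kinetic_params()].
#' @param eps Seeding fraction for the ratios.
#' @return Dimensionless value in (0, 1].
#' @export
redox_state_function <- function(state, params, eps = 1e-9) {
  r <- redox_ratios(state, eps = eps)
  .f_redox(r[["r_D"]], r[["r_A"]], params$k_D, params$k_A)
}

.mech_constants <- function(params) {
  md <- params$mech_dissoc
  if (is.null(md)) {
    list(Ki_D = params$Km_D, Ki_A = params$Km_A,
         K_D = params$Km_D, K_A = params$Km_A, defaulted = TRUE)
  } else {
    list(Ki_D = md$Ki_D %||% params$Km_D,
         Ki_A = md$Ki_A %||% params$Km_A,
         K_D = md$K_D %||% md$Ki_D %||% params$Km_D,
         K_A = md$K_A %||% md$Ki_A %||% params$Km_A,
         defaulted = FALSE)
  }
}

#' Saturation function
#'
#' Fraction of the enzyme ensemble present as the catalytically active
#' ternary complex, as a function of the carrier pool totals and the binding
#' mechanism. The parallel mechanism factorizes into two independent
#' hyperbolic terms; the ordered and random sequential variants are the
#' rapid-equilibrium bi-bi solutions. Sequential mechanisms without explicit
#' dissociation constants reuse `Km_D`/`Km_A` for the binary steps with
#' ternary = binary (a log message records the substitution).
#'
#' @param D_tot,A_tot Total donor and acceptor pool concentrations, uM
#'   (nonnegative).
#' @param params A [kinetic_params()].
#' @param quiet Suppress the dissociation-constant substitution message.
#' @return Dimensionless value in [0, 1).
#' @export
saturation_function <- function(D_tot, A_tot, params, quiet = TRUE) {
  stopifnot(all(D_tot >= 0), all(A_tot >= 0))
  switch(params$mechanism,
    parallel = (D_tot / (params$Km_D + D_tot)) *
               (A_tot / (params$Km_A + A_tot)),
    ordered_sequential = {
      k <- .mech_constants(params)
      if (k$defaulted && !quiet) {
        message("ordered_sequential: reusing Km_D/Km_A as dissociation constants (ternary = binary)")
      }
      D_tot * A_tot / (k$Ki_D * k$K_A + k$K_A * D_tot + D_tot * A_tot)
    },
    random_sequential = {
      k <- .mech_constants(params)
      if (k$defaulted && !quiet) {
        message("random_sequential: reusing Km_D/Km_A as dissociation constants (ternary = binary)")
      }
      num <- D_tot * A_tot / (k$Ki_D * k$K_A)
      num / (1 + D_tot / k$Ki_D + A_tot / k$Ki_A + num)
    }
  )
}

#' Maximum reverse velocity from the reference equilibrium
#'
#' In the reference system the equilibrium constant of the overall reaction
#' ties the two maximum velocities together:
#' `Vmf / Vmr = k_D * k_A * exp(n_e * F * dE0 / (R * T))`. Given `Vmf`,
#' `k_D`, `k_A` and the midpoint span, this returns the consistent `Vmr`.
#'
#' @inheritParams redox_potential_span
#' @param params A [kinetic_params()].
#' @return `Vmr` in uM/s (0 when `k_D * k_A = 0`: the reverse transition
#'   state is unpopulated in that limit).
#' @export
vmr_from_equilibrium <- function(params, spec, env) {
  if (is.null(params$Vmf) || params$Vmf <= 0) {
    stop("Vmf must be positive to derive Vmr", call. = FALSE)
  }
  keq <- exp(spec$n_e * env$F * spec$dE0 / 1000 / rt_energy(env))
  kk <- params$k_D * params$k_A
  if (kk == 0) return(0)
  params$Vmf / (kk * keq)
}

.vmr_warned <- new.env(parent = emptyenv())

.resolve_vmr <- function(params, spec, env) {
  implied <- vmr_from_equilibrium(params, spec, env)
  if (is.null(params$Vmr)) return(implied)
  if (implied > 0 && abs(params$Vmr / implied - 1) > 0.01) {
    key <- paste0(spec$name, "_", signif(params$Vmr, 6))
    if (is.null(.vmr_warned[[key]])) {
      .vmr_warned[[key]] <- TRUE
      warning(sprintf(
        "supplied Vmr (%.4g) deviates >1%% from the reference-equilibrium value (%.4g) for %s; treating as a non-reference system",
        params$Vmr, implied, spec$name), call. = FALSE)
    }
  }
  params$Vmr
}

#' Reduced effective force under slippage
#'
#' Slippage dissipates a fraction `1 - eff` of the thermodynamic force
#' through a short-circuit transition path; the force available to the
#' transduction cycle is `eff * TF`. Equilibrium (`TF = 0`) is a fixed point
#' for every efficiency.
#'
#' @param TF Thermodynamic force, J/mol.
#' @param eff Slippage efficiency in [0, 1].
#' @return Effective force `eff * TF`, J/mol.
#' @export
slip_force <- function(TF, eff) {
  if (any(eff < 0) || any(eff > 1)) {
    stop("eff must lie in [0, 1]", call. = FALSE)
  }
  eff * TF
}

#' Transform directional fluxes by added forces
#'
#' Applies one exponential pair per added force: the forward flux is scaled
#' by `exp((1 - lam) * X / RT)` and the reverse flux by `exp(-lam * X / RT)`,
#' so their ratio shifts by `exp(X / RT)` and the equilibrium constant by the
#' same factor. `lam = 1` leaves the forward flux unaltered while the
#' reverse flux bears all the influence of the force; `lam = 0` is the
#' mirror case.
#'
#' @param J_fwd,J_rev Reference forward and reverse one-way fluxes, uM/s.
#' @param extra_forces List of `list(force = <J/mol>, lam = <[0,1]>)`
#'   entries, one per added force.
#' @param env A [thermo_env()].
#' @return List with transformed `J_fwd`, `J_rev` and the net flux `J`.
#' @export
transform_flux <- function(J_fwd, J_rev, extra_forces, env) {
  rt <- rt_energy(env)
  a <- 0
  b <- 0
  for (f in extra_forces) {
    lam <- f$lam
    if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]", call. = FALSE)
    a <- a + (1 - lam) * f$force / rt
    b <- b - lam * f$force / rt
  }
  out_f <- J_fwd * exp(a)
  out_r <- J_rev * exp(b)
  list(J_fwd = out_f, J_rev = out_r, J = out_f - out_r)
}

# Fast scalar evaluation of the full transducing rate law.
# Returns c(J, F_S, F_R, F_T, TF). `pre` caches mechanism-independent
# constants; see .compile_complex().
.flux_core <- function(Dred, Dox, Aox, Ared, pre, env, eps = 1e-9) {
  D_tot <- Dred + Dox
  A_tot <- Aox + Ared
  fD <- eps * D_tot
  fA <- eps * A_tot
  r_D <- max(Dred, fD) / max(Dox, fD)
  r_A <- max(Aox, fA) / max(Ared, fA)

  rt <- rt_energy(env)
  TF_ref <- pre$dG0 + rt * log(r_D * r_A)
  X_mem <- if (env$membrane_intact) {
    pre$n_e_qF * env$dPsi / 1000 - pre$n_H * pmf_energy(env)
  } else 0
  TF <- TF_ref + X_mem
  TF_eff <- pre$eff * TF

  F_S <- saturation_function(D_tot, A_tot, pre$params)
  F_R <- .f_redox(r_D, r_A, pre$k_D, pre$k_A)
  F_T <- force_function(TF_eff, env)

  # exponents of the transformation pairs (membrane force + slippage force)
  slipX <- -(1 - pre$eff) * TF
  if (TF_eff >= 0) {
    a <- ((1 - pre$lam) * X_mem + (1 - pre$lam_slip) * slipX) / rt
    J <- pre$Vmf * F_S * F_R * exp(a) * F_T
  } else {
    b <- (-pre$lam * X_mem - pre$lam_slip * slipX) / rt
    F_R_rev <- (pre$k_D / (r_D + pre$k_D)) * (pre$k_A / (r_A + pre$k_A))
    J <- pre$Vmr * F_S * F_R_rev * exp(b) * F_T
  }
  c(J = J, F_S = F_S, F_R = F_R, F_T = F_T, TF = TF)
}

.compile_complex <- function(spec, params, env) {
  list(params = params,
       Vmf = params$Vmf,
       Vmr = .resolve_vmr(params, spec, env),
       k_D = params$k_D, k_A = params$k_A,
       eff = params$eff, lam = params$lam, lam_slip = params$lam_slip,
       dG0 = spec$n_e * env$F * spec$dE0 / 1000,
       n_e_qF = spec$n_e * spec$q * env$F,
       n_H = spec$n_H)
}

#' Chemiosmotic reaction flux of one complex
#'
#' Evaluates the full rate law `J = Vm(direction) * F_S * F_R * F_T` at a
#' carrier state, with the membrane (pmf) transformation exponentials
#' applied when the membrane is intact and the slippage scaling applied when
#' `eff < 1`. The sign of `J` always matches the sign of the effective
#' force.
#'
#' @param state A [carrier_state()].
#' @param spec A [complex_spec()].
#' @param params A [kinetic_params()].
#' @param env A [thermo_env()].
#' @param eps Seeding fraction for ratio guards.
#' @return A one-row tibble (columns `J`, `F_S`, `F_R`, `F_T`, `TF`,
#'   `direction`): the net flux in uM/s, the three dimensionless factors,
#'   the total thermodynamic force in J/mol, and the force sign.
#' @examples
#' st <- carrier_state(Dred = 50, Dox = 50, Aox = 50, Ared = 50)
#' flux(st, etc_complex("CI"), kinetic_params(1, 5, 20, 0.3, 0.03),
#'      thermo_env())
#' @export
flux <- function(state, spec, params, env = thermo_env(), eps = 1e-9) {
  pre <- .compile_complex(spec, params, env)
  v <- .flux_core(state$Dred, state$Dox, state$Aox, state$Ared, pre, env, eps)
  tibble::tibble(J = v[["J"]], F_S = v[["F_S"]], F_R = v[["F_R"]],
                 F_T = v[["F_T"]], TF = v[["TF"]],
                 direction = sign(v[["TF"]]))
}

#' Exact cycle fluxes of the condensed three-state kinetic diagram
#'
#' Solves the stationary distribution of the three-state cycle (free
#' complex, electron on the high-potential center, electron on the
#' low-potential center) by linear algebra and returns the one-way cycle
#' fluxes via the diagram (spanning-tree) method. When a `force` is
#' supplied, detailed balance is imposed by rescaling the `a13` rate so that
#' `RT * log(J_fwd / J_rev)` equals it exactly.
#'
#' @param rates Named positive rates `a12, a21, a23, a32, a31, a13` for the
#'   transitions 1->2, 2->1, 2->3, 3->2, 3->1, 1->3.
#' @param force Optional thermodynamic force (J/mol) to impose on the cycle.
#' @param env A [thermo_env()].
#' @return List with `J_fwd`, `J_rev`, `J_net` (per unit total complex
#'   concentration), the stationary probabilities `p`, and the realized
#'   `force`.
#' @export
cycle_oracle <- function(rates, force = NULL, env = thermo_env()) {
  need <- c("a12", "a21", "a23", "a32", "a31", "a13")
  stopifnot(all(need %in% names(rates)))
  r <- as.list(rates[need])
  if (any(unlist(r) <= 0)) stop("all rate constants must be positive", call. = FALSE)
  rt <- rt_energy(env)
  if (!is.null(force)) {
    # impose J_fwd/J_rev = exp(force/RT) through the 1->3 rate
    r$a13 <- r$a12 * r$a23 * r$a31 / (r$a21 * r$a32 * exp(force / rt))
  }
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- r$a12; Q[2, 1] <- r$a21
  Q[2, 3] <- r$a23; Q[3, 2] <- r$a32
  Q[3, 1] <- r$a31; Q[1, 3] <- r$a13
  G <- t(Q)
  diag(G) <- -rowSums(Q)
  A <- rbind(G, rep(1, 3))
  p <- qr.solve(A, c(0, 0, 0, 1))
  if (any(!is.finite(p))) stop("singular transition matrix", call. = FALSE)

  pi_f <- r$a12 * r$a23 * r$a31
  pi_r <- r$a21 * r$a32 * r$a13
  # spanning-tree normalization recovered from the stationary solution
  D1 <- r$a21 * r$a31 + r$a32 * r$a21 + r$a23 * r$a31
  sigma <- D1 / p[1]
  J_fwd <- pi_f / sigma
  J_rev <- pi_r / sigma
  list(J_fwd = J_fwd, J_rev = J_rev, J_net = J_fwd - J_rev,
       p = p, force = rt * log(pi_f / pi_r))
}

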