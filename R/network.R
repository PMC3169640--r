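#' Dehydrogenase drive specification
#'
#' First-order regeneration of the reduced donor (NADH) from its oxidized
#' form, standing in for the upstream dehydrogenases that keep the NAD pool
#' reduced in a respiring preparation. Irreversible by default; with
#' `reversible = TRUE` a mass-action back reaction with equilibrium constant
#' `keq` is included.
#'
#' @param red,ox Species ids of the regenerated pair.
#' @param k First-order rate constant, 1/s.
#' @param reversible Include the back reaction.
#' @param keq Equilibrium ratio red/ox of the reversible drive.
#' @return A `drive_spec` list.
#' @export
drive_spec <- function(red = "NADH", ox = "NAD", k, reversible = FALSE,
                       keq = 100) {
  stopifnot(k >= 0, keq > 0)
  structure(list(red = red, ox = ox, k = k, reversible = reversible,
                 keq = keq), class = "drive_spec")
}

.complex_stoich <- function(spec) {
  s <- c(-spec$nu_D, spec$nu_D, -spec$nu_A, spec$nu_A)
  names(s) <- c(spec$donor[["red"]], spec$donor[["ox"]],
                spec$acceptor[["ox"]], spec$acceptor[["red"]])
  s
}

#' Assemble an ETC pathway model
#'
#' Composes rate-law complexes into a pathway with shared carrier pools.
#' Consecutive complexes must be wired donor-to-acceptor through a common
#' redox pair (complex i's donor pool is complex i-1's acceptor pool).
#' Clamped species (oxygen, water activity) are held constant; their net
#' derivative is zero.
#'
#' @param complexes List of `list(spec = <complex_spec>, params =
#'   <kinetic_params>)` entries, ordered along the pathway.
#' @param clamps Named numeric vector of clamped species concentrations
#'   (uM; water as unit activity).
#' @param drive Optional [drive_spec()].
#' @param env A [thermo_env()].
#' @return An object of class `etc_network`.
#' @export
etc_network <- function(complexes, clamps = numeric(0), drive = NULL,
                        env = thermo_env()) {
  stopifnot(length(complexes) >= 1)
  for (cx in complexes) {
    stopifnot(inherits(cx$spec, "complex_spec"),
              inherits(cx$params, "kinetic_params"))
  }
  if (length(complexes) > 1) {
    for (i in seq_len(length(complexes) - 1)) {
      up <- complexes[[i]]$spec$acceptor
      dn <- complexes[[i + 1]]$spec$donor
      if (!setequal(unname(up), unname(dn))) {
        stop(sprintf("complex %d's acceptor pool must be complex %d's donor pool",
                     i, i + 1), call. = FALSE)
      }
    }
  }
  species <- unique(unlist(lapply(complexes,
                                  function(cx) names(.complex_stoich(cx$spec)))))
  if (!is.null(drive)) species <- unique(c(species, drive$red, drive$ox))
  structure(
    list(complexes = complexes,
         species = species,
         clamps = clamps,
         drive = drive,
         env = env,
         compiled = lapply(complexes, function(cx)
           .compile_complex(cx$spec, cx$params, env))),
    class = "etc_network"
  )
}

.complex_J <- function(conc, model, i, eps = 1e-9) {
  spec <- model$complexes[[i]]$spec
  .flux_core(conc[[spec$donor[["red"]]]], conc[[spec$donor[["ox"]]]],
             conc[[spec$acceptor[["ox"]]]], conc[[spec$acceptor[["red"]]]],
             model$compiled[[i]], model$env, eps)[["J"]]
}

# Index-compiled derivative evaluator over an unnamed numeric state vector
# ordered as model$species. Shared by the ODE and steady-state paths.
.compiled_rhs <- function(model, eps = 1e-9) {
  sp <- model$species
  cxs <- lapply(seq_along(model$complexes), function(i) {
    spec <- model$complexes[[i]]$spec
    st <- .complex_stoich(spec)
    list(iDred = match(spec$donor[["red"]], sp),
         iDox = match(spec$donor[["ox"]], sp),
         iAox = match(spec$acceptor[["ox"]], sp),
         iAred = match(spec$acceptor[["red"]], sp),
         s_idx = match(names(st), sp), s_coef = unname(st),
         pre = model$compiled[[i]])
  })
  clamp_idx <- match(names(model$clamps), sp)
  dr <- model$drive
  d_red <- if (!is.null(dr)) match(dr$red, sp) else NA_integer_
  d_ox <- if (!is.null(dr)) match(dr$ox, sp) else NA_integer_
  env <- model$env
  function(y) {
    y <- unname(y)
    d <- numeric(length(y))
    for (cx in cxs) {
      J <- .flux_core(y[cx$iDred], y[cx$iDox], y[cx$iAox], y[cx$iAred],
                      cx$pre, env, eps)[["J"]]
      d[cx$s_idx] <- d[cx$s_idx] + cx$s_coef * J
    }
    if (!is.null(dr)) {
      v <- dr$k * y[d_ox]
      if (dr$reversible) v <- v - (dr$k / dr$keq) * y[d_red]
      d[d_red] <- d[d_red] + v
      d[d_ox] <- d[d_ox] - v
    }
    if (length(clamp_idx)) d[clamp_idx] <- 0
    d
  }
}

#' Mass-balance right-hand side
#'
#' Time derivative of every species: the stoichiometry-weighted sum of the
#' complex fluxes plus the drive term; clamped species get zero.
#'
#' @param conc Named nonnegative concentrations, uM.
#' @param model An [etc_network()].
#' @param eps Ratio-seeding fraction forwarded to the rate law.
#' @return Named numeric vector of derivatives, uM/s.
#' @export
mass_balance_rhs <- function(conc, model, eps = 1e-9) {
  missing <- setdiff(model$species, names(conc))
  if (length(missing)) {
    stop("unknown/missing species id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- unlist(conc[model$species])
  d <- .compiled_rhs(model, eps)(y)
  stats::setNames(d, model$species)
}

#' Simulate a pathway trajectory
#'
#' Integrates the mass-balance ODEs with a stiff implicit solver (lsoda,
#' rtol 1e-8, atol 1e-12 uM by default — progress curves span several orders
#' of magnitude in species).
#'
#' @param model An [etc_network()].
#' @param init Named initial concentrations, uM; clamped species may be
#'   omitted (their clamp values are used).
#' @param times Strictly increasing time grid, seconds.
#' @param series_id Identifier stored in the output.
#' @param rtol,atol Solver tolerances.
#' @return A progress-curve tibble with columns `time_s`, `species`,
#'   `conc_uM`, `series_id`.
#' @export
simulate_network <- function(model, init, times, series_id = "sim",
                             rtol = 1e-8, atol = 1e-12) {
  stopifnot(all(diff(times) > 0), all(init >= 0))
  y0 <- stats::setNames(numeric(length(model$species)), model$species)
  y0[names(init)[names(init) %in% model$species]] <-
    init[names(init) %in% model$species]
  y0[names(model$clamps)] <- model$clamps
  f <- .compiled_rhs(model)
  rhs <- function(t, y, parms) list(f(y))
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("ODE solver failed; last accepted time %.6g s",
                 max(sol[, "time"], na.rm = TRUE)), call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "time_s"
  out <- tidyr::pivot_longer(out, -"time_s", names_to = "species",
                             values_to = "conc_uM")
  out$series_id <- series_id
  out[, c("time_s", "species", "conc_uM", "series_id")]
}

.network_pools <- function(model) {
  pools <- list()
  for (cx in model$complexes) {
    pools[[length(pools) + 1]] <- c(red = unname(cx$spec$donor[["red"]]),
                                    ox = unname(cx$spec$donor[["ox"]]))
    pools[[length(pools) + 1]] <- c(red = unname(cx$spec$acceptor[["red"]]),
                                    ox = unname(cx$spec$acceptor[["ox"]]))
  }
  pools <- unique(pools)
  # pools with any clamped member are not free state variables
  Filter(function(p) !any(p %in% names(model$clamps)), pools)
}

#' Solve the pathway steady state
#'
#' Damped Newton iteration on log redox-ratio coordinates (one per free
#' carrier pool, totals conserved), with a long-integration fallback for the
#' initial guess when Newton stalls. At the solution all complex electron
#' fluxes are equal (series pathway).
#'
#' @param model An [etc_network()] with a drive and clamps making a
#'   nontrivial steady state possible.
#' @param totals Named pool totals, uM (red + ox per free pool). Defaults
#'   to 100 uM per pool if not derivable.
#' @param init Optional named starting concentrations.
#' @param tol Residual norm tolerance on the derivatives, uM/s.
#' @param max_iter Newton iteration cap.
#' @return List with `state` (named concentrations), `J` (per-complex net
#'   fluxes, uM/s), `J_ss` (pathway electron flux, uM electrons/s),
#'   `residual`.
#' @export
steady_state <- function(model, totals, init = NULL, tol = 1e-10,
                         max_iter = 200) {
  pools <- .network_pools(model)
  if (!length(pools)) stop("no free pools: nothing to solve", call. = FALSE)
  for (p in pools) {
    if (!(p[["red"]] %in% names(totals)) && !(p[["ox"]] %in% names(totals))) {
      stop("pool total missing for pair ", p[["red"]], "/", p[["ox"]],
           call. = FALSE)
    }
  }
  pool_tot <- vapply(pools, function(p) {
    sum(totals[intersect(c(p[["red"]], p[["ox"]]), names(totals))])
  }, numeric(1))

  sp <- model$species
  f_rhs <- .compiled_rhs(model)
  red_idx <- vapply(pools, function(p) match(p[["red"]], sp), integer(1))
  ox_idx <- vapply(pools, function(p) match(p[["ox"]], sp), integer(1))
  clamp_idx <- match(names(model$clamps), sp)
  conc_from_x <- function(x) {
    y <- numeric(length(sp))
    if (length(clamp_idx)) y[clamp_idx] <- model$clamps
    fr <- stats::plogis(x)                # reduced fraction of each pool
    y[red_idx] <- fr * pool_tot
    y[ox_idx] <- (1 - fr) * pool_tot
    y
  }
  resid <- function(x) f_rhs(conc_from_x(x))[red_idx]

  x <- if (is.null(init)) {
    rep(0, length(pools))
  } else {
    vapply(pools, function(p) {
      fr <- init[[p[["red"]]]] / (init[[p[["red"]]]] + init[[p[["ox"]]]])
      stats::qlogis(min(max(fr, 1e-12), 1 - 1e-12))
    }, numeric(1))
  }

  newton <- function(x, iters) {
    f <- resid(x)
    for (it in seq_len(iters)) {
      n0 <- sqrt(sum(f^2))
      if (n0 < tol) break
      Jm <- matrix(0, length(x), length(x))
      h <- 1e-6 * pmax(abs(x), 1)
      for (j in seq_along(x)) {
        xp <- x; xp[j] <- xp[j] + h[j]
        Jm[, j] <- (resid(xp) - f) / h[j]
      }
      step <- tryCatch(solve(Jm, -f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        xn <- x + lam * step
        fn <- resid(xn)
        if (sqrt(sum(fn^2)) < n0 || lam < 1e-6) break
        lam <- lam / 2
      }
      if (sqrt(sum(fn^2)) >= n0) break   # stalled
      x <- xn; f <- fn
    }
    list(x = x, norm = sqrt(sum(resid(x)^2)))
  }

  sol <- newton(x, max_iter)
  if (sol$norm >= tol) {
    # fallback: relax by integration, then polish
    conc0 <- stats::setNames(conc_from_x(sol$x), sp)
    rhs <- function(t, y, parms) list(f_rhs(y))
    relax <- deSolve::lsoda(conc0, c(0, 10^(1:5)), rhs, parms = NULL,
                            rtol = 1e-10, atol = 1e-14)
    yend <- relax[nrow(relax), -1]
    x <- vapply(seq_along(pools), function(j) {
      fr <- yend[[red_idx[j]]] / pool_tot[j]
      stats::qlogis(min(max(fr, 1e-12), 1 - 1e-12))
    }, numeric(1))
    sol <- newton(x, max_iter)
  }
  if (sol$norm >= tol) {
    stop(sprintf("steady state not converged; best residual %.3g uM/s",
                 sol$norm), call. = FALSE)
  }
  conc <- as.list(stats::setNames(conc_from_x(sol$x), sp))
  Js <- vapply(seq_along(model$complexes),
               function(i) .complex_J(conc, model, i), numeric(1))
  e_flux <- Js * vapply(model$complexes, function(cx) cx$spec$n_e, numeric(1))
  list(state = unlist(conc),
       J = stats::setNames(Js, vapply(model$complexes,
                                      function(cx) cx$spec$name, character(1))),
       J_ss = mean(e_flux),
       residual = sol$norm)
}

#' Reference three-complex ETC network
#'
#' The CI-CIII-CIV pathway at the in vitro (homogenate) reference
#' conditions: carrier pool totals at the saturating assay concentrations
#' (NAD 100, CoQ 100, cytochrome c 50 uM), oxygen clamped at a bulk value,
#' water at unit activity, and a saturating irreversible dehydrogenase drive
#' (rate constant 10 x CI Vmf / NAD pool total). Kinetic parameters are the
#' package's synthetic reference set: redox-state constants follow the
#' fitted-complex regimes (CI k_D = 0.3, k_A = 0.03; cytochrome-c-side
#' constants above one; O2 side mass-action, k_A = 1), saturation constants
#' at field-plausible magnitudes, and maximum velocities placed so that
#' complex I is in excess while complexes III and IV share control of the
#' steady-state flux.
#'
#' @param Vmf Named numeric: maximum forward velocities (uM/s) for CI, CIII,
#'   CIV.
#' @param o2_uM Clamped bulk oxygen concentration.
#' @param drive_factor Drive rate constant as a multiple of
#'   `Vmf[CI] / NAD_tot`.
#' @param env A [thermo_env()].
#' @return List with the [etc_network()] under `$model` and the pool totals
#'   under `$totals`.
#' @export
reference_network <- function(Vmf = c(CI = 0.40, CIII = 0.55, CIV = 0.52),
                              o2_uM = 200, drive_factor = 10,
                              env = thermo_env()) {
  totals <- c(NAD = 100, Q = 100, cc = 50)
  complexes <- list(
    list(spec = etc_complex("CI"),
         params = kinetic_params(Vmf = Vmf[["CI"]], Km_D = 5, Km_A = 20,
                                 k_D = 0.03, k_A = 0.3)),
    list(spec = etc_complex("CIII"),
         params = kinetic_params(Vmf = Vmf[["CIII"]], Km_D = 10, Km_A = 5,
                                 k_D = 0.1, k_A = 2)),
    list(spec = etc_complex("CIV"),
         params = kinetic_params(Vmf = Vmf[["CIV"]], Km_D = 10, Km_A = 1,
                                 k_D = 3, k_A = 1))
  )
  model <- etc_network(
    complexes,
    clamps = c(O2 = o2_uM, H2O = 1),
    drive = drive_spec("NADH", "NAD",
                       k = drive_factor * Vmf[["CI"]] / totals[["NAD"]]),
    env = env
  )
  list(model = model,
       totals = c(NADH = totals[["NAD"]], NAD = 0,
                  Q = totals[["Q"]], QH2 = 0,
                  ccox = totals[["cc"]], ccred = 0))
}
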