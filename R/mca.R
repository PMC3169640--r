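#' Saturating assay reference composition of a complex
#'
#' The carrier composition of the standard activity assay: the donor pool
#' fully reduced and the acceptor pool fully oxidized at the saturating
#' concentrations of the reference experiments (CI: NADH 100, CoQ 100 uM;
#' CIII: QH2 100, cyt c 50 uM; CIV: cyt c 50 uM, O2 at bulk). Product
#' species are present only through the epsilon seeding of the ratio guards.
#'
#' @param spec A [complex_spec()].
#' @param o2_uM Bulk oxygen concentration used for CIV.
#' @return A [carrier_state()].
#' @export
assay_reference_state <- function(spec, o2_uM = 200) {
  switch(spec$name,
    CI = carrier_state(Dred = 100, Dox = 0, Aox = 100, Ared = 0),
    CIII = carrier_state(Dred = 100, Dox = 0, Aox = 50, Ared = 0),
    CIV = carrier_state(Dred = 50, Dox = 0, Aox = o2_uM, Ared = 1),
    stop("no built-in reference composition for ", spec$name, call. = FALSE)
  )
}

#' Isolated activity of a complex
#'
#' Net flux of a single complex at a fixed carrier composition — the
#' operational "activity" used by the sensitivity analyses.
#'
#' @inheritParams flux
#' @return Flux in uM/s.
#' @export
isolated_activity <- function(state, spec, params, env = thermo_env()) {
  flux(state, spec, params, env)$J
}

.rate_params <- c("Vmf", "Km_D", "Km_A", "k_D", "k_A", "eff")

.set_param <- function(params, name, value) {
  stopifnot(name %in% .rate_params)
  p <- params
  p[[name]] <- value
  p$Vmr <- NULL   # keep the reference-equilibrium tie
  kinetic_params(Vmf = p$Vmf, Km_D = p$Km_D, Km_A = p$Km_A,
                 k_D = p$k_D, k_A = p$k_A, eff = p$eff,
                 lam = p$lam, lam_slip = p$lam_slip,
                 mechanism = p$mechanism, mech_dissoc = p$mech_dissoc)
}

# Find the parameter value whose activity at `state` is (1 - target) times
# the base activity. Increases Km/k, decreases Vmf/eff.
.variation_root <- function(state, spec, params, env, param, target) {
  v0 <- isolated_activity(state, spec, params, env)
  f <- function(val) {
    isolated_activity(state, spec, .set_param(params, param, val), env) /
      v0 - (1 - target)
  }
  x0 <- params[[param]]
  if (param == "Vmf") {
    return(list(value = (1 - target) * x0, achieved = target, bounded = TRUE))
  }
  if (param == "eff") {
    if (f(1e-9) > 0) {
      return(list(value = NA_real_, achieved = NA_real_, bounded = FALSE))
    }
    root <- stats::uniroot(f, c(1e-9, x0), tol = 1e-13)$root
  } else {
    hi <- x0 * 2
    while (f(hi) > 0 && hi < x0 * 1e14) hi <- hi * 4
    if (f(hi) > 0) {
      return(list(value = NA_real_, achieved = NA_real_, bounded = FALSE))
    }
    root <- stats::uniroot(f, c(x0, hi), tol = max(1e-14, x0 * 1e-12))$root
  }
  ach <- 1 - isolated_activity(state, spec, .set_param(params, param, root),
                               env) / v0
  list(value = root, achieved = ach, bounded = TRUE)
}

#' Parameter variation producing a one-percent activity change
#'
#' Bisection-found variation of one rate-law parameter whose isolated-complex
#' flux change at the saturating assay reference composition is 1.00% (a
#' decrease). `Vmf` is exactly proportional; the saturation constants need
#' modest increases; the redox-state constants need multi-fold increases at
#' the substrate-rich reference where the redox ratios are enormous; `eff`
#' is capped at its [0, 1] range and reported unbounded when 1% cannot be
#' reached.
#'
#' @param spec A [complex_spec()].
#' @param params A [kinetic_params()].
#' @param param One of `"Vmf"`, `"Km_D"`, `"Km_A"`, `"k_D"`, `"k_A"`,
#'   `"eff"`.
#' @param env A [thermo_env()].
#' @param state Composition at which the activity is evaluated; default the
#'   assay reference of [assay_reference_state()].
#' @param target Relative flux decrease (default 0.01).
#' @return A one-row tibble with `param`, `value`, `fold`, `achieved`
#'   (realized relative decrease) and `bounded`.
#' @export
variation_for_one_percent <- function(spec, params, param,
                                      env = thermo_env(),
                                      state = assay_reference_state(spec),
                                      target = 0.01) {
  res <- .variation_root(state, spec, params, env, param, target)
  tibble::tibble(param = param, value = res$value,
                 fold = res$value / params[[param]],
                 achieved = res$achieved, bounded = res$bounded)
}

.perturbed_model <- function(model, idx, new_params) {
  cxs <- model$complexes
  cxs[[idx]]$params <- new_params
  etc_network(cxs, clamps = model$clamps, drive = model$drive,
              env = model$env)
}

.state_of <- function(model, conc, idx) {
  spec <- model$complexes[[idx]]$spec
  carrier_state(Dred = conc[[spec$donor[["red"]]]],
                Dox = conc[[spec$donor[["ox"]]]],
                Aox = conc[[spec$acceptor[["ox"]]]],
                Ared = conc[[spec$acceptor[["red"]]]])
}

#' Flux control coefficient of one parameter of one complex
#'
#' The relative change in the global steady-state flux divided by the
#' relative change of the complex's activity under the same parameter
#' variation; the activity change is evaluated at the (frozen) unperturbed
#' steady-state composition, so that every parameter of a complex probes the
#' same local sensitivity. The variation defaults to the one producing a 1%
#' local activity decrease.
#'
#' @param model An [etc_network()].
#' @param totals Pool totals for [steady_state()].
#' @param complex Complex name (e.g. `"CI"`).
#' @param param Rate-law parameter name.
#' @param variation Optional explicit parameter value to use.
#' @param base Optional precomputed base [steady_state()] result (reused
#'   across a table of coefficients).
#' @return A one-row tibble with the coefficient and its ingredients.
#' @export
fcc <- function(model, totals, complex, param, variation = NULL,
                base = NULL) {
  idx <- match(complex, vapply(model$complexes,
                               function(cx) cx$spec$name, character(1)))
  if (is.na(idx)) stop("unknown complex ", complex, call. = FALSE)
  spec <- model$complexes[[idx]]$spec
  params <- model$complexes[[idx]]$params
  if (is.null(base)) base <- steady_state(model, totals)
  st <- .state_of(model, as.list(base$state), idx)

  if (is.null(variation)) {
    res <- .variation_root(st, spec, params, model$env, param, 0.01)
    if (!res$bounded) {
      return(tibble::tibble(complex = complex, param = param,
                            value = NA_real_, dv_rel = NA_real_,
                            dJ_rel = NA_real_, fcc = NA_real_))
    }
    variation <- res$value
  }
  new_params <- .set_param(params, param, variation)
  v0 <- isolated_activity(st, spec, params, model$env)
  v1 <- isolated_activity(st, spec, new_params, model$env)
  dv_rel <- v1 / v0 - 1
  ss <- steady_state(.perturbed_model(model, idx, new_params), totals,
                     init = as.list(base$state))
  dJ_rel <- ss$J_ss / base$J_ss - 1
  tibble::tibble(complex = complex, param = param, value = variation,
                 dv_rel = dv_rel, dJ_rel = dJ_rel, fcc = dJ_rel / dv_rel)
}

#' Full flux-control-coefficient table
#'
#' One row per rate-law parameter, one column per complex, plus the row sum
#' (summation-theorem check: sums near one).
#'
#' @inheritParams fcc
#' @param params Parameters to vary (rows).
#' @return A tibble of class `fcc_table`.
#' @export
fcc_table <- function(model, totals, params = .rate_params) {
  base <- steady_state(model, totals)
  cx_names <- vapply(model$complexes, function(cx) cx$spec$name, character(1))
  rows <- lapply(params, function(p) {
    vals <- vapply(cx_names, function(cn) {
      fcc(model, totals, cn, p, base = base)$fcc
    }, numeric(1))
    out <- tibble::as_tibble(as.list(vals))
    out$param <- p
    out$sum <- sum(vals)
    out[, c("param", cx_names, "sum")]
  })
  structure(dplyr::bind_rows(rows), class = c("fcc_table", class(tibble::tibble())))
}

#' Threshold curve of one complex
#'
#' Sweeps one parameter so that the complex's activity (at the frozen
#' baseline steady-state composition) decreases by 0 to `max_drop` percent,
#' resolves the pathway steady state at each point, and pairs the activity
#' decrease with the relative decrease of the global flux. The area fraction
#' under the retained-flux curve over the full [0, 100]^2 square (straight
#' line = 0.5) summarizes the excess capacity of the complex.
#'
#' @inheritParams fcc
#' @param param Swept parameter (default `"Vmf"`).
#' @param n_grid Number of evenly spaced activity-decrease targets.
#' @param max_drop Largest targeted activity decrease, percent.
#' @return A tibble of class `threshold_curve` with columns
#'   `activity_drop_pct`, `flux_drop_pct`, `value`; attributes `complex`,
#'   `param`, `area`, `truncated`.
#' @export
threshold_curve <- function(model, totals, complex, param = "Vmf",
                            n_grid = 100, max_drop = 99, base = NULL) {
  idx <- match(complex, vapply(model$complexes,
                               function(cx) cx$spec$name, character(1)))
  if (is.na(idx)) stop("unknown complex ", complex, call. = FALSE)
  spec <- model$complexes[[idx]]$spec
  params <- model$complexes[[idx]]$params
  if (is.null(base)) base <- steady_state(model, totals)
  st <- .state_of(model, as.list(base$state), idx)

  targets <- seq(0, max_drop, length.out = n_grid)
  drops <- numeric(0)
  vals <- numeric(0)
  flux_drop <- numeric(0)
  warm <- as.list(base$state)
  truncated <- FALSE
  for (tg in targets) {
    if (tg == 0) {
      val <- params[[param]]
    } else if (param == "Vmf") {
      val <- params$Vmf * (1 - tg / 100)
    } else {
      res <- .variation_root(st, spec, params, model$env, param, tg / 100)
      if (!res$bounded) { truncated <- TRUE; break }
      val <- res$value
    }
    ss <- tryCatch(
      steady_state(.perturbed_model(model, idx,
                                    .set_param(params, param, val)),
                   totals, init = warm),
      error = function(e) NULL)
    if (is.null(ss)) { truncated <- TRUE; break }
    warm <- as.list(ss$state)
    drops <- c(drops, tg)
    vals <- c(vals, val)
    flux_drop <- c(flux_drop, 100 * (1 - ss$J_ss / base$J_ss))
  }
  out <- tibble::tibble(activity_drop_pct = drops,
                        flux_drop_pct = flux_drop,
                        value = vals)
  # retained-flux area over the unit square, closing the curve at (100, 100)
  x <- c(out$activity_drop_pct, 100) / 100
  y <- 1 - c(out$flux_drop_pct, 100) / 100
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(out, class = c("threshold_curve", class(tibble::tibble())),
            complex = complex, param = param, area = area,
            truncated = truncated)
}

#' Threshold profile of the pathway
#'
#' Threshold curves (Vmf sweeps) of every complex, optionally after applying
#' a single-parameter perturbation to the model, with the area fractions
#' under the curves.
#'
#' @inheritParams fcc
#' @param perturb Optional `list(complex =, param =, value =)` applied
#'   before the analysis.
#' @param n_grid Grid size per curve.
#' @return List with `curves` (named list of [threshold_curve()] results)
#'   and `areas` (tibble).
#' @export
threshold_profile <- function(model, totals, perturb = NULL, n_grid = 100) {
  if (!is.null(perturb)) {
    idx <- match(perturb$complex,
                 vapply(model$complexes, function(cx) cx$spec$name,
                        character(1)))
    model <- .perturbed_model(model, idx,
                              .set_param(model$complexes[[idx]]$params,
                                         perturb$param, perturb$value))
  }
  base <- steady_state(model, totals)
  cx_names <- vapply(model$complexes, function(cx) cx$spec$name, character(1))
  curves <- lapply(cx_names, function(cn)
    threshold_curve(model, totals, cn, "Vmf", n_grid = n_grid, base = base))
  names(curves) <- cx_names
  areas <- tibble::tibble(
    complex = cx_names,
    area = vapply(curves, function(cv) attr(cv, "area"), numeric(1)))
  list(curves = curves, areas = areas)
}

#' Slippage divergence threshold of complex I
#'
#' Applies each slippage efficiency on a descending grid to complex I,
#' recomputes the Vmf-swept threshold curve, and compares it pointwise to
#' the fully coupled (eff = 1) curve. Returns the smallest grid efficiency
#' whose curve (and every larger one) stays within `tol_pct` percent of full
#' scale of the reference curve, i.e. the value below which the threshold
#' curve first departs.
#'
#' @inheritParams fcc
#' @param grid Descending slippage efficiencies to scan.
#' @param tol_pct Full-scale divergence tolerance, percentage points.
#' @param n_grid Threshold-curve grid size.
#' @param complex Complex carrying the slippage (default `"CI"`).
#' @return List with `threshold` (the reported efficiency), and `scan`
#'   (tibble of max pointwise deviations per grid value).
#' @export
slip_threshold_scan <- function(model, totals,
                                grid = c(1, 0.5, 0.2, 0.1, 0.05, 0.02),
                                tol_pct = 2, n_grid = 100, complex = "CI") {
  grid <- sort(grid, decreasing = TRUE)
  idx <- match(complex, vapply(model$complexes,
                               function(cx) cx$spec$name, character(1)))
  curves <- lapply(grid, function(e) {
    m <- .perturbed_model(model, idx,
                          .set_param(model$complexes[[idx]]$params, "eff", e))
    threshold_curve(m, totals, complex, "Vmf", n_grid = n_grid)
  })
  ref <- curves[[1]]
  dev <- vapply(curves, function(cv) {
    n <- min(nrow(cv), nrow(ref))
    max(abs(cv$flux_drop_pct[seq_len(n)] - ref$flux_drop_pct[seq_len(n)]))
  }, numeric(1))
  within <- dev <= tol_pct
  # largest grid value such that it and everything above it stay within tol
  ok <- which(!within)
  threshold <- if (length(ok) == 0) min(grid) else grid[min(ok) - 1]
  list(threshold = threshold,
       scan = tibble::tibble(eff = grid, max_dev_pct = dev,
                             within = within),
       curves = stats::setNames(curves, paste0("eff_", grid)))
}
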