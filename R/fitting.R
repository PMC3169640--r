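#' Initial velocity of a progress curve
#'
#' Rate of change of the monitored concentration over the starting window,
#' sign-corrected to a positive rate. The default window ends where the
#' monitored concentration has covered 5% of its total excursion (so the
#' flux is still near its initial value even on strongly decelerating
#' curves), widened if needed to hold at least five samples. The default
#' `"quadratic"` method fits a local quadratic and reports the derivative
#' at time zero, which removes most of the truncation bias of a plain
#' secant slope on a curving trace; the `"linear"` method is the plain
#' window slope.
#'
#' @param curve Progress-curve tibble with one species (columns `time_s`,
#'   `conc_uM`).
#' @param window Window length in seconds; `NULL` for the default.
#' @param method `"quadratic"` (default) or `"linear"`.
#' @return Positive initial rate, uM/s.
#' @export
initial_velocity <- function(curve, window = NULL,
                             method = c("quadratic", "linear")) {
  method <- match.arg(method)
  sp <- unique(curve$species)
  if (length(sp) > 1) {
    stop("curve has multiple species; filter to the monitored one first",
         call. = FALSE)
  }
  t <- curve$time_s - min(curve$time_s)
  y <- curve$conc_uM
  sigma <- stats::mad(diff(y)) / sqrt(2)   # robust measurement-noise scale
  if (is.null(window)) {
    ys <- if (length(y) >= 7) stats::runmed(y, 7) else y
    exc <- abs(ys - ys[1])
    if (max(exc) == 0) {
      window <- max(t)
    } else {
      # enough signal for a stable slope: 5% of the excursion, or twenty
      # noise standard deviations, whichever is larger
      thr <- max(0.05 * max(exc), 20 * sigma)
      hit <- which(exc >= thr)[1]
      window <- if (is.na(hit)) max(t) else t[max(hit, 2)]
    }
    if (sum(t <= window) < 5) window <- sort(t)[min(5, length(t))]
  }
  keep <- t <= window
  if (sum(keep) < 3) stop("fewer than 3 samples in the window", call. = FALSE)
  qslope <- function(k) {
    tw <- t[k]; yw <- y[k]
    if (method == "linear" || sum(k) < 4) {
      stats::coef(stats::lm(yw ~ tw))[["tw"]]
    } else {
      stats::coef(stats::lm(yw ~ tw + I(tw^2)))[["tw"]]
    }
  }
  slope <- qslope(keep)
  half <- t <= window / 2
  half_exc <- abs(y[max(which(half))] - y[1])
  if (method == "quadratic" && sum(half) >= 5 &&
      (sigma == 0 || half_exc >= 20 * sigma)) {
    # Richardson step: the quadratic's leading bias scales with the squared
    # window, so the half-window estimate extrapolates it away; skipped when
    # noise would dominate the half-window signal
    slope <- (4 * qslope(half) - slope) / 3
  }
  abs(slope)
}

# turnover flux from the monitored-species rate
.monitor_coef <- function(complex) {
  switch(complex, CI = 1, CIII = 2, CIV = 2, 1)
}

#' Fit the hyperbolic saturation factor to an assay set
#'
#' Least-squares fit of `v = Vmax * S / (Km + S)` to the (actual initial
#' concentration, initial velocity) pairs of the set, where the initial
#' velocities are converted to turnover fluxes through the monitored
#' species' stoichiometric coefficient.
#'
#' @param set An [assay_set()].
#' @param window,method Passed to [initial_velocity()].
#' @return List with `Vmax`, `Km`, the data used, the `nls` fit object, and
#'   an `ill_conditioned` flag (design entirely above the fitted Km).
#' @export
fit_saturation <- function(set, window = NULL, method = "quadratic") {
  if (length(set$curves) < 4) {
    stop("need at least 4 distinct initial concentrations", call. = FALSE)
  }
  v <- vapply(set$curves, initial_velocity, numeric(1),
              window = window, method = method) / .monitor_coef(set$complex)
  S <- set$meta$actual
  dat <- data.frame(S = S, v = v)
  start <- list(Vmax = 1.2 * max(v),
                Km = max(min(S), stats::approx(v / max(v), S, 0.5,
                                               ties = "ordered")$y %||% stats::median(S)))
  if (!is.finite(start$Km)) start$Km <- stats::median(S)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = dat, start = start,
                      lower = c(Vmax = 0, Km = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) tryCatch(
      stats::nls(v ~ Vmax * S / (Km + S), data = dat, start = start,
                 algorithm = "port", lower = c(0, 1e-9)),
      error = function(e2) NULL))
  if (is.null(fit)) {
    # profiled 1-D fallback: for fixed Km the amplitude is linear
    prof <- function(logKm) {
      x <- S / (exp(logKm) + S)
      Vm <- sum(v * x) / sum(x^2)
      sum((v - Vm * x)^2)
    }
    o <- stats::optimize(prof, log(c(min(S) / 100, max(S) * 100)))
    x <- S / (exp(o$minimum) + S)
    est <- c(Vmax = sum(v * x) / sum(x^2), Km = exp(o$minimum))
  } else {
    est <- stats::coef(fit)
  }
  list(Vmax = est[["Vmax"]], Km = est[["Km"]], data = dat, fit = fit,
       ill_conditioned = min(S) > 2 * est[["Km"]] && est[["Km"]] < 0.5 * min(S) / 2)
}

#' Residual between an observed and a simulated curve
#'
#' Sum of squared differences of total-normalized concentrations; the
#' simulated curve is resampled onto the observed time grid by linear
#' interpolation.
#'
#' @param obs,sim Progress-curve tibbles (single, matching species).
#' @param total Normalizing pool total, uM; defaults to the maximum observed
#'   concentration.
#' @return Dimensionless residual.
#' @export
curve_residual <- function(obs, sim, total = NULL) {
  if (!identical(sort(unique(obs$species)), sort(unique(sim$species)))) {
    stop("observed and simulated curves monitor different species",
         call. = FALSE)
  }
  if (is.null(total)) total <- max(obs$conc_uM)
  y_sim <- stats::approx(sim$time_s, sim$conc_uM, xout = obs$time_s,
                         rule = 2, ties = "ordered")$y
  sum(((obs$conc_uM - y_sim) / total)^2)
}

.k_objective <- function(sets, which_curves, fixed, spec, env, thin = 1,
                         fix_k_A = NULL) {
  curves <- list()
  metas <- list()
  monit <- character(0)
  for (w in which_curves) {
    set <- sets[[w$set]]
    cv <- set$curves[[w$curve]]
    if (thin > 1) cv <- cv[seq(1, nrow(cv), by = thin), ]
    curves[[length(curves) + 1]] <- cv
    metas[[length(metas) + 1]] <- set$meta[w$curve, ]
    monit <- c(monit, set$monitored)
  }
  function(log10k) {
    k_A <- if (is.null(fix_k_A)) 10^log10k[2] else fix_k_A
    p <- kinetic_params(Vmf = fixed$Vmf, Km_D = fixed$Km_D,
                        Km_A = fixed$Km_A,
                        k_D = 10^log10k[1], k_A = k_A)
    tot <- 0
    for (i in seq_along(curves)) {
      m <- metas[[i]]
      sim <- tryCatch(
        simulate_assay(spec, p, D0 = m$D0, A0 = m$A0,
                       times = curves[[i]]$time_s, env = env),
        error = function(e) NULL)
      if (is.null(sim)) return(1e6)
      sim <- sim[sim$species == monit[i], ]
      tot <- tot + curve_residual(curves[[i]], sim,
                                  total = m$total_monitored)
    }
    tot
  }
}

#' Estimate the redox-state constants from progress curves
#'
#' Combined least-squares fit of the full rate-law simulation (with `Vmf`,
#' `Km_D`, `Km_A` already determined and `Vmr` pinned by the reference
#' equilibrium) to one or more total-normalized progress curves, over
#' `(k_D, k_A)` in log space with a multistart grid. Single-curve fits in
#' the symmetric regime are degenerate — several starts end within 1% of
#' the optimum at very different constants — which the multistart trace
#' documents; combined fitting across compositions removes the valley.
#'
#' @param sets List of [assay_set()] objects.
#' @param which_curves List of `list(set = <index>, curve = <index>)` pairs
#'   selecting the fitted curves.
#' @param fixed Named list with `Vmf`, `Km_D`, `Km_A`.
#' @param spec A [complex_spec()].
#' @param env A [thermo_env()].
#' @param grid Multistart values for each constant (log-spaced).
#' @param n_polish Number of best grid nodes refined by Nelder-Mead.
#' @param thin Keep every `thin`-th sample of each curve.
#' @return List with `k_D`, `k_A`, `residual`, `trace` (tibble over all
#'   starts), and `degenerate` (several near-optimal basins).
#' @export
fit_redox_constants <- function(sets, which_curves, fixed, spec,
                                env = thermo_env(),
                                grid = 10^seq(-3, 2, length.out = 5),
                                n_polish = 4, thin = 1, fix_k_A = NULL) {
  obj <- .k_objective(sets, which_curves, fixed, spec, env, thin, fix_k_A)
  if (!is.null(fix_k_A)) {
    # one free constant: the clamped-acceptor case (its k is a pure scale
    # factor and is adopted, not fitted)
    r0 <- vapply(grid, function(g) obj(log10(c(g, 1))), numeric(1))
    o <- stats::optimize(function(x) obj(c(x, 0)),
                         interval = log10(range(grid)) + c(-1, 1),
                         tol = 1e-10)
    trace <- tibble::tibble(start_k_D = grid, start_k_A = fix_k_A,
                            start_residual = r0, k_D_hat = NA_real_,
                            k_A_hat = NA_real_, residual = NA_real_)
    best_i <- which.min(r0)
    trace$k_D_hat[best_i] <- 10^o$minimum
    trace$k_A_hat[best_i] <- fix_k_A
    trace$residual[best_i] <- o$objective
    return(list(k_D = 10^o$minimum, k_A = fix_k_A,
                residual = o$objective, trace = trace,
                degenerate = FALSE))
  }
  nodes <- expand.grid(k_D = grid, k_A = grid)
  r0 <- apply(nodes, 1, function(g) obj(log10(as.numeric(g))))
  ord <- order(r0)
  polished <- lapply(ord[seq_len(min(n_polish, nrow(nodes)))], function(i) {
    o <- stats::optim(log10(as.numeric(nodes[i, ])), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10))
    list(i = i, par = o$par, value = o$value, conv = o$convergence)
  })
  if (all(vapply(polished, function(p) p$conv != 0, logical(1)))) {
    stop("redox-constant optimizer failed to converge from every start",
         call. = FALSE)
  }
  trace <- tibble::tibble(
    start_k_D = nodes$k_D, start_k_A = nodes$k_A, start_residual = r0,
    k_D_hat = NA_real_, k_A_hat = NA_real_, residual = NA_real_)
  for (p in polished) {
    trace$k_D_hat[p$i] <- 10^p$par[1]
    trace$k_A_hat[p$i] <- 10^p$par[2]
    trace$residual[p$i] <- p$value
  }
  best <- polished[[which.min(vapply(polished, function(p) p$value,
                                     numeric(1)))]]
  vals <- vapply(polished, function(p) p$value, numeric(1))
  pars <- do.call(rbind, lapply(polished, function(p) 10^p$par))
  near <- vals <= min(vals) * 1.01 + 1e-12
  spread <- if (sum(near) > 1) {
    max(apply(pars[near, , drop = FALSE], 2,
              function(col) max(col) / min(col)))
  } else 1
  list(k_D = 10^best$par[1], k_A = 10^best$par[2], residual = best$value,
       trace = trace, degenerate = spread > 2)
}

#' Two-stage kinetic parameter estimation for one complex
#'
#' The full estimation pipeline of the assay protocol: (1) initial
#' velocities of the donor-varied and acceptor-varied sets give the two
#' saturation constants and two apparent maxima; each maximum is corrected
#' for the finite saturation of its fixed co-substrate (using the Km from
#' the other set) and the corrected values are averaged into `Vmf`;
#' (2) the redox-state constants are estimated by combined least-squares
#' fitting of full simulated curves against several donor-varied traces,
#' with `Vmr` pinned by the reference equilibrium (six parameters reduced
#' to five).
#'
#' For complex IV the oxygen side is bulk-clamped: both sets vary the donor,
#' `Km_A` and `k_A` are adopted (`known_Km_A`, `known_k_A`) since a clamped
#' acceptor makes both pure scale factors, `Vmf` is corrected for both
#' acceptor-side factors at the bulk oxygen level, and only `k_D` is fitted
#' in the second stage.
#'
#' @param donor_set,second_set The two [assay_set()] objects of the complex.
#' @param spec A [complex_spec()].
#' @param env A [thermo_env()].
#' @param n_k_curves Number of donor-set curves used in the combined
#'   redox-constant fit.
#' @param known_Km_A Oxygen-side saturation constant used when no
#'   acceptor-varied set exists.
#' @param thin Curve thinning for the stage-2 objective.
#' @return An object of class `chemios_fit`.
#' @export
fit_etc_complex <- function(donor_set, second_set, spec,
                            env = thermo_env(), n_k_curves = 3,
                            known_Km_A = 1, known_k_A = 1, thin = 1) {
  stopifnot(donor_set$varied_side == "donor")
  satD <- fit_saturation(donor_set)
  has_acceptor <- second_set$varied_side == "acceptor"
  satA <- fit_saturation(second_set)
  Km_A <- if (has_acceptor) satA$Km else known_Km_A
  Km_D <- satD$Km
  # correct each fitted maximum for the fixed co-substrate's saturation
  if (has_acceptor) {
    VmfD <- satD$Vmax * (Km_A + donor_set$fixed_conc) / donor_set$fixed_conc
    VmfA <- satA$Vmax * (Km_D + second_set$fixed_conc) / second_set$fixed_conc
  } else {
    # clamped acceptor (bulk oxygen): both its saturation and redox-state
    # factors are constant scale factors at the bulk level
    A_bulk <- donor_set$fixed_conc
    corr <- ((Km_A + A_bulk) / A_bulk) * ((A_bulk + known_k_A) / A_bulk)
    VmfD <- satD$Vmax * corr
    VmfA <- satA$Vmax * corr
  }
  Vmf <- mean(c(VmfD, VmfA))

  # use the largest initial concentrations: those curves turn over enough of
  # the acceptor pool for both redox ratios to traverse their constants
  ord <- order(donor_set$meta$actual, decreasing = TRUE)
  sel <- lapply(ord[seq_len(min(n_k_curves, length(donor_set$curves)))],
                function(i) list(set = 1, curve = i))
  kfit <- fit_redox_constants(list(donor_set), sel,
                              fixed = list(Vmf = Vmf, Km_D = Km_D,
                                           Km_A = Km_A),
                              spec = spec, env = env, thin = thin,
                              fix_k_A = if (has_acceptor) NULL else
                                known_k_A)

  per_curve <- vapply(seq_along(sel), function(i) {
    w <- sel[[i]]
    m <- donor_set$meta[w$curve, ]
    p <- kinetic_params(Vmf = Vmf, Km_D = Km_D, Km_A = Km_A,
                        k_D = kfit$k_D, k_A = kfit$k_A)
    obs <- donor_set$curves[[w$curve]]
    obs <- obs[seq(1, nrow(obs), by = thin), ]   # same grid as the fit
    sim <- simulate_assay(spec, p, m$D0, m$A0, times = obs$time_s,
                          env = env)
    curve_residual(obs, sim[sim$species == donor_set$monitored, ],
                   total = m$total_monitored)
  }, numeric(1))

  structure(
    list(complex = spec$name,
         estimates = tibble::tibble(
           param = c("Vmf", "Km_D", "Km_A", "k_D", "k_A"),
           estimate = c(Vmf, Km_D, Km_A, kfit$k_D, kfit$k_A)),
         vmax_sets = c(donor = VmfD, second = VmfA),
         Km_A_fitted = has_acceptor,
         per_curve_residuals = per_curve,
         combined_residual = kfit$residual,
         trace = kfit$trace,
         degenerate = kfit$degenerate,
         saturation_flags = c(donor = satD$ill_conditioned,
                              second = satA$ill_conditioned)),
    class = "chemios_fit"
  )
}

#' @export
print.chemios_fit <- function(x, ...) {
  cat(sprintf("<chemios_fit %s> combined residual %.4g\n", x$complex,
              x$combined_residual))
  print(x$estimates)
  invisible(x)
}
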