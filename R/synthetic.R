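#' Synthetic assay design
#'
#' Describes one spectrophotometric assay set: which complex, which side is
#' varied and at which targeted (pipetted) initial concentrations, the
#' saturating fixed co-substrate level, the monitored species, and the noise
#' model — relative pipetting error on the targeted initial concentrations
#' and additive Gaussian measurement noise on the monitored trace.
#'
#' @param complex `"CI"`, `"CIII"` or `"CIV"`.
#' @param varied_side `"donor"` or `"acceptor"`.
#' @param targeted Positive, distinct targeted initial concentrations, uM.
#' @param fixed_conc Fixed co-substrate concentration, uM.
#' @param noise_sd_rel Additive noise standard deviation as a fraction of
#'   the monitored pool total.
#' @param pip_sd_rel Relative pipetting error standard deviation.
#' @param seed Integer seed; identical seeds give identical output.
#' @param dt Sampling interval, seconds; `NULL` (default) adapts the
#'   interval to each curve's predicted depletion time (about 400 samples
#'   over the main transition, clamped to [0.05, 2] s), the way an operator
#'   matches the spectrophotometer's sampling rate to the reaction speed.
#' @param t_max Hard cap on the assay duration, seconds.
#' @param depletion_frac Stop once this fraction of the initial substrate is
#'   consumed.
#' @param o2_uM Bulk oxygen for complex IV.
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(complex, varied_side, targeted, fixed_conc,
                         noise_sd_rel = 0.01, pip_sd_rel = 0.05,
                         seed = 1L, dt = NULL, t_max = 1800,
                         depletion_frac = 0.99, o2_uM = 200) {
  stopifnot(all(targeted > 0), !anyDuplicated(targeted),
            varied_side %in% c("donor", "acceptor"))
  structure(list(complex = complex, varied_side = varied_side,
                 targeted = targeted, fixed_conc = fixed_conc,
                 noise_sd_rel = noise_sd_rel, pip_sd_rel = pip_sd_rel,
                 seed = as.integer(seed), dt = dt, t_max = t_max,
                 depletion_frac = depletion_frac, o2_uM = o2_uM),
            class = "assay_design")
}

#' Generate one synthetic assay set
#'
#' For every targeted concentration: draws the actual initial concentration
#' as targeted times `1 + pipetting error`, simulates the closed reference
#' system until the substrate is depleted (or `t_max`), and adds i.i.d.
#' Gaussian noise to the monitored trace. Both targeted and actual values
#' are recorded. With zero noise and zero pipetting error, the curves equal
#' the plain simulation output.
#'
#' @param design An [assay_design()].
#' @param truth A [kinetic_params()] used as ground truth.
#' @param spec The matching [complex_spec()].
#' @param env A [thermo_env()].
#' @return An [assay_set()].
#' @export
generate_assay_set <- function(design, truth, spec, env = thermo_env()) {
  set.seed(design$seed)
  n <- length(design$targeted)
  pip <- stats::rnorm(n, 0, design$pip_sd_rel)
  monitored <- monitored_species(spec)
  curves <- vector("list", n)
  meta <- tibble::tibble(series_id = character(n), targeted = design$targeted,
                         actual = NA_real_, D0 = NA_real_, A0 = NA_real_,
                         total_monitored = NA_real_)
  for (i in seq_len(n)) {
    actual <- design$targeted[i] * (1 + pip[i])
    if (design$varied_side == "donor") {
      D0 <- actual; A0 <- design$fixed_conc
    } else {
      D0 <- design$fixed_conc; A0 <- actual
    }
    if (spec$name == "CIV") A0 <- design$o2_uM
    sid <- sprintf("%s_%s_%g", design$complex, design$varied_side,
                   design$targeted[i])
    if (is.null(design$dt)) {
      # adapt the sampling interval to the predicted depletion time
      J0 <- flux(carrier_state(D0, 0, A0,
                               if (spec$name == "CIV") 1 else 0),
                 spec, truth, env)$J
      turnovers <- D0 / spec$nu_D
      if (spec$name != "CIV") turnovers <- min(turnovers, A0 / spec$nu_A)
      t_rough <- turnovers / max(J0, 1e-12)
      dt_i <- min(2, max(0.05, t_rough / 400))
    } else {
      dt_i <- design$dt
    }
    times <- seq(0, design$t_max, by = dt_i)
    if (length(times) > 40000) times <- times[seq_len(40000)]
    full <- simulate_assay(spec, truth, D0, A0, times, env,
                           series_id = sid, o2_uM = design$o2_uM)
    # truncate once the limiting substrate is exhausted: check the donor and
    # (when not clamped) the acceptor against their own initial levels
    check <- list(c(spec$donor[["red"]], D0))
    if (spec$name != "CIV") check <- c(check, list(c(spec$acceptor[["ox"]],
                                                     A0)))
    t_end <- design$t_max
    for (ck in check) {
      tr <- full[full$species == ck[1], ]
      dep <- which(tr$conc_uM <= (1 - design$depletion_frac) *
                     as.numeric(ck[2]))
      if (length(dep)) t_end <- min(t_end, tr$time_s[dep[1]])
    }
    t_end <- max(t_end, 10 * dt_i)
    cv <- full[full$species == monitored & full$time_s <= t_end, ]
    total <- switch(spec$name, CI = D0, CIII = A0, CIV = D0)
    if (design$noise_sd_rel > 0) {
      cv$conc_uM <- cv$conc_uM +
        stats::rnorm(nrow(cv), 0, design$noise_sd_rel * total)
    }
    curves[[i]] <- cv
    meta$series_id[i] <- sid
    meta$actual[i] <- actual
    meta$D0[i] <- D0
    meta$A0[i] <- A0
    meta$total_monitored[i] <- total
  }
  assay_set(curves, meta, design$complex, design$varied_side,
            design$fixed_conc, monitored)
}

#' Default truth parameters of the reference experiments
#'
#' The synthetic stand-in kinetic parameter set used throughout the
#' package's reference analyses (see the methods vignette for how each value
#' is constrained).
#'
#' @return Named list of [kinetic_params()] for CI, CIII, CIV.
#' @export
reference_truth <- function() {
  list(CI = kinetic_params(Vmf = 0.40, Km_D = 5, Km_A = 20,
                           k_D = 0.03, k_A = 0.3),
       CIII = kinetic_params(Vmf = 0.55, Km_D = 10, Km_A = 5,
                             k_D = 0.1, k_A = 2),
       CIV = kinetic_params(Vmf = 0.52, Km_D = 10, Km_A = 1,
                            k_D = 3, k_A = 1))
}

#' The six reference assay designs
#'
#' Two assay sets per complex with the saturating co-substrate levels of the
#' reference experiments: CI donor-varied (CoQ fixed at 100 uM) and
#' acceptor-varied (NADH fixed at 100 uM, followed through the donor trace);
#' the CIII pair (cytochrome c at 50 uM / CoQ-side at 100 uM); and for CIV —
#' whose oxygen side is bulk-clamped and carries no saturation constant —
#' two donor-varied cytochrome-c designs on different targeted grids.
#'
#' @param seed Base seed; each design derives its own.
#' @param noise_sd_rel,pip_sd_rel Noise magnitudes (see [assay_design()]).
#' @return Named list of six [assay_design()] objects.
#' @export
reference_designs <- function(seed = 1L, noise_sd_rel = 0.01,
                              pip_sd_rel = 0.05) {
  d <- function(i, ...) assay_design(..., seed = seed + i,
                                     noise_sd_rel = noise_sd_rel,
                                     pip_sd_rel = pip_sd_rel)
  list(
    CI_donor = d(1, "CI", "donor",
                 targeted = c(1, 2, 5, 10, 25, 50, 75, 100),
                 fixed_conc = 100),
    CI_acceptor = d(2, "CI", "acceptor",
                    targeted = c(2, 5, 10, 20, 40, 80, 120, 160),
                    fixed_conc = 100),
    CIII_donor = d(3, "CIII", "donor",
                   targeted = c(1, 2, 5, 10, 25, 50, 75, 100),
                   fixed_conc = 50),
    CIII_acceptor = d(4, "CIII", "acceptor",
                      targeted = c(1, 2, 5, 10, 20, 30, 40, 50),
                      fixed_conc = 100),
    CIV_donor = d(5, "CIV", "donor",
                  targeted = c(1, 2, 5, 10, 20, 30, 40, 50),
                  fixed_conc = 200),
    CIV_donor2 = d(6, "CIV", "donor",
                   targeted = c(1.5, 3, 7, 15, 25, 35, 45, 50),
                   fixed_conc = 200)
  )
}

#' Generate the full six-set reference assay suite
#'
#' @param truth Named list of per-complex [kinetic_params()]; defaults to
#'   [reference_truth()].
#' @param seed Base seed.
#' @param env A [thermo_env()].
#' @param noise_sd_rel,pip_sd_rel Noise magnitudes.
#' @return Named list of six [assay_set()] objects.
#' @export
reference_experiment_suite <- function(truth = reference_truth(), seed = 1L,
                                       env = thermo_env(),
                                       noise_sd_rel = 0.01,
                                       pip_sd_rel = 0.05) {
  designs <- reference_designs(seed, noise_sd_rel, pip_sd_rel)
  lapply(designs, function(dg)
    generate_assay_set(dg, truth[[dg$complex]], etc_complex(dg$complex),
                       env))
}
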