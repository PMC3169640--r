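#' Thermodynamic environment
#'
#' Bundles the physical constants and membrane state shared by every rate-law
#' evaluation. The reference system is a membrane-fragmented (homogenate)
#' preparation: no compartmentalization, so the proton-motive force is zero
#' and `dPsi`/`dpH` must be zero when `membrane_intact = FALSE`.
#'
#' @param temperature Absolute temperature in kelvin.
#' @param dPsi Membrane electrical potential (P side minus N side), millivolts.
#' @param dpH pH difference across the membrane (inside minus outside).
#' @param membrane_intact Logical; `FALSE` selects the reference (homogenate)
#'   system in which the pmf is identically zero.
#' @return An object of class `thermo_env`.
#' @export
thermo_env <- function(temperature = 310.15, dPsi = 0, dpH = 0,
                       membrane_intact = FALSE) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature > 0)
  if (!membrane_intact && (dPsi != 0 || dpH != 0)) {
    stop("reference system (membrane_intact = FALSE) requires dPsi = 0 and dpH = 0",
         call. = FALSE)
  }
  structure(
    list(temperature = temperature,
         R = 8.314,        # J/(mol K)
         F = 96485,        # C/mol
         dPsi = dPsi,      # mV
         dpH = dpH,
         membrane_intact = membrane_intact),
    class = "thermo_env"
  )
}

#' RT in J/mol for an environment
#' @param env A [thermo_env()].
#' @return Numeric scalar, J/mol.
#' @export
rt_energy <- function(env) env$R * env$temperature

#' Specification of one electron-transport-chain complex
#'
#' Describes the overall transduction reaction of a prototypical
#' electron-proton pump: how many electrons per turnover, how many protons
#' are translocated, whether the electron itself crosses the membrane, the
#' standard midpoint potential span between the donor and acceptor carrier
#' pairs, and the signed stoichiometry that couples the complex to its
#' carrier pools.
#'
#' @param name Identifier, e.g. `"CI"`.
#' @param n_e Electrons transferred per turnover (>= 1).
#' @param n_H Protons translocated per turnover (>= 0).
#' @param q Membrane-crossing switch for the electron: +1 if it crosses from
#'   the N to the P side, -1 for the opposite direction, 0 if it does not
#'   cross.
#' @param dE0 Standard midpoint redox potential difference between acceptor
#'   and donor pairs, millivolts.
#' @param donor,acceptor Length-2 named character vectors giving the species
#'   ids of the redox pair, e.g. `c(red = "NADH", ox = "NAD")` for the donor
#'   and `c(ox = "Q", red = "QH2")` for the acceptor.
#' @param nu_D,nu_A Positive stoichiometric coefficients of the donor and
#'   acceptor carriers per turnover.
#' @return An object of class `complex_spec`.
#' @export
complex_spec <- function(name, n_e, n_H, q, dE0, donor, acceptor,
                         nu_D = 1, nu_A = 1) {
  stopifnot(n_e >= 1, n_e == as.integer(n_e), q %in% c(-1, 0, 1),
            n_H >= 0, nu_D > 0, nu_A > 0,
            all(c("red", "ox") %in% names(donor)),
            all(c("ox", "red") %in% names(acceptor)))
  structure(
    list(name = name, n_e = n_e, n_H = n_H, q = q, dE0 = dE0,
         donor = donor, acceptor = acceptor, nu_D = nu_D, nu_A = nu_A),
    class = "complex_spec"
  )
}

#' Built-in ETC complex specifications
#'
#' Returns the reaction stoichiometry and thermodynamic constants for the
#' three proton-pumping respiratory complexes. Midpoint spans (mV): CI
#' 359.49 (NAD pair to CoQ pair), CIII 168.58 (CoQ to cytochrome c), CIV
#' 318.55 (cytochrome c to O2/H2O). Electron/proton stoichiometry per
#' two-electron turnover: CI (2, 0, 4), CIII (2, -1, 4), CIV (2, 0, 2) as
#' (n_e, q, n_H).
#'
#' @param name One of `"CI"`, `"CIII"`, `"CIV"`.
#' @return A [complex_spec()].
#' @export
etc_complex <- function(name = c("CI", "CIII", "CIV")) {
  name <- match.arg(name)
  switch(name,
    CI = complex_spec("CI", n_e = 2, n_H = 4, q = 0, dE0 = 359.49,
                      donor = c(red = "NADH", ox = "NAD"),
                      acceptor = c(ox = "Q", red = "QH2"),
                      nu_D = 1, nu_A = 1),
    CIII = complex_spec("CIII", n_e = 2, n_H = 4, q = -1, dE0 = 168.58,
                        donor = c(red = "QH2", ox = "Q"),
                        acceptor = c(ox = "ccox", red = "ccred"),
                        nu_D = 1, nu_A = 2),
    CIV = complex_spec("CIV", n_e = 2, n_H = 2, q = 0, dE0 = 318.55,
                       donor = c(red = "ccred", ox = "ccox"),
                       acceptor = c(ox = "O2", red = "H2O"),
                       nu_D = 2, nu_A = 0.5)
  )
}

#' Kinetic parameters of the chemiosmotic rate law
#'
#' The six experimentally determinable parameters (`Vmf`, `Vmr`, `Km_D`,
#' `Km_A`, `k_D`, `k_A`) plus the transformation parameters: slippage
#' efficiency `eff` and the force-partition fractions. `Vmr` may be omitted,
#' in which case it is derived from the reference-system equilibrium constant
#' (see [vmr_from_equilibrium()]). A supplied `Vmr` inconsistent with that
#' relation by more than 1% triggers a warning (deliberately non-reference
#' systems are allowed).
#'
#' @param Vmf Apparent maximum forward velocity, concentration/time (uM/s).
#' @param Km_D,Km_A Saturation (Michaelis-Menten-like) constants, uM.
#' @param k_D,k_A Dimensionless redox-state constants (>= 0).
#' @param Vmr Optional apparent maximum reverse velocity, uM/s.
#' @param eff Slippage efficiency in [0, 1]; 1 means no slip.
#' @param lam Force-partition fraction in [0, 1] for added forces such as the
#'   pmf: `lam = 1` leaves the forward flux unaltered, `lam = 0` the reverse.
#' @param lam_slip Force-partition fraction used for the slippage force.
#'   Defaults to 1: slippage enhances the back-flux through the short-circuit
#'   path while the forward catalytic machinery is untouched.
#' @param mechanism Binding mechanism of the saturation factor: `"parallel"`
#'   (two independent hyperbolic factors), `"ordered_sequential"` or
#'   `"random_sequential"`.
#' @param mech_dissoc Optional named list of dissociation constants for the
#'   sequential mechanisms: `Ki_D`, `Ki_A` (binary) and `K_D`, `K_A`
#'   (ternary). When missing, `Km_D`/`Km_A` are reused for the binary steps
#'   and ternary = binary, which keeps the three mechanisms comparable on the
#'   same six parameters.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(Vmf, Km_D, Km_A, k_D, k_A, Vmr = NULL,
                           eff = 1, lam = 0.5, lam_slip = 1,
                           mechanism = c("parallel", "ordered_sequential",
                                         "random_sequential"),
                           mech_dissoc = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(Vmf > 0, Km_D > 0, Km_A > 0, k_D >= 0, k_A >= 0,
            eff >= 0, eff <= 1, lam >= 0, lam <= 1,
            lam_slip >= 0, lam_slip <= 1)
  if (!is.null(Vmr)) stopifnot(Vmr > 0)
  structure(
    list(Vmf = Vmf, Vmr = Vmr, Km_D = Km_D, Km_A = Km_A,
         k_D = k_D, k_A = k_A, eff = eff, lam = lam, lam_slip = lam_slip,
         mechanism = mechanism, mech_dissoc = mech_dissoc),
    class = "kinetic_params"
  )
}

#' Redox carrier pool state
#'
#' Concentrations of the four external carrier species around one complex.
#' Totals and the redox ratios r_D = Dred/Dox and r_A = Aox/Ared are derived;
#' ratio denominators are guarded by epsilon seeding (each product species is
#' assumed present at least at `eps` times its pool total, mirroring the
#' small product amount created during the pre-steady-state transient).
#'
#' @param Dred,Dox Reduced/oxidized donor carrier concentrations, uM.
#' @param Aox,Ared Oxidized/reduced acceptor carrier concentrations, uM.
#' @return An object of class `carrier_state`.
#' @export
carrier_state <- function(Dred, Dox, Aox, Ared) {
  conc <- c(Dred = Dred, Dox = Dox, Aox = Aox, Ared = Ared)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("carrier concentrations must be finite and nonnegative", call. = FALSE)
  }
  structure(as.list(conc), class = "carrier_state")
}

#' Redox ratios of a carrier state
#'
#' @param state A [carrier_state()].
#' @param eps Seeding fraction: every species is floored at `eps` times its
#'   pool total before the ratios are formed, so the ratios are always finite.
#' @return Named numeric vector `c(r_D, r_A)`.
#' @export
redox_ratios <- function(state, eps = 1e-9) {
  D_tot <- state$Dred + state$Dox
  A_tot <- state$Aox + state$Ared
  if (D_tot <= 0 || A_tot <= 0) {
    stop("carrier pool totals must be positive to form redox ratios",
         call. = FALSE)
  }
  floor_D <- eps * D_tot
  floor_A <- eps * A_tot
  c(r_D = max(state$Dred, floor_D) / max(state$Dox, floor_D),
    r_A = max(state$Aox, floor_A) / max(state$Ared, floor_A))
}

#' @export
print.complex_spec <- function(x, ...) {
  cat(sprintf("<complex_spec %s> n_e=%d n_H=%g q=%+d dE0=%.2f mV (%s/%s -> %s/%s)\n",
              x$name, x$n_e, x$n_H, x$q, x$dE0,
              x$donor[["red"]], x$donor[["ox"]],
              x$acceptor[["ox"]], x$acceptor[["red"]]))
  invisible(x)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> Vmf=%.4g Vmr=%s Km_D=%.4g Km_A=%.4g k_D=%.4g k_A=%.4g eff=%.3g (%s)\n",
    x$Vmf, if (is.null(x$Vmr)) "auto" else sprintf("%.4g", x$Vmr),
    x$Km_D, x$Km_A, x$k_D, x$k_A, x$eff, x$mechanism))
  invisible(x)
}
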