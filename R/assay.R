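#' Single-complex closed assay model
#'
#' A one-complex network representing the cuvette: closed for the carrier
#' pools, with oxygen (and water activity) clamped for complex IV.
#'
#' @param spec A [complex_spec()].
#' @param params A [kinetic_params()].
#' @param env A [thermo_env()].
#' @param o2_uM Bulk oxygen for complex IV assays.
#' @return An [etc_network()].
#' @export
closed_assay_model <- function(spec, params, env = thermo_env(),
                               o2_uM = 200) {
  clamps <- if (spec$name == "CIV") c(O2 = o2_uM, H2O = 1) else numeric(0)
  etc_network(list(list(spec = spec, params = params)), clamps = clamps,
              env = env)
}

#' Initial concentrations of a closed assay
#'
#' Donor pool fully reduced at `D0`, acceptor pool fully oxidized at `A0`
#' (ignored for complex IV, whose acceptor is clamped).
#'
#' @inheritParams closed_assay_model
#' @param D0,A0 Initial reduced-donor and oxidized-acceptor concentrations,
#'   uM.
#' @return Named numeric vector of initial concentrations.
#' @export
assay_init <- function(spec, D0, A0) {
  init <- c(D0, 0, A0, 0)
  names(init) <- c(spec$donor[["red"]], spec$donor[["ox"]],
                   spec$acceptor[["ox"]], spec$acceptor[["red"]])
  init
}

#' Monitored species of the standard assay
#'
#' NADH for complex I (both assay sets follow the donor trace), reduced
#' cytochrome c for complexes III and IV.
#'
#' @param spec A [complex_spec()].
#' @return Species id.
#' @export
monitored_species <- function(spec) {
  switch(spec$name, CI = "NADH", CIII = "ccred", CIV = "ccred",
         spec$donor[["red"]])
}

#' Simulate one closed assay progress curve
#'
#' @inheritParams closed_assay_model
#' @inheritParams assay_init
#' @param times Time grid, seconds.
#' @param series_id Identifier for the output curve.
#' @return Progress-curve tibble (all species).
#' @export
simulate_assay <- function(spec, params, D0, A0, times, env = thermo_env(),
                           series_id = "assay", o2_uM = 200) {
  model <- closed_assay_model(spec, params, env, o2_uM)
  simulate_network(model, assay_init(spec, D0, A0), times,
                   series_id = series_id)
}

#' Assemble an assay set
#'
#' A collection of progress curves from one assay design (one varied side,
#' fixed co-substrate), with the targeted and actual initial concentrations
#' carried alongside.
#'
#' @param curves List of progress-curve tibbles (monitored species).
#' @param meta Tibble with one row per curve: `series_id`, `targeted`,
#'   `actual`, `D0`, `A0`, `total_monitored`.
#' @param complex Complex name.
#' @param varied_side `"donor"` or `"acceptor"`.
#' @param fixed_conc Fixed co-substrate concentration, uM.
#' @param monitored Monitored species id.
#' @return An object of class `assay_set`.
#' @export
assay_set <- function(curves, meta, complex, varied_side, fixed_conc,
                      monitored) {
  stopifnot(varied_side %in% c("donor", "acceptor"),
            length(curves) == nrow(meta))
  structure(list(curves = curves, meta = meta, complex = complex,
                 varied_side = varied_side, fixed_conc = fixed_conc,
                 monitored = monitored),
            class = "assay_set")
}

#' @export
print.assay_set <- function(x, ...) {
  cat(sprintf("<assay_set %s, %s-varied, %d curves, fixed co-substrate %g uM, monitoring %s>\n",
              x$complex, x$varied_side, length(x$curves), x$fixed_conc,
              x$monitored))
  invisible(x)
}
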