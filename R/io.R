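#' Write progress curves to CSV
#'
#' Columns `time_s, species, conc_uM, series_id`, full double precision,
#' '.' decimal separator.
#'
#' @param curves Progress-curve tibble (possibly several series).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_progress_csv <- function(curves, path) {
  need <- c("time_s", "species", "conc_uM", "series_id")
  stopifnot(all(need %in% names(curves)))
  df <- as.data.frame(curves)[, need]
  df$time_s <- format(df$time_s, digits = 15, trim = TRUE,
                      scientific = FALSE)
  df$conc_uM <- format(df$conc_uM, digits = 15, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read progress curves from CSV
#'
#' Validates the column set, numeric types, time monotonicity (after a
#' canonical sort by series, species and time) and nonnegativity of the
#' concentrations; validation errors name the offending row numbers.
#'
#' @param path CSV file path.
#' @return Progress-curve tibble sorted canonically.
#' @export
read_progress_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "species", "conc_uM", "series_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$time_s) || !is.numeric(df$conc_uM)) {
    stop("time_s and conc_uM must be numeric", call. = FALSE)
  }
  bad <- which(df$conc_uM < 0)
  if (length(bad)) {
    stop("negative concentration at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$series_id, df$species, df$time_s), ]
  dup <- by(df, list(df$series_id, df$species),
            function(g) any(diff(g$time_s) <= 0))
  if (any(unlist(dup), na.rm = TRUE)) {
    stop("non-monotone or duplicated time points within a series",
         call. = FALSE)
  }
  tibble::as_tibble(df[, need])
}

#' Structured log line to stderr
#'
#' @param level Log level string.
#' @param stage Pipeline stage label.
#' @param ... Message parts.
#' @keywords internal
log_msg <- function(level, stage, ...) {
  message(sprintf("[%s] %s %s: %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, stage,
                  paste0(..., collapse = "")))
}

.config_schema <- list(
  top = c("seed", "environment", "network", "analysis", "output"),
  environment = c("temperature", "dPsi", "dpH", "membrane_intact"),
  network = c("complexes", "pools", "clamps", "drive"),
  complex = c("name", "Vmf", "Km_D", "Km_A", "k_D", "k_A", "eff", "Vmr",
              "mechanism"),
  drive = c("red", "ox", "k", "factor", "reversible", "keq"),
  analysis = c("n_grid", "fcc_params", "threshold_param", "eff_grid",
               "tol_pct", "thin")
)

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

#' Read and validate a run configuration
#'
#' YAML document describing the environment, the network (complexes with
#' kinetic parameters, pool totals, clamps, drive) and analysis settings.
#' Unknown keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  .check_keys(cfg, .config_schema$top, "config")
  if (!is.null(cfg$environment)) {
    .check_keys(cfg$environment, .config_schema$environment, "environment")
  }
  if (!is.null(cfg$network)) {
    .check_keys(cfg$network, .config_schema$network, "network")
    for (cx in cfg$network$complexes %||% list()) {
      .check_keys(cx, .config_schema$complex, paste0("complex ", cx$name))
      if (is.null(cx$name)) stop("complex entry lacks a name", call. = FALSE)
    }
    if (!is.null(cfg$network$drive)) {
      .check_keys(cfg$network$drive, .config_schema$drive, "drive")
    }
  }
  if (!is.null(cfg$analysis)) {
    .check_keys(cfg$analysis, .config_schema$analysis, "analysis")
  }
  structure(cfg, class = "run_config")
}

#' Build a network from a configuration
#'
#' @param cfg A [read_run_config()] result (or equivalent list).
#' @return List with `model`, `totals` and `env`, as for
#'   [reference_network()].
#' @export
config_to_network <- function(cfg) {
  ev <- cfg$environment %||% list()
  env <- thermo_env(temperature = ev$temperature %||% 310.15,
                    dPsi = ev$dPsi %||% 0, dpH = ev$dpH %||% 0,
                    membrane_intact = isTRUE(ev$membrane_intact))
  nw <- cfg$network %||% list()
  base <- reference_network(env = env)
  if (is.null(nw$complexes)) {
    complexes <- base$model$complexes
  } else {
    complexes <- lapply(nw$complexes, function(cx) {
      spec <- etc_complex(cx$name)
      defaults <- reference_truth()[[cx$name]]
      list(spec = spec,
           params = kinetic_params(
             Vmf = cx$Vmf %||% defaults$Vmf,
             Km_D = cx$Km_D %||% defaults$Km_D,
             Km_A = cx$Km_A %||% defaults$Km_A,
             k_D = cx$k_D %||% defaults$k_D,
             k_A = cx$k_A %||% defaults$k_A,
             eff = cx$eff %||% 1,
             Vmr = cx$Vmr,
             mechanism = cx$mechanism %||% "parallel"))
    })
  }
  clamps <- unlist(nw$clamps %||% list(O2 = 200, H2O = 1))
  pools <- unlist(nw$pools %||% list(NAD = 100, Q = 100, cc = 50))
  dr <- nw$drive
  vmf1 <- complexes[[1]]$params$Vmf
  drive <- if (is.null(dr)) {
    drive_spec("NADH", "NAD", k = 10 * vmf1 / pools[[1]])
  } else {
    drive_spec(dr$red %||% "NADH", dr$ox %||% "NAD",
               k = dr$k %||% ((dr$factor %||% 10) * vmf1 / pools[[1]]),
               reversible = isTRUE(dr$reversible), keq = dr$keq %||% 100)
  }
  model <- etc_network(complexes, clamps = clamps, drive = drive, env = env)
  totals <- c(NADH = unname(pools["NAD"]), NAD = 0,
              Q = unname(pools["Q"]), QH2 = 0,
              ccox = unname(pools["cc"]), ccred = 0)
  list(model = model, totals = totals, env = env)
}

.cli_usage <- function() {
  paste(
    "usage: chemios <subcommand> [--key value ...]",
    "subcommands:",
    "  simulate  --config <yaml> --out <csv> [--tmax S] [--dt S]",
    "  fit       --assay-dir <dir> --complex <CI|CIII|CIV> --out <json>",
    "  compare   --curve <csv> --complex <name> --d0 <uM> --a0 <uM> --out <json>",
    "  fcc       --config <yaml> --out <csv>",
    "  threshold --config <yaml> --complex <name> --param <name> --out <csv>",
    "  generate  --seed <int> --out <dir> [--noise sd_rel] [--pip sd_rel]",
    sep = "\n")
}

.cli_args <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    key <- argv[i]
    if (!startsWith(key, "--") || i == length(argv)) {
      stop("malformed argument: ", key, call. = FALSE)
    }
    out[[substring(key, 3)]] <- argv[i + 1]
    i <- i + 2
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `fit`, `compare`, `fcc`, `threshold` and
#' `generate` subcommands, writing outputs to the requested paths and a
#' structured log to stderr. Returns (rather than calls) the exit status:
#' 0 on success, 2 on bad arguments, 1 on computational failure.
#'
#' @param argv Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status.
#' @export
cli_main <- function(argv) {
  sub <- argv[1]
  known <- c("simulate", "fit", "compare", "fcc", "threshold", "generate")
  if (is.na(sub) || !(sub %in% known)) {
    message(.cli_usage())
    return(2L)
  }
  args <- tryCatch(.cli_args(argv[-1]), error = function(e) {
    message(conditionMessage(e)); message(.cli_usage()); NULL
  })
  if (is.null(args)) return(2L)

  run <- function() {
    switch(sub,
      simulate = {
        cfg <- read_run_config(args$config)
        nw <- config_to_network(cfg)
        tmax <- as.numeric(args$tmax %||% 600)
        dt <- as.numeric(args$dt %||% 1)
        log_msg("INFO", "simulate", "integrating to ", tmax, " s")
        out <- simulate_network(nw$model, nw$totals, seq(0, tmax, by = dt))
        write_progress_csv(out, args$out)
      },
      fit = {
        files <- sort(list.files(args[["assay-dir"]], pattern = "\\.csv$",
                                 full.names = TRUE))
        sets <- lapply(files, .read_assay_csv)
        sets <- Filter(function(s) s$complex == args$complex, sets)
        if (length(sets) < 2) stop("need the two assay sets of ",
                                   args$complex)
        donor <- Filter(function(s) s$varied_side == "donor", sets)[[1]]
        second <- if (any(vapply(sets, function(s)
          s$varied_side == "acceptor", logical(1)))) {
          Filter(function(s) s$varied_side == "acceptor", sets)[[1]]
        } else sets[[2]]
        log_msg("INFO", "fit", "fitting ", args$complex)
        ft <- fit_etc_complex(donor, second, etc_complex(args$complex),
                              thin = as.integer(args$thin %||% "3"))
        jsonlite::write_json(list(
          complex = ft$complex,
          estimates = ft$estimates,
          vmax_sets = as.list(ft$vmax_sets),
          per_curve_residuals = ft$per_curve_residuals,
          combined_residual = ft$combined_residual,
          multistart_trace = ft$trace), args$out, auto_unbox = TRUE,
          digits = NA)
      },
      compare = {
        curve <- read_progress_csv(args$curve)
        spec <- etc_complex(args$complex)
        truth <- reference_truth()[[args$complex]]
        cmp <- compare_models(curve, spec, as.numeric(args$d0),
                              as.numeric(args$a0),
                              Km = c(Km_D = truth$Km_D, Km_A = truth$Km_A),
                              thin = as.integer(args$thin %||% "2"))
        jsonlite::write_json(list(
          model = cmp$model, residual = cmp$residual,
          params = cmp$params), args$out, auto_unbox = TRUE, digits = NA)
      },
      fcc = {
        cfg <- read_run_config(args$config)
        nw <- config_to_network(cfg)
        log_msg("INFO", "fcc", "computing control coefficients")
        ft <- fcc_table(nw$model, nw$totals)
        utils::write.csv(as.data.frame(ft), args$out, row.names = FALSE)
      },
      threshold = {
        cfg <- read_run_config(args$config)
        nw <- config_to_network(cfg)
        cv <- threshold_curve(nw$model, nw$totals, args$complex,
                              args$param %||% "Vmf")
        utils::write.csv(as.data.frame(cv), args$out, row.names = FALSE)
      },
      generate = {
        suite <- reference_experiment_suite(
          seed = as.integer(args$seed %||% "1"),
          noise_sd_rel = as.numeric(args$noise %||% "0.01"),
          pip_sd_rel = as.numeric(args$pip %||% "0.05"))
        dir.create(args$out, showWarnings = FALSE, recursive = TRUE)
        for (nm in names(suite)) {
          .write_assay_csv(suite[[nm]],
                           file.path(args$out, paste0(nm, ".csv")))
        }
      }
    )
    invisible(NULL)
  }
  status <- tryCatch({ run(); 0L },
    error = function(e) {
      log_msg("ERROR", sub, conditionMessage(e))
      1L
    })
  if (status == 0L) log_msg("INFO", sub, "done")
  status
}

# assay-set CSV dialect: progress CSV plus a commented header carrying the
# set metadata
.write_assay_csv <- function(set, path) {
  hdr <- sprintf("# complex=%s varied_side=%s fixed_conc=%g monitored=%s",
                 set$complex, set$varied_side, set$fixed_conc,
                 set$monitored)
  meta <- sprintf("# series %s targeted=%.10g actual=%.10g D0=%.10g A0=%.10g total=%.10g",
                  set$meta$series_id, set$meta$targeted, set$meta$actual,
                  set$meta$D0, set$meta$A0, set$meta$total_monitored)
  con <- file(path, "w")
  writeLines(c(hdr, meta), con)
  close(con)
  df <- do.call(rbind, lapply(set$curves, as.data.frame))
  df$time_s <- format(df$time_s, digits = 15, trim = TRUE,
                      scientific = FALSE)
  df$conc_uM <- format(df$conc_uM, digits = 15, trim = TRUE)
  suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}

.read_assay_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  tc <- textConnection(body)
  df <- utils::read.csv(tc, stringsAsFactors = FALSE)
  close(tc)
  kv <- strsplit(sub("^# ", "", hdr[1]), " ")[[1]]
  kvl <- stats::setNames(lapply(strsplit(kv, "="), `[`, 2),
                         vapply(strsplit(kv, "="), `[`, character(1), 1))
  meta_lines <- hdr[startsWith(hdr, "# series")]
  meta <- do.call(rbind, lapply(meta_lines, function(ln) {
    parts <- strsplit(sub("^# series ", "", ln), " ")[[1]]
    vals <- vapply(strsplit(parts[-1], "="), `[`, character(1), 2)
    data.frame(series_id = parts[1], targeted = as.numeric(vals[1]),
               actual = as.numeric(vals[2]), D0 = as.numeric(vals[3]),
               A0 = as.numeric(vals[4]),
               total_monitored = as.numeric(vals[5]))
  }))
  curves <- lapply(meta$series_id, function(sid) {
    tibble::as_tibble(df[df$series_id == sid,
                         c("time_s", "species", "conc_uM", "series_id")])
  })
  assay_set(curves, tibble::as_tibble(meta), kvl$complex, kvl$varied_side,
            as.numeric(kvl$fixed_conc), kvl$monitored)
}
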