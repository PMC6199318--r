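#' Build a run configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()]:
#' model variant and size, rate constants, disorder, titration grid,
#' simulation counts, detection thresholds and output location. Unknown keys
#' are rejected. The resolved configuration is serializable to JSON
#' ([write_config()] / [read_config()]) and is emitted alongside every
#' pipeline run.
#'
#' @param variant Reaction scheme, `"model1"` or `"model2"`.
#' @param n_sites Nucleotides degraded between the dyes.
#' @param rates Named list or [rate_constants()] with `kB_off`, `kB_b`,
#'   `kA_off`, `kA_b`.
#' @param sigma,n_draws Disorder width (kB*T) and number of prediction draws.
#' @param concentrations Titration grid, mM.
#' @param n_traces Simulated traces per concentration.
#' @param pause_s,report_s Pause stall and reporting thresholds, seconds.
#' @param low_frac,high_frac Velocity-measurement thresholds.
#' @param frame_dt,noise_sd FRET synthesis settings.
#' @param kaoff_candidates Grid-search candidates, s^-1.
#' @param kaoff_concentrations Conditions used for the histogram comparison.
#' @param hist_edges Bin edges in zeta for the histogram comparison.
#' @param grid_points Master-equation time-grid size.
#' @param seed Seed for all stochastic stages.
#' @param out_dir Output directory (created if missing).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(variant = "model1", n_sites = 20,
                       rates = lambda_rates(), sigma = 0.5, n_draws = 5000,
                       concentrations = mg_concentrations(), n_traces = 30,
                       pause_s = 2, report_s = 10,
                       low_frac = 0.05, high_frac = 0.95,
                       frame_dt = 0.1, noise_sd = 0.05,
                       kaoff_candidates = c(0.01, 0.1, 1),
                       kaoff_concentrations = c(0.03, 0.1, 0.3, 3),
                       hist_edges = seq(-3, 2, by = 0.1),
                       grid_points = 400,
                       seed = 1L, out_dir = tempfile("lexokin_run_")) {
  if (inherits(rates, "rate_constants")) rates <- unclass(rates)
  cfg <- list(variant = variant, n_sites = n_sites, rates = rates,
              sigma = sigma, n_draws = n_draws,
              concentrations = concentrations, n_traces = n_traces,
              pause_s = pause_s, report_s = report_s,
              low_frac = low_frac, high_frac = high_frac,
              frame_dt = frame_dt, noise_sd = noise_sd,
              kaoff_candidates = kaoff_candidates,
              kaoff_concentrations = kaoff_concentrations,
              hist_edges = hist_edges, grid_points = grid_points,
              seed = seed, out_dir = out_dir)
  validate_config(cfg)
}

config_keys <- function() names(formals(run_config))

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_keys())
  if (length(unknown) > 0L) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(config_keys(), names(cfg))
  if (length(missing) > 0L) {
    defaults <- formals(run_config)
    for (k in missing) cfg[[k]] <- eval(defaults[[k]])
  }
  # type/shape checks piggy-back on the constructors
  rate_constants(cfg$rates$kB_off, cfg$rates$kB_b, cfg$rates$kA_off,
                 cfg$rates$kA_b)
  stopifnot(cfg$variant %in% c("model1", "model2"),
            cfg$n_sites >= 1, cfg$sigma >= 0, cfg$n_traces >= 1,
            all(cfg$concentrations > 0), cfg$pause_s > 0,
            cfg$report_s >= cfg$pause_s, cfg$low_frac < cfg$high_frac)
  structure(cfg[config_keys()], class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

cfg_rates <- function(cfg) {
  rate_constants(cfg$rates$kB_off, cfg$rates$kB_b, cfg$rates$kA_off,
                 cfg$rates$kA_b)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> measure -> fit -> estimate -> pause statistics on
#' synthetic data and writes a JSON report plus intermediate files to
#' `cfg$out_dir`. Stages:
#' 1. simulate: Gillespie trajectories with quenched disorder at each
#'    concentration; FRET traces synthesized for each trajectory.
#' 2. measure: per-trace velocities from the FRET traces (threshold
#'    crossing), assembled into a velocity dataset (written as CSV).
#' 3. fit: velocity-curve fits (model1 / MM / Hill) on condition means.
#' 4. estimate: grid-search for `kA_off` from log10-velocity histograms.
#' 5. pauses: pause extraction at the lowest concentration and summary
#'    statistics.
#'
#' Any stage failure aborts with the stage name; files already written are
#' preserved.
#'
#' @param cfg A [run_config()] (or a path to a JSON config).
#' @return The report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- object_hash(unclass(cfg))
  write_config(cfg, file.path(cfg$out_dir, "config.json"))
  rates <- cfg_rates(cfg)
  spec <- model_spec(cfg$variant, cfg$n_sites, rates)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", cfg$out_dir, ")", call. = FALSE)
    })
  }

  result <- with_seed(cfg$seed, {
    trajs <- stage("simulate", {
      out <- list()
      for (mg in cfg$concentrations) {
        out[[as.character(mg)]] <- lapply(seq_len(cfg$n_traces), function(i) {
          fac <- exp(-stats::rnorm(1, 0, cfg$sigma))
          simulate_trajectory(
            model_spec(cfg$variant, cfg$n_sites, scale_rates(rates, fac)), mg)
        })
      }
      out
    })

    measured <- stage("measure", {
      rows <- list()
      for (mg_chr in names(trajs)) {
        for (i in seq_along(trajs[[mg_chr]])) {
          tr <- trajectory_to_fret(trajs[[mg_chr]][[i]],
                                   frame_dt = cfg$frame_dt,
                                   noise_sd = cfg$noise_sd)
          v <- measure_velocity_from_trace(tr, cfg$low_frac, cfg$high_frac)
          if (is.finite(v)) {
            rows[[length(rows) + 1L]] <- data.frame(
              mg_mM = as.numeric(mg_chr), velocity_nt_s = v,
              trace_id = sprintf("mg%s_%04d", mg_chr, i),
              stringsAsFactors = FALSE)
          }
        }
      }
      ds <- do.call(rbind, rows)
      class(ds) <- c("velocity_dataset", "data.frame")
      write_velocity_dataset(ds, file.path(cfg$out_dir, "velocities.csv"))
      ds
    })

    fits <- stage("fit", {
      lapply(stats::setNames(nm = c("model1", "mm", "hill")), function(m)
        fit_velocity_curve(measured, model = m))
    })

    est <- stage("estimate", {
      obs <- list()
      for (mg in cfg$kaoff_concentrations) {
        v <- measured$velocity_nt_s[measured$mg_mM == mg]
        if (length(v) == 0L) next
        obs[[as.character(mg)]] <- suppressWarnings(
          logv_histogram(v, cfg$hist_edges))
      }
      estimate_kAoff(cfg$kaoff_candidates, obs, rates,
                     disorder_spec(cfg$sigma, cfg$n_draws, seed = cfg$seed),
                     n_sites = cfg$n_sites, variant = cfg$variant)
    })

    pstats <- stage("pauses", {
      mg_low <- as.character(min(cfg$concentrations))
      ps <- lapply(seq_along(trajs[[mg_low]]), function(i) {
        p <- extract_pauses(trajs[[mg_low]][[i]], min_dwell = cfg$pause_s)
        if (nrow(p) > 0L) p$trace_id <- i
        p
      })
      ps <- do.call(rbind, ps[vapply(ps, nrow, 1L) > 0])
      pause_statistics(ps, cfg$report_s, n_traces = cfg$n_traces)
    })

    K <- eq_constants(rates)
    report <- list(
      provenance = list(package = "lexokin",
                        version = as.character(utils::packageVersion("lexokin")),
                        seed = cfg$seed, config_hash = hash),
      fits = lapply(fits, function(f)
        list(model = f$model, params = as.list(f$par), rss = f$rss,
             converged = f$converged)),
      derived = list(K_A = K[["K_A"]], K_B = K[["K_B"]],
                     K_ratio = K[["K_B"]] / K[["K_A"]],
                     kB_b = rates$kB_b, kA_b = rates$kA_b,
                     barrier_difference_kBT = barrier_difference(rates)),
      kaoff_estimate = list(best = est$best, mse = as.list(est$mse)),
      pause_summary = list(
        n_pauses = pstats$n_pauses,
        mean_duration_s = pstats$mean_duration,
        state_fractions = as.list(pstats$state_fractions),
        frac_traces_with_pause = pstats$frac_traces_with_pause,
        no_long_pauses = pstats$n_pauses == 0L)
    )
    report
  })
  jsonlite::write_json(result, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(result)
}
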