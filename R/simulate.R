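#' Exact stochastic simulation of a degradation trajectory
#'
#' Gillespie simulation of the three-state metal-ion cycle from `EMM(0)`
#' until absorption at position `n_sites`, using exactly the transition
#' wiring of [build_generator()]. The returned trajectory is a right-open
#' step function: the system occupies `(state[k], position[k])` on
#' `[time[k], time[k+1])`; the final row records entry into the absorbing
#' state.
#'
#' @inheritParams build_generator
#' @param seed Optional RNG seed (the caller's RNG stream is preserved).
#' @param max_events Safety cap on the number of transitions; exceeding it is
#'   an explicit error, never a silent truncation.
#' @return An object of class `state_trajectory`: list with `time`, `state`
#'   (character, E/EM/EMM), `position` (integer 0..N), `terminal` flag,
#'   `tau` (absorption time) and provenance metadata.
#' @examples
#' traj <- simulate_trajectory(model_spec("model1"), mg = 3, seed = 7)
#' traj$tau
#' @export
simulate_trajectory <- function(spec, mg, seed = NULL, max_events = 1e7) {
  stopifnot(inherits(spec, "model_spec"))
  mg <- check_mg(mg)
  with_seed(seed, {
    r <- spec$rates
    on <- on_rates(r, mg)
    kA_on <- on[["kA_on"]]; kB_on <- on[["kB_on"]]
    kA_off <- r$kA_off; kB_off <- r$kB_off
    N <- spec$n_sites
    model1 <- spec$variant == "model1"
    p_adv <- kB_on / (kB_on + kA_off)  # EM branch: advance vs lose A ion

    cap <- 256L
    t_v <- numeric(cap); s_v <- integer(cap); n_v <- integer(cap)
    k <- 1L
    t_v[1L] <- 0; s_v[1L] <- 3L; n_v[1L] <- 0L  # start in EMM(0)
    t_now <- 0; s_now <- 3L; n_now <- 0L        # 1=E, 2=EM, 3=EMM

    repeat {
      if (s_now == 3L) {
        # EMM: single exit, cleavage/translocation at kB_off
        t_now <- t_now + stats::rexp(1L, kB_off)
        if (model1) {
          s_now <- 2L
        } else {
          s_now <- 1L; n_now <- n_now + 1L
        }
      } else if (s_now == 2L) {
        t_now <- t_now + stats::rexp(1L, kB_on + kA_off)
        if (stats::runif(1L) < p_adv) {
          s_now <- 3L
          if (model1) n_now <- n_now + 1L
        } else {
          s_now <- 1L
        }
      } else {
        t_now <- t_now + stats::rexp(1L, kA_on)
        s_now <- 2L
      }
      k <- k + 1L
      if (k > cap) {
        cap <- cap * 2L
        length(t_v) <- cap; length(s_v) <- cap; length(n_v) <- cap
      }
      t_v[k] <- t_now; s_v[k] <- s_now; n_v[k] <- n_now
      if (s_now == 3L && n_now == N) break
      if (k >= max_events) {
        stop("event cap exceeded (", max_events,
             " transitions) before absorption; raise max_events")
      }
    }
    structure(list(time = t_v[seq_len(k)],
                   state = c("E", "EM", "EMM")[s_v[seq_len(k)]],
                   position = n_v[seq_len(k)],
                   terminal = TRUE, tau = t_now,
                   spec = spec, mg = mg, seed = seed),
              class = "state_trajectory")
  })
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf(
    "state trajectory (%s, %g mM): %d events, absorbed at position %d, tau = %.4g s\n",
    x$spec$variant, x$mg, length(x$time), max(x$position), x$tau))
  invisible(x)
}

#' Synthesize a FRET efficiency trace from a trajectory
#'
#' Maps the cleaved-nucleotide position linearly onto FRET efficiency
#' (`E_min` for the intact duplex, `E_max` when all `n_sites` nucleotides are
#' degraded), averages the position over each camera frame (translocation
#' events are fast relative to a frame at high Mg2+), and adds Gaussian
#' per-frame noise. The trace extends `tail_s` seconds beyond absorption.
#'
#' @param traj A [simulate_trajectory()] result.
#' @param frame_dt Frame interval in seconds (default 0.1, a typical EMCCD
#'   setting).
#' @param E_min,E_max Efficiencies of the intact and fully degraded reporter
#'   (defaults 0.26 and 0.53).
#' @param noise_sd Per-frame Gaussian noise, efficiency units (default 0.05).
#' @param seed Optional RNG seed for the noise.
#' @param tail_s Trace duration appended after absorption, seconds.
#' @param lead_s Baseline duration at `E_min` prepended before the reaction
#'   starts (seconds); mirrors the pre-degradation plateau of a measured
#'   trace and anchors the lower threshold of
#'   [measure_velocity_from_trace()].
#' @return An object of class `fret_trace`: data.frame with columns
#'   `time_s` (frame centres), `fret`, and the ground-truth `state` and
#'   `position` at the frame centre; provenance metadata in
#'   `attr(, "meta")`.
#' @export
trajectory_to_fret <- function(traj, frame_dt = 0.1, E_min = 0.26,
                               E_max = 0.53, noise_sd = 0.05, seed = NULL,
                               tail_s = 2, lead_s = 2) {
  stopifnot(inherits(traj, "state_trajectory"))
  if (frame_dt <= 0) stop("frame_dt must be positive")
  if (E_max <= E_min) stop("E_max must exceed E_min")
  if (noise_sd < 0 || lead_s < 0 || tail_s < 0) {
    stop("noise_sd, lead_s and tail_s must be non-negative")
  }
  N <- traj$spec$n_sites
  n_frames <- max(2L, as.integer(ceiling((lead_s + traj$tau + tail_s) /
                                           frame_dt)))
  bounds <- seq(0, by = frame_dt, length.out = n_frames + 1L)

  # time-weighted mean position per frame from the cumulative integral of
  # the piecewise-constant position path; the reaction starts at t = lead_s
  tt <- traj$time; pp <- traj$position
  cumI <- c(0, cumsum(pp[-length(pp)] * diff(tt)))
  at <- function(b) {
    b <- pmax(b - lead_s, 0)
    i <- findInterval(b, tt)
    cumI[i] + pp[i] * (b - tt[i])
  }
  mean_pos <- diff(at(bounds)) / frame_dt
  centres <- bounds[-1L] - frame_dt / 2
  ci <- findInterval(pmax(centres - lead_s, 0), tt)
  noise <- with_seed(seed, stats::rnorm(n_frames, 0, noise_sd))
  out <- data.frame(
    time_s = centres,
    fret = E_min + (mean_pos / N) * (E_max - E_min) + noise,
    state = traj$state[ci],
    position = traj$position[ci],
    stringsAsFactors = FALSE
  )
  attr(out, "meta") <- list(frame_dt = frame_dt, E_min = E_min, E_max = E_max,
                            noise_sd = noise_sd, seed = seed,
                            lead_s = lead_s, tail_s = tail_s,
                            mg = traj$mg, rates = traj$spec$rates,
                            n_sites = N, variant = traj$spec$variant,
                            tau = traj$tau)
  class(out) <- c("fret_trace", "data.frame")
  out
}

#' Extract pauses from a trajectory
#'
#' A pause is a maximal interval during which the enzyme remains at the same
#' nucleotide for longer than `min_dwell` seconds (default 2 s, the stall
#' rule). Each record carries the time-weighted occupancy fractions of the
#' three chemical states within the interval and the majority-state label.
#' The interval at the final position `n_sites` is excluded: degradation of
#' the reporter is complete once the last nucleotide is cleaved.
#'
#' @param traj A [simulate_trajectory()] result.
#' @param min_dwell Detection threshold in seconds (default 2).
#' @return A data.frame with columns `start`, `duration`, `position`,
#'   `frac_E`, `frac_EM`, `frac_EMM`, `majority_state` (zero rows if no
#'   interval exceeds the threshold).
#' @export
extract_pauses <- function(traj, min_dwell = 2) {
  stopifnot(inherits(traj, "state_trajectory"))
  runs <- rle(traj$position)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  empty <- data.frame(start = numeric(0), duration = numeric(0),
                      position = integer(0), frac_E = numeric(0),
                      frac_EM = numeric(0), frac_EMM = numeric(0),
                      majority_state = character(0),
                      stringsAsFactors = FALSE)
  # drop the terminal run (absorbing position: reporter fully degraded)
  keep <- seq_len(length(runs$values) - 1L)
  if (length(keep) == 0L) return(empty)
  recs <- lapply(keep, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    t0 <- traj$time[i0]; t1 <- traj$time[i1 + 1L]
    dur <- t1 - t0
    if (dur <= min_dwell) return(NULL)
    dt <- diff(traj$time[i0:(i1 + 1L)])
    occ <- vapply(c("E", "EM", "EMM"), function(s)
      sum(dt[traj$state[i0:i1] == s]), numeric(1)) / dur
    data.frame(start = t0, duration = dur, position = runs$values[j],
               frac_E = occ[["E"]], frac_EM = occ[["EM"]],
               frac_EMM = occ[["EMM"]],
               majority_state = c("E", "EM", "EMM")[which.max(occ)],
               stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) return(empty)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Synthetic per-trace velocity dataset with quenched disorder
#'
#' Emulates a Mg2+ titration: for each concentration, `n_traces` molecules
#' are simulated, each with its own activation-energy perturbation
#' `dG ~ Normal(0, sigma^2)` scaling all four rate constants by `exp(-dG)`.
#' The per-trace velocity is `n_sites / tau_N`.
#'
#' @inheritParams simulate_trajectory
#' @param concentrations Mg2+ concentrations in mM (default, the standard
#'   titration grid [mg_concentrations()]).
#' @param n_traces Traces per concentration.
#' @param disorder A [disorder_spec()]; only `sigma` is used here (one draw
#'   per trace).
#' @param seed RNG seed governing both the disorder draws and the
#'   trajectories; a fixed seed reproduces the dataset exactly.
#' @return A `velocity_dataset`: data.frame with columns `mg_mM`,
#'   `velocity_nt_s`, `trace_id`.
#' @export
synth_velocity_dataset <- function(spec, concentrations = mg_concentrations(),
                                   n_traces = 50,
                                   disorder = disorder_spec(),
                                   seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), inherits(disorder, "disorder_spec"),
            n_traces >= 1)
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  with_seed(seed, {
    rows <- vector("list", length(concentrations) * n_traces)
    k <- 0L
    for (mg in concentrations) {
      for (i in seq_len(n_traces)) {
        fac <- exp(-stats::rnorm(1L, 0, disorder$sigma))
        spec_i <- model_spec(spec$variant, spec$n_sites,
                             scale_rates(spec$rates, fac))
        traj <- simulate_trajectory(spec_i, mg)
        k <- k + 1L
        rows[[k]] <- data.frame(mg_mM = mg,
                                velocity_nt_s = spec$n_sites / traj$tau,
                                trace_id = sprintf("mg%g_%04d", mg, i),
                                stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("velocity_dataset", "data.frame")
    attr(out, "meta") <- list(variant = spec$variant, n_sites = spec$n_sites,
                              rates = spec$rates, sigma = disorder$sigma,
                              seed = seed)
    out
  })
}

#' Per-condition aggregates of a velocity dataset
#'
#' Mean, standard error of the mean (`sd/sqrt(n)`, always recomputed) and
#' count per Mg2+ condition.
#'
#' @param data A `velocity_dataset` or any data.frame with columns `mg_mM`
#'   and `velocity_nt_s`.
#' @return data.frame with columns `mg_mM`, `mean`, `sem`, `n`, sorted by
#'   concentration.
#' @export
aggregate_velocity <- function(data) {
  stopifnot(all(c("mg_mM", "velocity_nt_s") %in% names(data)))
  sp <- split(data$velocity_nt_s, data$mg_mM)
  out <- data.frame(
    mg_mM = as.numeric(names(sp)),
    mean = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)),
    n = vapply(sp, length, numeric(1))
  )
  out <- out[order(out$mg_mM), , drop = FALSE]
  rownames(out) <- NULL
  out
}
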