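#' FRET efficiency from donor and acceptor intensities
#'
#' Ratiometric efficiency `E = A' / (D + A')` with the acceptor corrected for
#' donor-channel crosstalk, `A' = max(A - crosstalk * D, 0)`. Frames with
#' both intensities zero are undefined and returned as `NA` (a marker, not an
#' error).
#'
#' @param donor,acceptor Non-negative intensities (vectors, arbitrary units).
#' @param crosstalk Donor-into-acceptor crosstalk fraction (default 0).
#' @return Numeric vector of efficiencies in `[0, 1]` with `NA` markers.
#' @examples
#' compute_fret(300, 300, crosstalk = 0.1)
#' @export
compute_fret <- function(donor, acceptor, crosstalk = 0) {
  if (any(donor < 0, na.rm = TRUE) || any(acceptor < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  stopifnot(crosstalk >= 0, crosstalk < 1)
  a <- pmax(acceptor - crosstalk * donor, 0)
  tot <- donor + a
  out <- a / tot
  out[tot == 0] <- NA_real_
  out
}

#' Measure a degradation velocity from a FRET trace
#'
#' Operationalizes the "time from minimum to maximum FRET" readout against
#' noise: the degradation time is the interval between the last visit at or
#' below the lower threshold (`E_min + low_frac * range`) preceding the
#' rise, and the first crossing of the upper threshold
#' (`E_min + high_frac * range`). That interval covers the fraction
#' `high_frac - low_frac` of the reporter, so the full degradation time is
#' estimated as `interval / (high_frac - low_frac)` and the velocity as
#' `n_sites` divided by it (with the exact thresholds 0 and 1 this reduces
#' to `n_sites / interval`).
#'
#' @param trace A [trajectory_to_fret()] trace (or a data.frame with
#'   `time_s` and `fret`, in which case `E_min`, `E_max` and `n_sites` must
#'   be supplied).
#' @param low_frac,high_frac Threshold positions as fractions of the
#'   `E_min -> E_max` range (defaults 0.05 and 0.95).
#' @param E_min,E_max,n_sites Calibration; default from the trace metadata.
#' @param smooth Odd running-median window (frames) applied before
#'   thresholding to suppress spurious crossings from frame noise
#'   (default 5; use 1 to disable).
#' @return Velocity in nt s^-1, or `NA` (no-event marker) if either
#'   threshold is never crossed.
#' @export
measure_velocity_from_trace <- function(trace, low_frac = 0.05,
                                        high_frac = 0.95, E_min = NULL,
                                        E_max = NULL, n_sites = NULL,
                                        smooth = 5) {
  meta <- attr(trace, "meta")
  E_min <- E_min %||% meta$E_min
  E_max <- E_max %||% meta$E_max
  n_sites <- n_sites %||% meta$n_sites
  if (is.null(E_min) || is.null(E_max) || is.null(n_sites)) {
    stop("E_min, E_max and n_sites must be available (metadata or arguments)")
  }
  stopifnot(low_frac < high_frac)
  thr_lo <- E_min + low_frac * (E_max - E_min)
  thr_hi <- E_min + high_frac * (E_max - E_min)
  f <- trace$fret; t <- trace$time_s
  if (smooth > 1 && length(f) >= smooth) {
    f <- stats::runmed(f, k = smooth, endrule = "median")
  }
  hi <- which(f >= thr_hi)
  if (length(hi) == 0L) return(NA_real_)
  h <- hi[1L]
  # sub-frame refinement: linear interpolation across the crossing frame
  t_hi <- if (h > 1L && f[h] > f[h - 1L]) {
    t[h - 1L] + (t[h] - t[h - 1L]) * (thr_hi - f[h - 1L]) / (f[h] - f[h - 1L])
  } else t[h]
  lo <- which(f <= thr_lo & t <= t_hi)
  if (length(lo) == 0L) return(NA_real_)
  l <- lo[length(lo)]
  t_lo <- if (l < length(f) && f[l + 1L] > f[l]) {
    t[l] + (t[l + 1L] - t[l]) * (thr_lo - f[l]) / (f[l + 1L] - f[l])
  } else t[l]
  if (t_hi <= t_lo) return(NA_real_)
  n_sites * (high_frac - low_frac) / (t_hi - t_lo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# velocity-curve model functions on the natural parameter scale
curve_fun <- function(model) {
  switch(model,
    model1 = function(par, c) {
      par[["kB_off"]] * c / (c + par[["K_B"]] + par[["K_B"]] * par[["K_A"]] / c)
    },
    mm = function(par, c) par[["v_max"]] * c / (c + par[["K_m"]]),
    hill = function(par, c) {
      par[["v_max"]] * c^par[["n"]] / (c^par[["n"]] + par[["K"]]^par[["n"]])
    },
    stop("unknown model: ", model))
}

#' Fit a velocity-vs-Mg2+ curve
#'
#' Nonlinear least squares on the per-condition mean velocities (the same
#' loss for all three models so that model comparison is like-for-like).
#' Parameters are log-transformed to enforce positivity, and the fit is
#' multi-started from a Michaelis-Menten-derived initial guess plus
#' deterministic +/-50% perturbations of each parameter; the best residual
#' sum of squares is kept and polished.
#'
#' Models: `"model1"` (sequential two-ion curve; parameters `kB_off`, `K_B`,
#' `K_A`), `"mm"` (Michaelis-Menten; `v_max`, `K_m`), `"hill"` (`v_max`,
#' `K`, `n`).
#'
#' @param data A `velocity_dataset`, a per-trace data.frame with `mg_mM` and
#'   `velocity_nt_s`, or a pre-aggregated data.frame with `mg_mM` and `mean`
#'   (optionally `sem`).
#' @param model One of `"model1"`, `"mm"`, `"hill"`.
#' @param weighted If `TRUE`, weight conditions by `1/sem^2` (off by
#'   default).
#' @return An object of class `fit_result`: list with `model`, `par` (named,
#'   natural scale), `rss`, `converged`, `data` (the aggregated points).
#' @examples
#' spec <- model_spec("model1", rates = lambda_rates())
#' v <- vapply(mg_concentrations(), function(c) mean_velocity(spec, c), 1)
#' fit <- fit_velocity_curve(data.frame(mg_mM = mg_concentrations(), mean = v),
#'                           model = "model1")
#' fit$par
#' @export
fit_velocity_curve <- function(data, model = c("model1", "mm", "hill"),
                               weighted = FALSE) {
  model <- match.arg(model)
  agg <- if (all(c("mg_mM", "mean") %in% names(data))) {
    data
  } else {
    aggregate_velocity(data)
  }
  agg <- agg[order(agg$mg_mM), , drop = FALSE]
  cc <- agg$mg_mM; vv <- agg$mean
  if (any(cc <= 0) || any(vv <= 0)) stop("concentrations and velocities must be positive")
  npar <- switch(model, model1 = 3L, hill = 3L, mm = 2L)
  if (length(unique(cc)) < npar) {
    stop("need at least ", npar, " distinct concentrations to fit '", model, "'")
  }
  w <- if (weighted) {
    if (is.null(agg$sem) || any(!is.finite(agg$sem)) || any(agg$sem <= 0)) {
      stop("weighted fit requires finite positive sem values")
    }
    1 / agg$sem^2
  } else rep(1, length(cc))

  f <- curve_fun(model)
  obj <- function(theta) {
    par <- exp(theta)
    names(par) <- par_names
    resid <- vv - f(par, cc)
    sum(w * resid^2)
  }

  # MM-derived starting values: plateau from the top condition, K from
  # half-maximum interpolation
  v0 <- max(vv)
  half <- v0 / 2
  K0 <- tryCatch(stats::approx(vv, cc, xout = half, ties = "ordered")$y,
                 error = function(e) NA_real_)
  if (!is.finite(K0) || K0 <= 0) K0 <- stats::median(cc)
  start <- switch(model,
    model1 = c(kB_off = v0, K_B = K0, K_A = K0 / 2),
    mm = c(v_max = v0, K_m = K0),
    hill = c(v_max = v0, K = K0, n = 1.5))
  par_names <- names(start)

  starts <- list(log(start))
  for (j in seq_along(start)) {
    for (fac in c(1.5, 1 / 1.5)) {
      s <- start; s[j] <- s[j] * fac
      starts[[length(starts) + 1L]] <- log(s)
    }
  }
  best <- NULL
  for (th0 in starts) {
    res <- tryCatch(
      stats::optim(th0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    stop("velocity-curve fit failed to converge from all ",
         length(starts), " starts (model '", model, "')")
  }
  # Nelder-Mead polish from the best point
  pol <- stats::optim(best$par, obj,
                      control = list(maxit = 2000, reltol = 1e-15))
  if (pol$value < best$value) best <- pol
  par <- exp(best$par)
  names(par) <- par_names
  structure(list(model = model, par = par, rss = best$value,
                 converged = TRUE, weighted = weighted, data = agg),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("velocity-curve fit: %s (RSS %.4g%s)\n", x$model, x$rss,
              if (x$weighted) ", SEM-weighted" else ""))
  print(round(x$par, 5))
  invisible(x)
}

#' Estimate the quenched-disorder width from velocities
#'
#' Fits a Gaussian to the log10-velocity values (maximum likelihood: sample
#' mean and standard deviation) and converts the width to activation-energy
#' units: `sigma = sigma_zeta * ln(10)` kB*T. Because even a disorder-free
#' enzyme has a finite stochastic width in zeta, an intrinsic width (e.g. the
#' standard deviation of the disorder-free zeta density) may be supplied and
#' is subtracted in quadrature; both raw and corrected values are reported.
#'
#' @param velocities Numeric vector of per-trace velocities (>= 20 values).
#' @param intrinsic_sd_zeta Optional disorder-free width in zeta to subtract
#'   in quadrature.
#' @return List with `sigma_zeta`, `sigma_kBT`, and (when the correction is
#'   requested) `sigma_zeta_corrected`, `sigma_kBT_corrected`.
#' @export
estimate_sigma <- function(velocities, intrinsic_sd_zeta = NULL) {
  velocities <- velocities[is.finite(velocities)]
  if (length(velocities) < 20L) stop("need at least 20 finite velocities")
  if (any(velocities <= 0)) stop("velocities must be positive")
  zeta <- log10(velocities)
  s <- stats::sd(zeta)
  if (s == 0) {
    warning("all velocities identical; returning sigma = 0")
  }
  out <- list(sigma_zeta = s, sigma_kBT = s * log(10))
  if (!is.null(intrinsic_sd_zeta)) {
    sc <- sqrt(max(s^2 - intrinsic_sd_zeta^2, 0))
    out$sigma_zeta_corrected <- sc
    out$sigma_kBT_corrected <- sc * log(10)
  }
  out
}

#' Histogram of log10-velocities
#'
#' @param velocities Positive velocities, nt s^-1.
#' @param edges Strictly increasing bin edges in zeta = log10(velocity).
#'   Values outside the edge range are dropped with a warning.
#' @return An object of class `logv_histogram`: list with `edges`, `prob`
#'   (normalized over retained values) and `n`.
#' @export
logv_histogram <- function(velocities, edges) {
  stopifnot(all(diff(edges) > 0), length(edges) >= 2L)
  zeta <- log10(velocities[is.finite(velocities) & velocities > 0])
  inside <- zeta >= edges[1L] & zeta <= edges[length(edges)]
  if (any(!inside)) {
    warning(sum(!inside), " of ", length(zeta),
            " values fall outside the bin range and were dropped")
  }
  zeta <- zeta[inside]
  counts <- tabulate(findInterval(zeta, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  structure(list(edges = edges,
                 prob = if (sum(counts) > 0) counts / sum(counts)
                        else rep(0, length(counts)),
                 n = sum(counts)),
            class = "logv_histogram")
}

#' Predicted log10-velocity histogram from the master equation
#'
#' Integrates the disorder-averaged zeta density over the requested bins.
#' Bin probabilities sum to the mass captured by the bin range (close to 1
#' when the edges cover the support); they are deliberately not
#' renormalized.
#'
#' @inheritParams disorder_average_pdf
#' @param edges Bin edges in zeta (shared with the observed histograms).
#' @return A `logv_histogram` (with `n = NA`).
#' @export
predict_logV_histogram <- function(spec, mg, disorder = disorder_spec(),
                                   edges, ...) {
  zpdf <- logV_transform(disorder_average_pdf(spec, mg, disorder, ...))
  Cfun <- stats::approxfun(zpdf$x, cumtrapz(zpdf$x, zpdf$density),
                           yleft = 0, yright = trapz(zpdf$x, zpdf$density))
  prob <- diff(Cfun(edges))
  structure(list(edges = edges, prob = pmax(prob, 0), n = NA_integer_),
            class = "logv_histogram")
}

#' Grid-search estimation of the A-ion dissociation rate
#'
#' For each candidate `kA_off`, predicts the log10-velocity histograms at the
#' observed Mg2+ conditions (with `kA_b = kA_off / K_A` so the equilibrium
#' constant, fixed by the titration fit, is preserved) and computes the mean
#' squared error against the observed bin probabilities, summed over
#' conditions and bins. Returns the candidate minimizing the MSE; ties break
#' toward the smaller candidate (conservative: favours the more stable
#' A-site ion).
#'
#' @param candidates Candidate dissociation rates, s^-1.
#' @param observed Named list of [logv_histogram()] objects; names are Mg2+
#'   concentrations in mM. All must share the same bin edges.
#' @param rates Base [rate_constants()]; `kB_off`, `kB_b` and the implied
#'   `K_A` are held fixed while `kA_off` is scanned.
#' @param disorder A [disorder_spec()] used for the predictions.
#' @param n_sites Number of nucleotides (default 20).
#' @param variant Reaction scheme for the predictions (default `"model1"`).
#' @return List with `best` (selected rate), `mse` (named vector over
#'   candidates) and `table` (data.frame).
#' @export
estimate_kAoff <- function(candidates, observed, rates,
                           disorder = disorder_spec(), n_sites = 20,
                           variant = "model1") {
  stopifnot(length(candidates) >= 2L, all(candidates > 0),
            inherits(rates, "rate_constants"), length(observed) >= 1L)
  mgs <- suppressWarnings(as.numeric(names(observed)))
  if (length(mgs) != length(observed) || any(!is.finite(mgs))) {
    stop("'observed' must be a named list; names are Mg2+ concentrations (mM)")
  }
  edges <- observed[[1L]]$edges
  for (h in observed) {
    if (!isTRUE(all.equal(h$edges, edges))) {
      stop("all observed histograms must share the same bin edges")
    }
  }
  K_A <- eq_constants(rates)[["K_A"]]
  candidates <- sort(candidates)  # ties then resolve to the smaller value
  mse <- vapply(candidates, function(k) {
    r_k <- rate_constants(rates$kB_off, rates$kB_b, k, k / K_A)
    spec_k <- model_spec(variant, n_sites, r_k)
    sum(vapply(seq_along(mgs), function(i) {
      pred <- predict_logV_histogram(spec_k, mgs[i], disorder, edges)
      sum((observed[[i]]$prob - pred$prob)^2)
    }, numeric(1)))
  }, numeric(1))
  names(mse) <- as.character(candidates)
  list(best = candidates[which.min(mse)], mse = mse,
       table = data.frame(kA_off = candidates, mse = as.numeric(mse)))
}

#' Summary statistics of reported pauses
#'
#' Filters pause records to those longer than `report_threshold` (default
#' 10 s, chosen so that camera noise cannot masquerade as a pause) and
#' summarizes durations and state attribution.
#'
#' @param pauses A data.frame of pause records ([extract_pauses()] output,
#'   possibly row-bound over traces with an added `trace_id` column).
#' @param report_threshold Minimum duration in seconds for a pause to be
#'   reported (default 10).
#' @param n_traces Optional total number of traces analysed, used for the
#'   fraction of traces containing a reported pause.
#' @return List with `n_pauses`, `mean_duration`, `durations`,
#'   `state_fractions` (share of reported pauses whose majority state is
#'   E/EM/EMM) and `frac_traces_with_pause` (NA unless computable).
#' @export
pause_statistics <- function(pauses, report_threshold = 10,
                             n_traces = NULL) {
  empty <- list(n_pauses = 0L, mean_duration = NA_real_,
                durations = numeric(0),
                state_fractions = c(E = NA_real_, EM = NA_real_,
                                    EMM = NA_real_),
                frac_traces_with_pause = NA_real_)
  if (is.null(pauses) || nrow(pauses) == 0L) return(empty)
  rep_p <- pauses[pauses$duration > report_threshold, , drop = FALSE]
  if (nrow(rep_p) == 0L) return(empty)
  fr <- table(factor(rep_p$majority_state, levels = c("E", "EM", "EMM")))
  fr <- as.numeric(fr) / nrow(rep_p)
  names(fr) <- c("E", "EM", "EMM")
  frac_traces <- NA_real_
  if (!is.null(rep_p$trace_id) && !is.null(n_traces)) {
    frac_traces <- length(unique(rep_p$trace_id)) / n_traces
  }
  list(n_pauses = nrow(rep_p), mean_duration = mean(rep_p$duration),
       durations = rep_p$duration, state_fractions = fr,
       frac_traces_with_pause = frac_traces)
}
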