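#' Generator matrix of the position-resolved master equation
#'
#' Builds the rate generator over the composite state space
#' (chemical state in \{E, EM, EMM\}) x (position n in 0..N), dimension
#' 3(N+1). The column convention is used: `dp/dt = Q p`, so `Q[to, from]`
#' holds the rate of the transition from -> to and every non-absorbing column
#' sums to zero.
#'
#' Sequential scheme (`model1`): `EMM(n) -> EM(n)` at `kB_off` for `n < N`
#' (cleavage/translocation), `EM(n) -> EMM(n+1)` at `kB_on` (B-ion rebinding,
#' carries the position increment as in the position-resolved rate
#' equations), `EM(n) -> E(n)` at `kA_off`, `E(n) -> EM(n)` at `kA_on`.
#' `EMM(N)` is absorbing.
#'
#' Coincident scheme (`model2`): `EMM(n) -> E(n+1)` at `kB_off` (cleavage
#' expels both ions and carries the increment), `E(n) <-> EM(n)` at
#' `kA_on`/`kA_off`, `EM(n) -> EMM(n)` at `kB_on`; `EMM(N)` absorbing.
#'
#' As printed, the gain term of the EMM balance equation carries a boundary
#' guard `(1 - delta_{0,n-1})` which, read literally, would disconnect
#' `EM(0) -> EMM(1)` and trap probability at position 0. It is interpreted
#' here as a guard against the out-of-range source `EM(-1)`: the gain term is
#' active for every `n >= 1`.
#'
#' @param spec A [model_spec()].
#' @param mg Mg2+ concentration, mM (> 0).
#' @return An object of class `generator_matrix`: list with `Q` (dense
#'   matrix), `states` (data.frame of `state`, `position`), `absorbing`
#'   (index of `EMM(N)`), and the pseudo-first-order rates used.
#' @export
build_generator <- function(spec, mg) {
  stopifnot(inherits(spec, "model_spec"))
  mg <- check_mg(mg)
  N <- spec$n_sites
  r <- spec$rates
  on <- on_rates(r, mg)
  kA_on <- on[["kA_on"]]; kB_on <- on[["kB_on"]]

  states <- data.frame(
    state = rep(c("E", "EM", "EMM"), N + 1L),
    position = rep(0:N, each = 3L),
    stringsAsFactors = FALSE
  )
  idx <- function(state, n) 3L * n + match(state, c("E", "EM", "EMM"))
  M <- 3L * (N + 1L)
  Q <- matrix(0, M, M)
  add <- function(from, to, rate) Q[to, from] <<- Q[to, from] + rate

  for (n in 0:N) {
    add(idx("E", n), idx("EM", n), kA_on)
    add(idx("EM", n), idx("E", n), r$kA_off)
    if (spec$variant == "model1") {
      if (n < N) {
        add(idx("EMM", n), idx("EM", n), r$kB_off)
        add(idx("EM", n), idx("EMM", n + 1L), kB_on)
      }
    } else {
      if (n < N) add(idx("EMM", n), idx("E", n + 1L), r$kB_off)
      add(idx("EM", n), idx("EMM", n), kB_on)
    }
  }
  diag(Q) <- diag(Q) - colSums(Q)

  structure(list(Q = Q, states = states, absorbing = idx("EMM", N),
                 start = idx("EMM", 0L), kA_on = kA_on, kB_on = kB_on,
                 spec = spec, mg = mg),
            class = "generator_matrix")
}

# Propagate p(t) = expm(Q t) p0 for the transient sub-generator at a vector
# of times. Eigendecomposition is used when it reconstructs Q accurately;
# otherwise falls back to stepwise matrix exponentials (Matrix::expm).
propagate_transient <- function(Qtr, p0, times) {
  eg <- tryCatch(eigen(Qtr), error = function(e) NULL)
  if (!is.null(eg)) {
    V <- eg$vectors
    rec <- tryCatch({
      c0 <- solve(V, p0 + 0i)
      err <- max(Mod(V %*% (eg$values * solve(V)) - Qtr))
      list(c0 = c0, err = err / max(1, max(abs(Qtr))))
    }, error = function(e) NULL)
    if (!is.null(rec) && rec$err < 1e-9) {
      P <- V %*% (exp(outer(eg$values, times)) * as.vector(rec$c0))
      return(Re(P))
    }
  }
  # fallback: step through the sorted grid with dense matrix exponentials
  ord <- order(times)
  ts <- times[ord]
  P <- matrix(0, length(p0), length(times))
  p <- p0
  t_prev <- 0
  for (k in seq_along(ts)) {
    E <- as.matrix(Matrix::expm(Matrix::Matrix(Qtr * (ts[k] - t_prev))))
    p <- as.vector(E %*% p)
    P[, ord[k]] <- p
    t_prev <- ts[k]
  }
  P
}

#' Mean first-passage time to complete degradation
#'
#' Exact mean time to reach the absorbing state `EMM(N)` from `EMM(0)`,
#' computed by a linear solve on the transient sub-generator. For the
#' sequential scheme this equals `n_sites * tau1(spec, mg)` (renewal
#' identity); for the coincident scheme it equals `n_sites / mean_velocity`.
#' A structurally blocked path (numerically singular system) is reported as
#' `Inf`.
#'
#' @inheritParams build_generator
#' @return Time in seconds (possibly `Inf`).
#' @export
mean_first_passage_time <- function(spec, mg) {
  g <- build_generator(spec, mg)
  # restrict to states that can reach absorption (in the sequential scheme
  # E(N)/EM(N) form a closed bouncing pair that would make the system
  # singular); if the start cannot reach absorption the MFPT is infinite
  co <- co_reachable(g$Q, g$absorbing)
  if (!(g$start %in% co)) return(Inf)
  tr <- setdiff(co, g$absorbing)
  tt <- tryCatch(solve(-t(g$Q[tr, tr]), rep(1, length(tr))),
                 error = function(e) NULL)
  if (is.null(tt) || any(!is.finite(tt))) return(Inf)
  tt[match(g$start, tr)]
}

# indices of states from which `target` is reachable (including target),
# following the column-convention generator Q[to, from]
co_reachable <- function(Q, target) {
  keep <- logical(nrow(Q))
  keep[target] <- TRUE
  frontier <- target
  while (length(frontier) > 0L) {
    preds <- which(colSums(Q[frontier, , drop = FALSE] > 0) > 0)
    new <- preds[!keep[preds]]
    keep[new] <- TRUE
    frontier <- new
  }
  which(keep)
}

#' First-passage-time density of the N-nucleotide degradation time
#'
#' Solves the position-resolved master equation from the initial condition
#' "all probability in EMM(0)" (enzyme engaged with both ions at the start of
#' the processive phase) and returns the probability density of the
#' absorption time tau_N. The density is computed as the probability influx
#' into the absorbing state (`kB_on` times the probability of its boundary
#' precursor state), avoiding numerical differentiation of the absorbed mass.
#'
#' @inheritParams build_generator
#' @param grid Optional strictly increasing time grid (s). By default a
#'   geometric grid of `grid_points` points spanning
#'   `c(grid_min_factor, grid_max_factor) * N * tau1` is used.
#' @param grid_points,grid_min_factor,grid_max_factor Default-grid controls.
#' @return An object of class `fp_pdf`: list with `x` (grid), `density`,
#'   `space = "tau_s"`, `mass` (trapezoid integral), `truncated` flag and
#'   `n_sites`. A warning is raised when the grid captures less than 99.9%
#'   of the distribution; below 99% the result is flagged `truncated`.
#' @export
first_passage_pdf <- function(spec, mg, grid = NULL, grid_points = 400,
                              grid_min_factor = 1e-3, grid_max_factor = 50) {
  g <- build_generator(spec, mg)
  N <- spec$n_sites
  if (is.null(grid)) {
    t_scale <- N * tau1(spec, mg)
    grid <- geom_grid(grid_min_factor * t_scale, grid_max_factor * t_scale,
                      grid_points)
  }
  if (any(diff(grid) <= 0) || any(grid <= 0)) {
    stop("grid must be strictly increasing and positive")
  }
  tr <- setdiff(seq_len(nrow(g$Q)), g$absorbing)
  p0 <- numeric(length(tr))
  p0[match(g$start, tr)] <- 1
  P <- propagate_transient(g$Q[tr, tr], p0, grid)
  # boundary precursor: EM(N-1) feeds EMM(N) in model1, EM(N) in model2
  pre_n <- if (spec$variant == "model1") N - 1L else N
  pre <- which(g$states$state[tr] == "EM" & g$states$position[tr] == pre_n)
  dens <- pmax(g$kB_on * P[pre, ], 0)
  mass <- trapz(grid, dens)
  truncated <- mass < 0.99
  if (mass < 0.999) {
    warning(sprintf(
      "time grid captures only %.4f of the first-passage mass; extend it",
      mass))
  }
  structure(list(x = grid, density = dens, space = "tau_s", mass = mass,
                 truncated = truncated, n_sites = N,
                 meta = list(variant = spec$variant, mg = mg)),
            class = "fp_pdf")
}

#' @export
print.fp_pdf <- function(x, ...) {
  cat(sprintf("first-passage density in %s space: %d grid points, mass %.5f%s\n",
              x$space, length(x$x), x$mass,
              if (isTRUE(x$truncated)) " (TRUNCATED)" else ""))
  invisible(x)
}

#' Quenched-disorder specification
#'
#' Molecule-to-molecule (static) disorder is modelled as a Gaussian
#' perturbation dG of the activation free energy, applied as a common factor
#' `exp(-dG)` to all four rate constants of a molecule. `sigma` is the
#' standard deviation of dG in kB*T units.
#'
#' @param sigma Disorder width in kB*T (>= 0). Default 0.5, a realistic
#'   molecule-to-molecule spread for single-enzyme turnover data (the
#'   generating value is not observable directly; see the methods vignette).
#' @param n_draws Number of disorder draws to average over (default 5000).
#' @param seed RNG seed used for the draws.
#' @return An object of class `disorder_spec`.
#' @export
disorder_spec <- function(sigma = 0.5, n_draws = 5000, seed = 1L) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            sigma >= 0, n_draws >= 1)
  structure(list(sigma = sigma, n_draws = as.integer(n_draws),
                 seed = seed), class = "disorder_spec")
}

#' Disorder-averaged first-passage density
#'
#' Averages the first-passage density over `n_draws` molecules whose rate
#' constants are jointly scaled by `exp(-dG)`, `dG ~ Normal(0, sigma^2)`.
#' Because the scaling is common to all four rates, the per-molecule density
#' is an exact time rescaling of the disorder-free one,
#' `f_s(t) = s f(s t)` with `s = exp(-dG)`; the default `method = "scaling"`
#' exploits this (one master-equation solve total). `method = "direct"`
#' re-solves the master equation per draw and is provided as a slow
#' cross-check for small `n_draws`.
#'
#' The average is an expectation over the normal disorder law. With
#' `draws = "stratified"` (default) the `n_draws` perturbations are the
#' midpoint normal quantiles `sigma * qnorm((i - 1/2) / n)` - a
#' deterministic quadrature that converges much faster than raw Monte
#' Carlo at the same `n`; `draws = "random"` reproduces the literal
#' random-number procedure (seeded).
#'
#' @inheritParams first_passage_pdf
#' @param disorder A [disorder_spec()].
#' @param method `"scaling"` (default) or `"direct"`.
#' @param draws `"stratified"` (quadrature, default) or `"random"`.
#' @return An `fp_pdf` in tau space on `grid`.
#' @export
disorder_average_pdf <- function(spec, mg, disorder = disorder_spec(),
                                 grid = NULL, grid_points = 400,
                                 method = c("scaling", "direct"),
                                 draws = c("stratified", "random")) {
  method <- match.arg(method)
  draws <- match.arg(draws)
  stopifnot(inherits(disorder, "disorder_spec"))
  if (is.null(grid)) {
    t_scale <- spec$n_sites * tau1(spec, mg)
    # widen the default window: disorder spreads the density in log-time
    pad <- exp(4 * disorder$sigma)
    grid <- geom_grid(1e-3 * t_scale / pad, 50 * t_scale * pad, grid_points)
  }
  dG <- if (draws == "stratified") {
    disorder$sigma *
      stats::qnorm((seq_len(disorder$n_draws) - 0.5) / disorder$n_draws)
  } else {
    with_seed(disorder$seed, stats::rnorm(disorder$n_draws, 0,
                                          disorder$sigma))
  }
  s <- exp(-dG)
  if (disorder$sigma == 0) {
    dens <- suppressWarnings(first_passage_pdf(spec, mg, grid = grid))$density
  } else if (method == "direct") {
    acc <- numeric(length(grid))
    for (si in s) {
      spec_i <- model_spec(spec$variant, spec$n_sites,
                           scale_rates(spec$rates, si))
      pdf_i <- suppressWarnings(first_passage_pdf(spec_i, mg, grid = grid))
      acc <- acc + pdf_i$density
    }
    dens <- acc / length(s)
  } else {
    base_grid <- geom_grid(min(grid) * min(min(s), 1) * 0.999,
                           max(grid) * max(max(s), 1) * 1.001,
                           max(4 * grid_points, 1200))
    base <- suppressWarnings(
      first_passage_pdf(spec, mg, grid = base_grid))
    # evaluate s_i * f(s_i * t) for all draws at once; density interpolated
    # linearly in log-time, zero outside the computed support
    args <- outer(s, grid)                       # n_draws x length(grid)
    fi <- stats::approx(log(base_grid), base$density, xout = log(args),
                        yleft = 0, yright = 0)$y
    dens <- colMeans(matrix(fi * as.vector(s), nrow = length(s)))
  }
  mass <- trapz(grid, dens)
  if (mass < 0.999) {
    warning(sprintf(
      "disorder-averaged grid captures only %.4f of the mass", mass))
  }
  structure(list(x = grid, density = dens, space = "tau_s", mass = mass,
                 truncated = mass < 0.99, n_sites = spec$n_sites,
                 meta = list(variant = spec$variant, mg = mg,
                             sigma = disorder$sigma,
                             n_draws = disorder$n_draws,
                             seed = disorder$seed)),
            class = "fp_pdf")
}

#' Log10-velocity transform of a first-passage density
#'
#' Mass-preserving change of variables between the degradation time tau_N and
#' zeta = log10(V) = log10(n_sites / tau_N):
#' `P(zeta) = tau * ln(10) * P(tau)`. Applying the transform to a density
#' already in zeta space inverts it back to tau space.
#'
#' @param pdf An `fp_pdf` (either space).
#' @param n_sites Number of nucleotides; defaults to the value carried by
#'   `pdf`.
#' @return An `fp_pdf` in the other space, grid increasing.
#' @export
logV_transform <- function(pdf, n_sites = pdf$n_sites) {
  stopifnot(inherits(pdf, "fp_pdf"))
  if (pdf$space == "tau_s") {
    if (any(pdf$x <= 0)) stop("time grid must be strictly positive")
    zeta <- log10(n_sites / pdf$x)
    dens <- pdf$x * log(10) * pdf$density
    ord <- order(zeta)
    out_x <- zeta[ord]; out_d <- dens[ord]; space <- "log10_v"
  } else {
    tau <- n_sites * 10^(-pdf$x)
    dens <- pdf$density / (tau * log(10))
    ord <- order(tau)
    out_x <- tau[ord]; out_d <- dens[ord]; space <- "tau_s"
  }
  structure(list(x = out_x, density = out_d, space = space, mass = pdf$mass,
                 truncated = pdf$truncated, n_sites = n_sites,
                 meta = pdf$meta),
            class = "fp_pdf")
}
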