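#' Kinetic rate constants for the two-metal-ion cycle
#'
#' Container for the four elementary rate constants of the three-state
#' (E / EM / EMM) metal-ion cycle. Units are fixed package-wide: seconds,
#' millimolar, nucleotides; bimolecular (binding) rates are in s^-1 mM^-1.
#'
#' The equilibrium dissociation constants `K_A = kA_off / kA_b` and
#' `K_B = kB_off / kB_b` (mM) are always recomputed from the stored rates via
#' [eq_constants()]; they are never stored independently. Pseudo-first-order
#' binding rates at a given Mg2+ concentration are obtained with [on_rates()].
#'
#' @param kB_off Dissociation rate of the B-site ion, s^-1. In the sequential
#'   scheme this is also the cleavage/translocation rate (EMM -> EM).
#' @param kB_b Bimolecular binding rate of the B-site ion, s^-1 mM^-1.
#' @param kA_off Dissociation rate of the A-site ion (EM -> E), s^-1.
#' @param kA_b Bimolecular binding rate of the A-site ion, s^-1 mM^-1.
#'
#' @return An object of class `rate_constants`.
#' @seealso [lambda_rates()] for the concluded parameter set of the enzyme,
#'   [eq_constants()], [on_rates()], [scale_rates()].
#' @examples
#' r <- rate_constants(kB_off = 18, kB_b = 25, kA_off = 0.1, kA_b = 0.34)
#' eq_constants(r)
#' on_rates(r, mg = 3)
#' @export
rate_constants <- function(kB_off, kB_b, kA_off, kA_b) {
  x <- c(kB_off = kB_off, kB_b = kB_b, kA_off = kA_off, kA_b = kA_b)
  if (length(x) != 4L || !is.numeric(x)) {
    stop("all four rate constants must be numeric scalars")
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("rate constants must be strictly positive and finite, got: ",
         paste(sprintf("%s=%g", names(x), x), collapse = ", "))
  }
  structure(as.list(x), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  K <- eq_constants(x)
  cat("Two-metal-ion rate constants\n")
  cat(sprintf("  kB_off = %g s^-1   kB_b = %g s^-1 mM^-1  (K_B = %.4g mM)\n",
              x$kB_off, x$kB_b, K[["K_B"]]))
  cat(sprintf("  kA_off = %g s^-1   kA_b = %g s^-1 mM^-1  (K_A = %.4g mM)\n",
              x$kA_off, x$kA_b, K[["K_A"]]))
  invisible(x)
}

#' Equilibrium dissociation constants
#'
#' @param rates A [rate_constants()] object.
#' @return Named numeric vector `c(K_A =, K_B =)` in mM, recomputed from the
#'   stored rates.
#' @export
eq_constants <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  c(K_A = rates$kA_off / rates$kA_b, K_B = rates$kB_off / rates$kB_b)
}

#' Pseudo-first-order binding rates at a Mg2+ concentration
#'
#' @param rates A [rate_constants()] object.
#' @param mg Mg2+ concentration in mM (non-negative scalar).
#' @return Named numeric vector `c(kA_on =, kB_on =)` in s^-1.
#' @export
on_rates <- function(rates, mg) {
  stopifnot(inherits(rates, "rate_constants"))
  mg <- check_mg(mg, allow_zero = TRUE)
  c(kA_on = rates$kA_b * mg, kB_on = rates$kB_b * mg)
}

#' Scale all four rate constants by a common factor
#'
#' Quenched disorder perturbs the activation free energy of one molecule by
#' dG (in kB*T), multiplying every rate constant by `exp(-dG)`. Equilibrium
#' constants are invariant under this scaling.
#'
#' @param rates A [rate_constants()] object.
#' @param factor Positive multiplicative factor, typically `exp(-dG)`.
#' @return A new `rate_constants` object.
#' @export
scale_rates <- function(rates, factor) {
  stopifnot(inherits(rates, "rate_constants"),
            is.numeric(factor), length(factor) == 1L, is.finite(factor),
            factor > 0)
  rate_constants(rates$kB_off * factor, rates$kB_b * factor,
                 rates$kA_off * factor, rates$kA_b * factor)
}

#' Concluded rate constants for lambda exonuclease
#'
#' The parameter set concluded for the enzyme from Mg2+-titration velocity
#' data and log-velocity histogram matching: `kB_off = 18` s^-1,
#' `K_B = 0.71` mM, `K_A = 0.30` mM and `kA_off = 0.1` s^-1. Binding rates
#' are derived from the equilibrium constants (`kB_b = 18/0.71 = 25.35`,
#' `kA_b = 0.1/0.30 = 0.333`), of which 25 and 0.34 are the conventionally
#' quoted rounded values.
#'
#' @return A [rate_constants()] object.
#' @export
lambda_rates <- function() {
  rate_constants(kB_off = 18, kB_b = 18 / 0.71, kA_off = 0.1, kA_b = 0.1 / 0.30)
}

#' Standard Mg2+ titration grid
#'
#' The ten non-zero Mg2+ concentrations (mM) of the titration series used for
#' velocity-curve fitting. 0 mM supports no degradation and is excluded.
#'
#' @return Numeric vector of concentrations in mM.
#' @export
mg_concentrations <- function() {
  c(0.03, 0.08, 0.1, 0.2, 0.3, 0.5, 1, 3, 6, 9)
}

#' Model specification for the degradation kinetics
#'
#' Binds a reaction-scheme variant, the number of nucleotides to degrade, and
#' a set of rate constants.
#'
#' Two variants are supported:
#' * `"model1"` (sequential dissociation): the B-site ion leaves on each
#'   cleavage/translocation step (EMM -> EM at `kB_off`); the A-site ion
#'   leaves only stochastically (EM -> E at `kA_off`).
#' * `"model2"` (coincident dissociation): cleavage expels both ions
#'   (EMM -> E at `kB_off`); both must rebind before the next cleavage.
#'
#' @param variant `"model1"` or `"model2"`.
#' @param n_sites Number of nucleotides degraded between the FRET reporter
#'   dyes (default 20).
#' @param rates A [rate_constants()] object.
#' @return An object of class `model_spec`.
#' @examples
#' spec <- model_spec("model1", rates = lambda_rates())
#' mean_velocity(spec, mg = 3)
#' @export
model_spec <- function(variant = c("model1", "model2"), n_sites = 20,
                       rates = lambda_rates()) {
  variant <- match.arg(variant)
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1 ||
      n_sites != round(n_sites)) {
    stop("n_sites must be a positive integer (got ", n_sites, ")")
  }
  stopifnot(inherits(rates, "rate_constants"))
  structure(list(variant = variant, n_sites = as.integer(n_sites),
                 rates = rates),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Degradation model '%s', N = %d nt\n", x$variant, x$n_sites))
  print(x$rates)
  invisible(x)
}

#' Hill equation parameters
#'
#' @param v_max Maximum velocity, nt s^-1.
#' @param K Half-saturation concentration, mM.
#' @param n Hill coefficient (dimensionless).
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(v_max, K, n = 1) {
  x <- c(v_max = v_max, K = K, n = n)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("Hill parameters must be strictly positive and finite")
  }
  structure(as.list(x), class = "hill_params")
}

# shared concentration validation; zero only allowed where an explicit
# limit branch exists
check_mg <- function(mg, allow_zero = FALSE) {
  if (!is.numeric(mg) || length(mg) != 1L || !is.finite(mg)) {
    stop("mg must be a finite numeric scalar (mM)")
  }
  if (mg < 0 || (!allow_zero && mg == 0)) {
    stop("Mg2+ concentration must be ", if (allow_zero) "non-negative"
         else "strictly positive", " (got ", mg, " mM)")
  }
  mg
}
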