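#' Mean degradation velocity
#'
#' Closed-form mean velocity (nt s^-1) of the three-state metal-ion cycle at a
#' Mg2+ concentration `mg`.
#'
#' For the sequential scheme (`model1`),
#' \deqn{V = \frac{k_B^{off}\,c}{c + K_B + K_B K_A / c},}
#' with `c = [Mg2+]`. For the coincident scheme (`model2`) the mean cycle time
#' is the exact renewal sum
#' \deqn{\tau_1 = 1/k_B^{off} + 1/k_A^{on} + 1/k_B^{on} +
#'   k_A^{off}/(k_A^{on} k_B^{on})}
#' and `V = 1/tau_1`. For both variants `V` is strictly increasing in `c`,
#' tends to `kB_off` as `c -> Inf`, and equals `n_sites` divided by the mean
#' first-passage time of the corresponding master equation (see
#' [mean_first_passage_time()]). The model-2 velocity can equivalently be
#' written in the titration-curve form
#' `kB_off / (1 + S/c + P/c^2)` with the *effective* coefficients
#' `(S, P)` returned by [model2_effective_constants()]; note these are not the
#' raw equilibrium constants unless `kA_off = kB_off`.
#'
#' @param spec A [model_spec()].
#' @param mg Mg2+ concentration, mM. Must be positive unless
#'   `zero_limit = TRUE`.
#' @param zero_limit If `TRUE`, `mg = 0` returns the limiting velocity 0
#'   instead of raising an error (the raw formula divides by zero).
#' @return Mean velocity in nt s^-1.
#' @examples
#' mean_velocity(model_spec("model1", rates = lambda_rates()), mg = 9)
#' @export
mean_velocity <- function(spec, mg, zero_limit = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  mg <- check_mg(mg, allow_zero = zero_limit)
  if (mg == 0) return(0)
  r <- spec$rates
  K <- eq_constants(r)
  if (spec$variant == "model1") {
    r$kB_off * mg / (mg + K[["K_B"]] + K[["K_B"]] * K[["K_A"]] / mg)
  } else {
    on <- on_rates(r, mg)
    1 / (1 / r$kB_off + 1 / on[["kA_on"]] + 1 / on[["kB_on"]] +
           r$kA_off / (on[["kA_on"]] * on[["kB_on"]]))
  }
}

#' Mean degradation time per nucleotide
#'
#' `tau1 = 1 / mean_velocity` (an algebraic identity). For the sequential
#' scheme it decomposes as `1/kB_off + tau_d + 1/kB_on`: the cleavage step,
#' the mean time spent in excursions to the apo state E per cycle
#' ([tau_d()]), and the B-ion rebinding step.
#'
#' @inheritParams mean_velocity
#' @return Time in seconds.
#' @export
tau1 <- function(spec, mg) {
  1 / mean_velocity(spec, mg)
}

#' Mean per-cycle dwell contributed by A-ion excursions
#'
#' In the sequential scheme the enzyme in EM either rebinds the B ion
#' (rate `kB_on`) or loses the A ion (rate `kA_off`) and must wait for it to
#' rebind. Summing the geometric series over the number of excursions to E
#' gives the closed form `kA_off / (kA_on * kB_on)`.
#'
#' @param rates A [rate_constants()] object.
#' @param mg Mg2+ concentration, mM (> 0).
#' @return Time in seconds.
#' @export
tau_d <- function(rates, mg) {
  stopifnot(inherits(rates, "rate_constants"))
  mg <- check_mg(mg)
  on <- on_rates(rates, mg)
  rates$kA_off / (on[["kA_on"]] * on[["kB_on"]])
}

#' Hill and Michaelis-Menten reference velocity curves
#'
#' `hill_velocity` evaluates `v_max * c^n / (c^n + K^n)`; `mm_velocity` is the
#' `n = 1` special case.
#'
#' @param p A [hill_params()] object.
#' @param mg Mg2+ concentration, mM (>= 0; both curves vanish at 0).
#' @return Velocity in nt s^-1.
#' @export
hill_velocity <- function(p, mg) {
  stopifnot(inherits(p, "hill_params"))
  mg <- check_mg(mg, allow_zero = TRUE)
  p$v_max * mg^p$n / (mg^p$n + p$K^p$n)
}

#' @rdname hill_velocity
#' @param v_max Maximum velocity, nt s^-1.
#' @param K_m Michaelis constant, mM.
#' @export
mm_velocity <- function(v_max, K_m, mg) {
  hill_velocity(hill_params(v_max, K_m, n = 1), mg)
}

#' Kinetic-barrier difference between the two dissociation steps
#'
#' The difference in activation free energy for dissociation of the B-site
#' and A-site ions, in units of kB*T: `log(kB_off / kA_off)` (natural log).
#' For the concluded constants 18 and 0.1 s^-1 this is ~5.2 kB*T, i.e. the
#' A ion dissociates ~200-fold more slowly.
#'
#' @param rates A [rate_constants()] object.
#' @return Energy difference in kB*T units.
#' @export
barrier_difference <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  log(rates$kB_off / rates$kA_off)
}

#' Effective titration-curve coefficients of the coincident scheme
#'
#' When the model-2 mean velocity is written in the titration form
#' `V(c) = kB_off / (1 + S/c + P/c^2)` (the same functional family as the
#' model-1 curve), the coefficients are
#' `S = kB_off * (1/kA_b + 1/kB_b)` and `P = kA_off * kB_off / (kA_b * kB_b)`.
#' A fit of the titration curve therefore determines `(kB_off, S, P)`; the
#' pair of "effective equilibrium constants" `(K_A, K_B)` reported by such a
#' fit are the roots of `x^2 - S x + P`. [model2_binding_rates()] inverts this
#' relation.
#'
#' @param rates A [rate_constants()] object.
#' @return List with `K_sum` (S, mM), `K_prod` (P, mM^2) and `K_pair`, the
#'   root pair sorted increasingly (`NA` if complex).
#' @export
model2_effective_constants <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  S <- rates$kB_off * (1 / rates$kA_b + 1 / rates$kB_b)
  P <- rates$kA_off * rates$kB_off / (rates$kA_b * rates$kB_b)
  disc <- S^2 - 4 * P
  pair <- if (disc >= 0) sort(c((S - sqrt(disc)) / 2, (S + sqrt(disc)) / 2))
          else c(NA_real_, NA_real_)
  list(K_sum = S, K_prod = P, K_pair = pair)
}

#' Binding rates of the coincident scheme from fitted constants
#'
#' Given the parameters `(K_A, K_B, kB_off)` determined by fitting the
#' titration curve under the coincident-dissociation interpretation, and a
#' candidate `kA_off`, the two bimolecular binding rates are the roots of a
#' quadratic:
#' \deqn{k_{A,B}^b = \frac{(K_A+K_B) k_A^{off} \mp
#'   \sqrt{k_A^{off\,2}(K_A+K_B)^2 - 4 k_B^{off} k_A^{off} K_A K_B}}
#'   {2 K_A K_B}.}
#' The assignment `kA_b <= kB_b` reflects the structural expectation that the
#' buried A site binds its ion more slowly. A real solution exists iff
#' `kA_off >= model2_kAoff_lower_bound(K_A, K_B, kB_off)`.
#'
#' @param K_A,K_B Effective equilibrium constants from the titration fit, mM.
#' @param kB_off Cleavage/translocation rate, s^-1.
#' @param kA_off Candidate A-ion dissociation rate, s^-1.
#' @return Named numeric vector `c(kA_b =, kB_b =)` in s^-1 mM^-1.
#' @export
model2_binding_rates <- function(K_A, K_B, kB_off, kA_off) {
  stopifnot(K_A > 0, K_B > 0, kB_off > 0, kA_off > 0)
  disc <- kA_off^2 * (K_A + K_B)^2 - 4 * kB_off * kA_off * K_A * K_B
  # round-off guard: exactly-critical inputs may land epsilon-negative
  if (disc < 0 && disc > -1e-12 * kA_off^2 * (K_A + K_B)^2) disc <- 0
  if (disc < 0) {
    stop(sprintf(paste0(
      "coincident-dissociation scheme infeasible: kA_off = %g s^-1 is below ",
      "the bound 4*K_A*K_B*kB_off/(K_A+K_B)^2 = %g s^-1"),
      kA_off, model2_kAoff_lower_bound(K_A, K_B, kB_off)))
  }
  root <- sqrt(disc)
  den <- 2 * K_A * K_B
  c(kA_b = ((K_A + K_B) * kA_off - root) / den,
    kB_b = ((K_A + K_B) * kA_off + root) / den)
}

#' Feasibility bound on the coincident-scheme dissociation rate
#'
#' The smallest `kA_off` for which [model2_binding_rates()] has a real
#' solution: `4 * K_A * K_B * kB_off / (K_A + K_B)^2`. Equality holds iff the
#' two binding rates coincide (double root); by the AM-GM inequality the
#' bound equals `kB_off` when `K_A = K_B`.
#'
#' For the printed constants `K_A = 0.30`, `K_B = 0.71`, `kB_off = 18` the
#' formula gives 15.03 s^-1; the originally quoted 31.4 s^-1 derives from an
#' unpublished coincident-scheme refit and is not reproducible from the
#' printed values (see the methods vignette).
#'
#' @inheritParams model2_binding_rates
#' @return Rate in s^-1.
#' @export
model2_kAoff_lower_bound <- function(K_A, K_B, kB_off) {
  stopifnot(K_A > 0, K_B > 0, kB_off > 0)
  4 * K_A * K_B * kB_off / (K_A + K_B)^2
}
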