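# Independent oracles used to freeze expected values. These deliberately do
# not reuse package internals beyond basic constructors.

# trapezoid integral (local copy so oracle checks do not depend on the
# package's own quadrature helpers)
trapz_o <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# two-exponential (hypoexponential) density with distinct rates a, b
hypoexp_density <- function(t, a, b) {
  a * b / (b - a) * (exp(-a * t) - exp(-b * t))
}

# closed-form N = 1 mean first-passage time of the sequential scheme,
# assembled term by term (cleavage + A-excursions + B rebinding)
mfpt1_oracle <- function(kB_off, kB_b, kA_off, kA_b, mg) {
  1 / kB_off + kA_off / ((kA_b * mg) * (kB_b * mg)) + 1 / (kB_b * mg)
}

# Monte-Carlo oracle for the per-cycle A-excursion dwell: the number of
# excursions to E per cycle is geometric with success probability
# kB_on/(kB_on + kA_off); each excursion lasts Exp(kA_on)
tau_d_mc_oracle <- function(kB_off, kB_b, kA_off, kA_b, mg, n = 1e6,
                            seed = 1) {
  withr::with_seed(seed, {
    kA_on <- kA_b * mg
    kB_on <- kB_b * mg
    m <- stats::rgeom(n, kB_on / (kB_on + kA_off))
    tot <- numeric(n)
    pos <- m > 0
    tot[pos] <- stats::rgamma(sum(pos), shape = m[pos], rate = kA_on)
    list(mean = mean(tot), se = stats::sd(tot) / sqrt(n))
  })
}

# quadratic-root oracle for the coincident-scheme binding rates via polyroot
model2_roots_oracle <- function(K_A, K_B, kB_off, kA_off) {
  S <- kA_off * (K_A + K_B) / (K_A * K_B)
  P <- kA_off * kB_off / (K_A * K_B)
  rt <- sort(Re(polyroot(c(P, -S, 1))))
  c(kA_b = rt[1], kB_b = rt[2])
}

# empirical CDF comparison grid for fp densities
fp_cdf_fun <- function(pdf) {
  stats::approxfun(pdf$x, lexokin:::cumtrapz(pdf$x, pdf$density) / pdf$mass,
                   yleft = 0, yright = 1)
}

# pause records pooled over n simulated traces
pooled_pauses <- function(spec, mg, n_traces, seed, min_dwell = 2) {
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_traces), function(i) {
      p <- extract_pauses(simulate_trajectory(spec, mg),
                         min_dwell = min_dwell)
      if (nrow(p) > 0L) p$trace_id <- i
      p
    })
    keep <- vapply(out, nrow, integer(1)) > 0L
    if (!any(keep)) return(NULL)
    do.call(rbind, out[keep])
  })
}
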