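# small numeric utilities shared across modules

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) * diff(x) / 2))
}

geom_grid <- function(from, to, n) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# FNV-1a hash over the serialized object; used to stamp outputs with a
# config fingerprint without a digest dependency.
object_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)  # xor touches the low byte only
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
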