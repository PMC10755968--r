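#' @keywords internal
"_PACKAGE"

#' @importFrom stats plogis quantile rnorm runif setNames predict coef fitted residuals simulate
#' @importFrom utils read.table write.table write.csv head
NULL

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: one root seed fans out to per-purpose
# streams so e.g. ablation variants share initial conditions. Kept < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629L)
}

# Numerically stable softplus log(1 + exp(x)).
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

stop_arg <- function(...) stop(..., call. = FALSE)
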