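#' @keywords internal
"_PACKAGE"

#' @importFrom stats ar fft filter ks.test optim quantile rnorm runif rexp
#'   sd var dnorm approx predict glm binomial coef wilcox.test p.adjust
#'   cor setNames median rgamma rpois
#' @importFrom utils head tail combn modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib tremorlab, .registration = TRUE
NULL

# Deterministic child seeds below 2^31, derived from a master seed and a
# variable number of integer offsets. Plain integer mixing; stable across
# platforms because everything stays inside the exact-double range.
derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  h <- 0
  for (p in parts) h <- (h * 1103515245 + as.numeric(p) + 12345) %% 2147483647
  as.integer(h)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library code never disturbs user RNG streams.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

recording_key <- function(patient_id, condition, hand) {
  paste(patient_id, condition, hand, sep = "/")
}

stop_rec <- function(rec_name, fmt, ...) {
  stop(sprintf("recording '%s': %s", rec_name, sprintf(fmt, ...)), call. = FALSE)
}
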