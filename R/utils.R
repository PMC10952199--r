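#' Inverse logit
#'
#' @param x numeric vector on the log-odds scale.
#' @return probabilities in (0, 1).
#' @export
expit <- function(x) stats::plogis(x)

#' Logit
#'
#' @param p probabilities in (0, 1).
#' @return log-odds.
#' @export
logit <- function(p) stats::qlogis(p)

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

#' Derive a reproducible child seed
#'
#' Deterministically maps a root seed plus a stream label (e.g. scenario id and
#' replicate index) to a child seed below 2^31, so that scenarios and
#' replicates get independent, scheduling-invariant random streams.
#'
#' @param root_seed integer root seed.
#' @param scenario_id integer scenario identifier.
#' @param rep integer replicate index (default 0).
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(root_seed, scenario_id, rep = 0L) {
  # multiplicative hashing; all intermediates stay below 2^53 so doubles are exact
  m <- 2147483629 # largest prime < 2^31
  h <- (as.numeric(root_seed) %% m) * 40503 %% m
  h <- (h + as.numeric(scenario_id)) * 2654435 %% m
  h <- (h + as.numeric(rep)) * 40503 %% m
  as.integer(h %% m)
}

# Evaluate expr with a given seed without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
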