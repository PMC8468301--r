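#' @keywords internal
"_PACKAGE"

utils::globalVariables(c("obs", "pred", "group", "anchor", "zeta", "sspb"))

# hours per day; all internal times are hours, user-facing windows in days
HOURS_PER_DAY <- 24

#' Derive a reproducible substream seed from a top-level seed
#'
#' All stochastic components (cohort generation, VPC replicates, multi-start
#' perturbations) draw their seed from a single top-level seed through a
#' labelled hash, so that adding one component never shifts the random
#' numbers consumed by another.
#'
#' @param seed Integer top-level seed.
#' @param label Character label naming the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) %% 2147483647 + h * 10007) %% 2147483646)
}

# Evaluate `expr` with the given seed while leaving the caller's RNG state
# untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# quantile with type 7 everywhere, kept in one place
qtl <- function(x, p) unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
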