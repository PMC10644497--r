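#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats rnbinom rlnorm rnorm rpois runif rgamma sd var cor
#'   pchisq pt phyper p.adjust quantile loess predict median setNames
#'   glm.fit lm.fit binomial shapiro.test t.test wilcox.test dist hclust
#'   rbinom na.omit
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seed from the single
#' run seed via this hash, so stages are decoupled: changing the number of
#' random draws in one stage does not perturb the others.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(seed) %% 2147480009 * 131 + h) %% 2147480009 + 1)
}

# run expr with a local RNG state seeded by `seed`; restores global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# coerce counts (base matrix or any Matrix) to double CsparseMatrix
to_sparse <- function(m) {
  if (!inherits(m, "Matrix")) m <- Matrix::Matrix(as.matrix(m), sparse = TRUE)
  as(as(m, "CsparseMatrix"), "dMatrix")
}
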