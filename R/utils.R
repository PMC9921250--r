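#' @useDynLib clinstack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate cor glm lm median pchisq predict pnorm qnorm
#'   quantile rbinom rnorm runif sd var setNames binomial coef mad
#'   complete.cases dist
#' @importFrom utils head read.csv write.csv
NULL

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded components do not
#' perturb each other.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# stable rank of scores, best (largest) first; ties broken by position
order_desc_stable <- function(scores) order(-scores, seq_along(scores))

abort <- function(msg, class) {
  stop(structure(class = c(class, "clinstack_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample skewness (g1, biased moment estimator)
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}
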