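#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist lm pf prcomp pnorm qnorm rnorm runif sd
#'   shapiro.test var complete.cases coef
#' @importFrom utils read.csv write.csv head
NULL

## Run code under a local RNG state seeded with `seed`, restoring the
## caller's stream afterwards. All stochastic entry points funnel through
## this so a user-level seed gives reproducible results without clobbering
## the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Deterministic per-stage substream: hash a tag string into the master seed
## so stages rerun in isolation reproduce the pipeline's stream.
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}

## Sample-moment skewness (g1); used as the shape gate for SES correction.
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

#' Validate a labelled distance matrix
#'
#' Checks the contract shared by every distance matrix in the pipeline:
#' square, labelled, symmetric (within 1e-9), non-negative, zero diagonal.
#'
#' @param d numeric matrix with identical row and column labels.
#' @return `d`, invisibly, after validation.
#' @export
validate_distance_matrix <- function(d) {
  stopifnot(is.matrix(d), is.numeric(d))
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    stop("distance matrix must carry row and column labels")
  if (!identical(rownames(d), colnames(d)))
    stop("row and column labels differ")
  if (anyDuplicated(rownames(d))) stop("duplicate labels in distance matrix")
  if (any(!is.finite(d))) stop("non-finite distances")
  if (any(d < 0)) stop("negative distances")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix not symmetric (tol 1e-9)")
  if (any(abs(diag(d)) > 0)) stop("distance matrix diagonal must be exactly 0")
  invisible(d)
}
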