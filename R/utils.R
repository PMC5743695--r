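#' @useDynLib elevdisp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats lm coef sd var setNames rexp rnorm runif quantile
#' @importFrom utils head
NULL

#' Derive a per-stage random seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seed from one master
#' integer through this documented splitter, so the full analysis is
#' reproducible from a single number while stages stay independently
#' re-runnable. The split is `(seed * 48271 + 11 * counter) mod (2^31 - 1)`,
#' a Lehmer-style mix that keeps results within R's integer range.
#'
#' @param seed master integer seed.
#' @param counter non-negative integer identifying the stage (documented in
#'   [run_all()]).
#' @return an integer seed.
#' @export
split_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(counter))
  m <- 2147483647
  as.integer((abs(seed) * 48271 + 11 * counter) %% m)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(seed)
  force(code)
}

#' Validate a labelled distance matrix
#'
#' Checks the contract shared by every distance carrier in the package:
#' square, labelled, symmetric to 1e-12, nonnegative, zero diagonal.
#'
#' @param d numeric matrix with identical row and column names.
#' @return `d`, invisibly, after validation.
#' @export
validate_distance_matrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d)) || is.null(colnames(d)) ||
      !identical(rownames(d), colnames(d))) {
    stop("distance matrix must carry identical row and column labels")
  }
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be exactly 0")
  if (any(d < 0)) stop("distances must be nonnegative")
  invisible(d)
}

# coerce a binary/count community matrix to integer storage with dimnames
as_comm_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("community matrix must have site rownames and species colnames")
  }
  m
}
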