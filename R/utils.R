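.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Validate a row-stochastic matrix
#'
#' Checks that a matrix is square, non-negative and that every row sums to 1
#' within \code{tol}. Errors name the first offending row.
#'
#' @param tpm numeric matrix.
#' @param tol numeric tolerance on row sums.
#' @return \code{TRUE}, invisibly.
#' @export
checkStochasticMatrix <- function(tpm, tol = 1e-9) {
  if (!is.matrix(tpm) || nrow(tpm) != ncol(tpm))
    .stopf("transition matrix must be square (got %d x %d)",
           NROW(tpm), NCOL(tpm))
  if (any(tpm < -tol))
    .stopf("transition matrix has negative entries (first in row %d)",
           which(apply(tpm, 1, function(r) any(r < -tol)))[1])
  rs <- rowSums(tpm)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    .stopf("row %d of transition matrix sums to %.12g, not 1", bad[1], rs[bad[1]])
  invisible(TRUE)
}

#' Derive a per-stream child seed from a master seed
#'
#' Deterministic counter scheme used by all generators: child i of master m is
#' \code{(m * 10007 + i) mod (2^31 - 1)}. Keeps every derived seed a valid
#' 32-bit integer and makes each trajectory individually regenerable.
#'
#' @param master integer master seed.
#' @param index positive integer stream index.
#' @return integer seed.
#' @export
deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483647 * 10007 + index) %% 2147483647)
}

# gas constant in kcal/(mol K), the unit convention of the free-energy module
.R_KCAL <- 0.0019872

.isWholeNumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol * max(1, abs(x))

.resKey <- function(segment, resid) paste0(segment, ":", resid)
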