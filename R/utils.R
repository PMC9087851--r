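#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data .env
#' @useDynLib tractsens, .registration = TRUE
NULL

# Derive a child seed from a master seed. Keeps results reproducible when one
# master seed drives many subjects/volumes, and stays below .Machine$integer.max.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1103515245 + 12345 * as.double(index)) %% 2147483647L)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Near-uniform unit vectors on the sphere (spherical Fibonacci lattice).
# Deterministic; used for gradient tables and kurtosis direction averages.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Unit vectors spread on a hemisphere (antipodally symmetric designs);
# conventional for diffusion gradient schemes.
hemisphere_dirs <- function(n) {
  v <- fibonacci_sphere(2L * n)
  v <- v[v[, 3] >= 0, , drop = FALSE]
  v[seq_len(n), , drop = FALSE]
}

vnorm <- function(x) sqrt(sum(x^2))
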