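#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

#' Gaussian radial-basis expansion of a distance
#'
#' Expands a scalar distance into `n_centers` Gaussian basis values with
#' centers evenly spaced on `[0, cutoff]` and bandwidth equal to the center
#' spacing, so a distance sitting exactly on a center contributes 1.0 there.
#'
#' @param distance numeric vector of distances (Angstrom), all >= 0.
#' @param cutoff upper end of the center grid (Angstrom).
#' @param n_centers number of Gaussian centers.
#' @return a matrix with `length(distance)` rows and `n_centers` columns.
#' @export
rbf_expand <- function(distance, cutoff, n_centers = 16L) {
  .assert(all(is.finite(distance)) && all(distance >= 0), "distances must be finite and non-negative")
  .assert(cutoff > 0, "cutoff must be positive")
  centers <- seq(0, cutoff, length.out = n_centers)
  width <- centers[2L] - centers[1L]
  out <- exp(-((outer(distance, centers, "-")) / width)^2)
  dimnames(out) <- NULL
  out
}

# FNV-1a hash of an arbitrary R object (config fingerprints for checkpoints).
.obj_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L)[-seq_len(14L)]) # skip header
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Deterministic pairwise Euclidean distance matrix for an n x 3 coordinate
# matrix. Plain O(n^2); node counts here are small by design.
.pairwise_dist <- function(a, b = NULL) {
  if (is.null(b)) b <- a
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

.is_coord <- function(x) is.numeric(x) && length(x) == 3L && all(is.finite(x))
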