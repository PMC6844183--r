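#' ICE matrix balancing
#'
#' Iterative correction of a raw contact matrix under the factorization
#' assumption M[i,j] = b_i * b_j * Mhat[i,j]: the observed contact between
#' two loci is the true relative contact probability distorted by the product
#' of two per-bin visibility biases. The algorithm alternates dividing rows
#' and columns by their relative marginals until the unmasked row sums are
#' equal (coefficient of variation below \code{tolerance}).
#'
#' Before iterating, the \code{ignore_low} fraction of bins with the lowest
#' marginal coverage is masked out (bins with no coverage at all are always
#' masked, since their row sums cannot be balanced), and the top \code{winsor_high} fraction
#' of upper-triangle entries is capped at the corresponding quantile to damp
#' high-abundance bin pairs. The balanced matrix is rescaled so the mean
#' unmasked row sum of the (masked, winsorized) input is preserved. Masked
#' bins yield NA rows/columns; with \code{na_policy = "set_min"} every NA is
#' replaced by the minimum finite entry of the normalized matrix.
#'
#' @param M A raw \code{ContactMatrix} or a plain symmetric non-negative
#'   matrix.
#' @param winsor_high Fraction of highest upper-triangle entries to cap
#'   (default 0.02).
#' @param ignore_low Fraction of lowest-coverage bins to mask (default 0).
#' @param max_iterations Iteration cap (default 200).
#' @param tolerance Row-sum coefficient-of-variation target (default 1e-8).
#' @param na_policy \code{"keep_na"} (default) or \code{"set_min"}.
#' @return list with \code{matrix} (normalized; a \code{ContactMatrix} when
#'   the input was one), \code{biases} (per-bin, NA for masked bins),
#'   \code{converged}, \code{iterations}.
#' @export
ice_normalize <- function(M, winsor_high = 0.02, ignore_low = 0,
                          max_iterations = 200, tolerance = 1e-8,
                          na_policy = c("keep_na", "set_min")) {
  na_policy <- match.arg(na_policy)
  is_cm <- inherits(M, "ContactMatrix")
  bins <- if (is_cm) M$bins else NULL
  X <- if (is_cm) M$matrix else M
  X <- matrix(as.numeric(X), nrow(X))
  n <- nrow(X)
  stopifnot(n == ncol(X))
  if (winsor_high < 0 || winsor_high >= 1 || ignore_low < 0 || ignore_low >= 1
      || winsor_high + ignore_low >= 1)
    stop("winsor_high and ignore_low must be fractions with sum < 1")
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (any(X < 0)) stop("contact matrix must be non-negative")
  if (all(X == 0)) stop("all-zero matrix cannot be balanced")

  # mask the lowest-coverage fraction of bins; bins with no coverage at all
  # are always masked, since their row sums can never be balanced
  marg <- rowSums(X)
  n_mask <- floor(ignore_low * n)
  masked <- if (n_mask > 0) order(marg)[seq_len(n_mask)] else integer()
  masked <- union(masked, which(marg == 0))
  unmasked <- setdiff(seq_len(n), masked)
  if (length(unmasked) < 2L) stop("fewer than 2 unmasked bins remain")

  W <- X
  W[masked, ] <- 0
  W[, masked] <- 0
  if (winsor_high > 0) {
    ut <- W[upper.tri(W, diag = TRUE)]
    cap <- stats::quantile(ut, 1 - winsor_high, names = FALSE)
    W[W > cap] <- cap
    W[masked, ] <- 0
    W[, masked] <- 0
  }
  target <- mean(rowSums(W)[unmasked])
  if (target == 0) stop("unmasked part of the matrix is all zero")

  b <- rep(1, n)
  converged <- FALSE
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    s <- rowSums(W)
    su <- s[unmasked]
    m <- mean(su)
    cv <- if (m > 0) stats::sd(su) / m else Inf
    if (is.finite(cv) && cv < tolerance) { converged <- TRUE; break }
    db <- s / m
    db[db == 0] <- 1
    db[masked] <- 1
    W <- W / outer(db, db)
    b <- b * db
  }
  if (!converged) {
    s <- rowSums(W)[unmasked]
    converged <- stats::sd(s) / mean(s) < tolerance
    if (!converged)
      warning("ICE did not converge within ", max_iterations, " iterations")
  }

  alpha <- target / mean(rowSums(W)[unmasked])
  Mhat <- W * alpha
  biases <- b / sqrt(alpha)
  Mhat <- (Mhat + t(Mhat)) / 2     # remove round-off asymmetry
  Mhat[masked, ] <- NA_real_
  Mhat[, masked] <- NA_real_
  biases[masked] <- NA_real_
  if (na_policy == "set_min" && anyNA(Mhat))
    Mhat[is.na(Mhat)] <- min(Mhat, na.rm = TRUE)

  out <- if (is_cm) contact_matrix(Mhat, bins, normalized = TRUE,
                                   biases = biases) else Mhat
  list(matrix = out, biases = biases, converged = converged, iterations = it)
}

# -- mean-preserving Haar pyramid (analysis used by the Haar-Fisz transform) -

.haar_analyze <- function(v) {
  details <- list()
  s <- v
  while (length(s) > 1L) {
    even <- s[seq(1L, length(s), 2L)]
    odd <- s[seq(2L, length(s), 2L)]
    details[[length(details) + 1L]] <- (even - odd) / 2
    s <- (even + odd) / 2
  }
  list(s0 = s, details = details)   # details[[1]] = finest
}

.haar_synthesize <- function(s0, details) {
  s <- s0
  for (j in rev(seq_along(details))) {
    d <- details[[j]]
    out <- numeric(2L * length(s))
    out[seq(1L, length(out), 2L)] <- s + d
    out[seq(2L, length(out), 2L)] <- s - d
    s <- out
  }
  s
}

#' Haar-Fisz variance stabilization of a Poisson count vector
#'
#' Decomposes the vector into its Haar smooth/detail pyramid, divides each
#' detail by the square root of the corresponding smooth coefficient (the
#' local intensity estimate, which for Poisson data is also the local
#' variance), and re-synthesizes. The result has approximately unit noise
#' variance, so Gaussian wavelet shrinkage applies.
#'
#' @param v Non-negative numeric vector, length a power of two.
#' @return Stabilized vector of the same length.
#' @export
haar_fisz <- function(v) {
  .check_pow2(length(v))
  a <- .haar_analyze(v)
  f <- lapply(seq_along(a$details), function(j) {
    s <- .smooth_at_level(v, j)
    d <- a$details[[j]]
    out <- ifelse(s > 0, d / sqrt(s), 0)
    out
  })
  .haar_synthesize(a$s0, f)
}

#' Inverse of [haar_fisz()]
#'
#' @param u Stabilized vector, length a power of two.
#' @return Reconstructed count-scale vector.
#' @export
haar_fisz_inverse <- function(u) {
  .check_pow2(length(u))
  a <- .haar_analyze(u)
  J <- length(a$details)
  s <- a$s0
  for (j in J:1) {
    f <- a$details[[j]]
    d <- ifelse(s > 0, f * sqrt(s), 0)
    out <- numeric(2L * length(s))
    out[seq(1L, length(out), 2L)] <- s + d
    out[seq(2L, length(out), 2L)] <- s - d
    s <- out
  }
  s
}

# smooth (local mean) coefficients of v at detail level j (1 = finest)
.smooth_at_level <- function(v, j) {
  s <- v
  for (k in seq_len(j)) {
    even <- s[seq(1L, length(s), 2L)]
    odd <- s[seq(2L, length(s), 2L)]
    s <- (even + odd) / 2
  }
  s
}

.check_pow2 <- function(n) {
  if (n < 1L || bitwAnd(n, n - 1L) != 0L)
    stop("length must be a power of two")
}

# orthonormal Haar DWT soft-threshold denoising with the universal threshold
.wavelet_denoise <- function(u) {
  n <- length(u)
  details <- list()
  s <- u
  while (length(s) > 1L) {
    even <- s[seq(1L, length(s), 2L)]
    odd <- s[seq(2L, length(s), 2L)]
    details[[length(details) + 1L]] <- (even - odd) / sqrt(2)
    s <- (even + odd) / sqrt(2)
  }
  fine <- details[[1L]]
  sigma <- stats::median(abs(fine)) / 0.6745
  lambda <- sigma * sqrt(2 * log(n))
  if (is.finite(lambda) && lambda > 0) {
    details <- lapply(details, function(d)
      sign(d) * pmax(abs(d) - lambda, 0))
  }
  for (j in rev(seq_along(details))) {
    d <- details[[j]]
    out <- numeric(2L * length(s))
    out[seq(1L, length(out), 2L)] <- (s + d) / sqrt(2)
    out[seq(2L, length(out), 2L)] <- (s - d) / sqrt(2)
    s <- out
  }
  s
}

#' Wavelet-denoising normalization of a single-chromosome contact block
#'
#' Treats the raw counts of one chromosome's diagonal block as Poisson
#' observations of a smooth contact intensity. Each row is variance
#' stabilized with the Haar-Fisz transform, denoised by Haar wavelet soft
#' shrinkage at the universal threshold, and transformed back; the result is
#' re-symmetrized by averaging with its transpose and clamped at zero.
#' Blocks whose dimension is not a power of two are zero-padded for the
#' transforms and cropped afterwards.
#'
#' @param M_chrom Square raw count block of one chromosome (plain matrix or
#'   the \code{matrix} element of [chrom_block()]).
#' @param remove_uncovered Mark bins with no coverage at all (all-zero row
#'   and column) as NA in the output (default FALSE).
#' @return Normalized block of the same dimension.
#' @export
wavsis_normalize <- function(M_chrom, remove_uncovered = FALSE) {
  X <- if (is.list(M_chrom) && !is.null(M_chrom$matrix)) M_chrom$matrix
       else M_chrom
  X <- matrix(as.numeric(X), nrow(X))
  n <- nrow(X)
  stopifnot(n == ncol(X))
  if (any(X < 0)) stop("raw block must be non-negative")
  uncov <- which(rowSums(X != 0) == 0 & colSums(X != 0) == 0)

  N <- 2^ceiling(log2(max(n, 1)))
  den <- matrix(0, n, N)
  for (i in seq_len(n)) {
    v <- c(X[i, ], rep(0, N - n))
    u <- haar_fisz(v)
    u <- .wavelet_denoise(u)
    den[i, ] <- haar_fisz_inverse(u)
  }
  Y <- den[, seq_len(n), drop = FALSE]
  Y <- (Y + t(Y)) / 2
  Y[Y < 0] <- 0
  if (remove_uncovered && length(uncov)) {
    Y[uncov, ] <- NA_real_
    Y[, uncov] <- NA_real_
  }
  Y
}
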