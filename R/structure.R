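#' A/B compartment analysis by eigenvector decomposition
#'
#' Computes principal-component eigenvectors of a per-chromosome normalized
#' contact block. Two input transforms are supported: \code{"oe_correlation"}
#' (default) divides every diagonal of the block by its mean (observed over
#' expected at that genomic distance), takes the Pearson correlation matrix,
#' and eigen-decomposes it; \code{"direct"} performs plain PCA of the
#' column-centered block. Compartments are read off the sign pattern of a
#' chosen component: bins with positive loadings interact preferentially
#' with each other and against the negative group.
#'
#' Rows containing NA are excluded and re-inserted as NA in the output. Each
#' eigenvector has unit norm and its global sign is fixed so that it
#' correlates positively with per-bin total coverage.
#'
#' @param M_chrom Square normalized block of one chromosome.
#' @param n_components Number of leading eigenvectors to return (default 2).
#' @param mode \code{"oe_correlation"} or \code{"direct"}.
#' @return list with \code{vectors} (n x n_components matrix, NA rows where
#'   input rows were NA or the decomposition was degenerate),
#'   \code{values} (eigenvalues) and \code{mode}.
#' @export
compartment_pca <- function(M_chrom, n_components = 2,
                            mode = c("oe_correlation", "direct")) {
  mode <- match.arg(mode)
  X <- matrix(as.numeric(M_chrom), nrow(M_chrom))
  n <- nrow(X)
  keep <- which(rowSums(is.na(X)) < n)
  keep <- keep[rowSums(is.na(X[keep, keep, drop = FALSE])) == 0]
  if (length(keep) < 2L) stop("fewer than 2 usable bins in the block")
  B <- X[keep, keep, drop = FALSE]
  m <- length(keep)
  k <- min(n_components, m)

  if (mode == "oe_correlation") {
    OE <- B
    offs <- abs(row(B) - col(B))
    for (d in 0:(m - 1L)) {
      idx <- which(offs == d)
      mu <- mean(B[idx])
      if (mu > 0) OE[idx] <- B[idx] / mu
    }
    C <- suppressWarnings(stats::cor(OE))
    C[!is.finite(C)] <- 0
    eg <- eigen(C, symmetric = TRUE)
    vec <- eg$vectors[, seq_len(k), drop = FALSE]
    val <- eg$values[seq_len(k)]
    degenerate <- abs(eg$values[1]) < 1e-10
  } else {
    pc <- stats::prcomp(B, center = TRUE, scale. = FALSE)
    kk <- min(k, ncol(pc$rotation))
    vec <- pc$rotation[, seq_len(kk), drop = FALSE]
    if (kk < k) vec <- cbind(vec, matrix(NA_real_, m, k - kk))
    val <- c(pc$sdev^2, rep(NA_real_, k))[seq_len(k)]
    degenerate <- pc$sdev[1] < 1e-10
  }

  cov_per_bin <- rowSums(B)
  for (j in seq_len(k)) {
    v <- vec[, j]
    if (all(is.na(v))) next
    v <- v / sqrt(sum(v^2))
    r <- suppressWarnings(stats::cor(v, cov_per_bin))
    if (is.finite(r) && r < 0) v <- -v
    vec[, j] <- v
  }
  if (degenerate) vec[] <- NA_real_

  out <- matrix(NA_real_, n, k)
  out[keep, ] <- vec
  list(vectors = out, values = val, mode = mode)
}

#' A/B labels from a compartment eigenvector
#'
#' @param pca Result of [compartment_pca()].
#' @param component Which eigenvector to use (default 1; at fine scales the
#'   second component often carries the compartment signal).
#' @return Character vector of \code{"A"}/\code{"B"}/NA per bin.
#' @export
compartment_labels <- function(pca, component = 1) {
  v <- pca$vectors[, component]
  ifelse(is.na(v), NA_character_, ifelse(v >= 0, "A", "B"))
}

#' Directionality index track
#'
#' For each bin, contrasts upstream and downstream contact totals with the
#' signed chi-square-like statistic
#' \deqn{d_i = \mathrm{sign}(b_i - a_i)\left(\frac{(a_i-e_i)^2}{e_i} +
#'   \frac{(b_i-e_i)^2}{e_i}\right), \quad e_i = \frac{a_i+b_i}{2},}
#' where \code{a_i} sums the bin's contacts with the \code{window} bins
#' upstream and \code{b_i} with the \code{window} bins downstream (both
#' clipped at the chromosome ends). Sharp sign changes of the track mark TAD
#' boundaries. When \code{a_i = b_i} (including the all-zero case) the index
#' is defined as 0.
#'
#' @param M_chrom Square contact block of one chromosome (raw counts by
#'   convention; normalized values are accepted).
#' @param window Number of flanking bins on each side; must be at least 1
#'   and smaller than the block dimension.
#' @return Numeric vector of d_i, one per bin.
#' @export
directionality_index <- function(M_chrom, window) {
  X <- matrix(as.numeric(M_chrom), nrow(M_chrom))
  n <- nrow(X)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window >= n) stop("window must be smaller than the chromosome bin count")
  d <- numeric(n)
  for (i in seq_len(n)) {
    up <- seq(max(1L, i - window), i - 1L)
    dn <- seq(i + 1L, min(n, i + window))
    a <- if (i > 1L) sum(X[i, up]) else 0
    b <- if (i < n) sum(X[i, dn]) else 0
    e <- (a + b) / 2
    d[i] <- if (a == b || e == 0) 0 else
      sign(b - a) * ((a - e)^2 / e + (b - e)^2 / e)
  }
  d
}

#' Default directionality-index window in bins
#'
#' The conventional flanking extent is 2 Mb; this converts it to bins at the
#' analysis resolution.
#'
#' @param w_b Bin width in bp.
#' @param extent_bp Flanking extent in bp (default 2e6).
#' @export
di_window_bins <- function(w_b, extent_bp = 2e6) {
  max(1L, as.integer(round(extent_bp / w_b)))
}

.new_segmentation <- function(chrom, boundaries, n, method, parameters) {
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  domains <- data.frame(start_bin = starts, end_bin = ends,
                        label = paste0("domain_", seq_along(starts)))
  structure(list(chrom = chrom, boundaries = as.integer(boundaries),
                 domains = domains, n_bins = as.integer(n),
                 method = method, parameters = parameters),
            class = "Segmentation")
}

#' @export
print.Segmentation <- function(x, ...) {
  cat(sprintf("Segmentation (%s): %d bins, %d domain(s), boundaries: %s\n",
              x$method, x$n_bins, nrow(x$domains),
              if (length(x$boundaries)) paste(x$boundaries, collapse = ", ")
              else "none"))
  invisible(x)
}

#' TAD calling by window-signal local minima with rank-sum validation
#'
#' Three steps: (1) the boundary signal at bin i is the mean contact
#' frequency of the \code{window_size} bins ending at i with the
#' \code{window_size} bins starting at i+1 (windows clipped at chromosome
#' edges); (2) candidate boundaries are strict local minima of this signal
#' (the leftmost bin of a minimal plateau); (3) each candidate is kept only
#' if a one-sided Wilcoxon rank-sum test (normal approximation with
#' continuity correction) confirms that within-domain contact values on
#' either side of the candidate exceed the cross-boundary values, at
#' significance \code{p_threshold}.
#'
#' @param M_chrom Square contact block of one chromosome.
#' @param window_size Flanking window in bins; the caller's only tuning
#'   parameter.
#' @param p_threshold Rank-sum significance cutoff (default 0.05).
#' @param chrom Chromosome label recorded in the result.
#' @return A \code{Segmentation} whose domains tile the block.
#' @export
topdom_call <- function(M_chrom, window_size, p_threshold = 0.05,
                        chrom = NA_character_) {
  X <- matrix(as.numeric(M_chrom), nrow(M_chrom))
  n <- nrow(X)
  w <- as.integer(window_size)
  if (w < 1L) stop("window_size must be >= 1")
  params <- list(window_size = w, p_threshold = p_threshold)
  if (n < 2L * w) {
    warning("chromosome shorter than 2*window_size bins; empty segmentation")
    return(.new_segmentation(chrom, integer(), n, "topdom", params))
  }

  signal <- rep(NA_real_, n)
  for (i in seq_len(n - 1L)) {
    rows <- seq(max(1L, i - w + 1L), i)
    cols <- seq(i + 1L, min(n, i + w))
    signal[i] <- mean(X[rows, cols])
  }

  cand <- .plateau_minima(signal[seq_len(n - 1L)])
  keep <- logical(length(cand))
  for (ci in seq_along(cand)) {
    i <- cand[ci]
    rows <- seq(max(1L, i - w + 1L), i)
    cols <- seq(i + 1L, min(n, i + w))
    cross <- as.numeric(X[rows, cols, drop = FALSE])
    within <- c(.upper_tri_values(X, rows), .upper_tri_values(X, cols))
    if (length(within) < 1L || length(cross) < 1L) next
    p <- suppressWarnings(stats::wilcox.test(
      within, cross, alternative = "greater",
      exact = FALSE, correct = TRUE)$p.value)
    keep[ci] <- is.finite(p) && p < p_threshold
  }
  .new_segmentation(chrom, cand[keep], n, "topdom", params)
}

.upper_tri_values <- function(X, idx) {
  if (length(idx) < 2L) return(numeric())
  B <- X[idx, idx, drop = FALSE]
  B[upper.tri(B)]
}

# strict local minima; a minimal plateau contributes its leftmost index
.plateau_minima <- function(s) {
  n <- length(s)
  if (n < 3L) return(integer())
  out <- integer()
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    if (j <= n - 1L && s[i] < s[i - 1L] && s[i] < s[j + 1L])
      out <- c(out, i)
    i <- j + 1L
  }
  out
}

#' Maximum-likelihood block segmentation of a contact matrix
#'
#' Fits change points 0 = t_0 < t_1 < ... < t_K = n so that the diagonal
#' block of each segment has its own distribution parameter while all
#' remaining entries share one background parameter (shape
#' \code{"block_diagonal"}); with shape \code{"extended"} the off-diagonal
#' rectangle between each pair of consecutive segments also receives its own
#' parameter. For a fixed number of segments the exact likelihood optimum is
#' found by dynamic programming on precomputed block costs. Gaussian
#' likelihood (applied to a standardized matrix) is meant for normalized
#' matrices; Poisson or negative binomial for raw counts. Unless \code{K} is
#' forced, the returned number of segments maximizes a BIC-penalized
#' likelihood over 1..Kmax, preferring fewer segments on ties.
#'
#' @param M_chrom Square symmetric contact block.
#' @param Kmax Maximum number of segments (TADs) considered.
#' @param distribution \code{"gaussian"}, \code{"poisson"} or
#'   \code{"negbin"}. A negative-binomial block whose dispersion is not
#'   identifiable (variance <= mean) falls back to Poisson for that block.
#' @param shape \code{"block_diagonal"} or \code{"extended"}.
#' @param K Force this exact number of segments (optional).
#' @param chrom Chromosome label recorded in the result.
#' @return A \code{Segmentation}; \code{parameters$loglik} carries the
#'   objective for each K and \code{parameters$K} the selected K.
#' @export
hicseg_call <- function(M_chrom, Kmax,
                        distribution = c("gaussian", "poisson", "negbin"),
                        shape = c("block_diagonal", "extended"),
                        K = NULL, chrom = NA_character_) {
  distribution <- match.arg(distribution)
  shape <- match.arg(shape)
  X <- matrix(as.numeric(M_chrom), nrow(M_chrom))
  n <- nrow(X)
  Kmax <- as.integer(Kmax)
  if (Kmax < 1L) stop("Kmax must be >= 1")
  if (Kmax > n) stop("Kmax cannot exceed the number of bins")
  if (!is.null(K) && (K < 1L || K > Kmax)) stop("forced K must be in 1..Kmax")

  prep <- .seg_prepare(X, distribution)
  cost <- matrix(-Inf, n + 1L, n + 1L)   # cost[u+1, v+1] = gain of block (u, v]
  for (u in 0:(n - 1L)) for (v in (u + 1L):n)
    cost[u + 1L, v + 1L] <- .seg_block_gain(prep, u, v)

  if (shape == "block_diagonal") {
    dp <- .seg_dp_diag(cost, n, Kmax)
  } else {
    dp <- .seg_dp_extended(prep, cost, n, Kmax)
  }
  loglik <- prep$base + dp$obj          # full objective per K

  if (is.null(K)) {
    n_par <- switch(shape, block_diagonal = seq_len(Kmax) + 1L,
                    extended = 2L * seq_len(Kmax))
    crit <- loglik - 0.5 * n_par * log(n^2)
    K <- which.max(crit)                 # which.max keeps the smaller K on ties
  }
  breaks <- dp$breaks[[K]]
  boundaries <- breaks[-length(breaks)]  # interior change points
  .new_segmentation(chrom, boundaries, n, "hicseg",
                    list(Kmax = Kmax, K = K, distribution = distribution,
                         shape = shape, loglik = loglik))
}

# shared sufficient statistics + background parameter
.seg_prepare <- function(X, distribution) {
  n <- nrow(X)
  if (distribution == "gaussian") {
    s <- stats::sd(X)
    Z <- if (s > 0) (X - mean(X)) / s else X - mean(X)
    mu0 <- mean(Z)
  } else {
    Z <- X
    mu0 <- mean(Z)
  }
  # 2D prefix sums over the full square matrix
  P1 <- rbind(0, cbind(0, apply(apply(Z, 2, cumsum), 1, cumsum)))
  P2 <- rbind(0, cbind(0, apply(apply(Z^2, 2, cumsum), 1, cumsum)))
  base <- .seg_base_loglik(Z, mu0, distribution)
  list(Z = Z, n = n, mu0 = mu0, distribution = distribution,
       P1 = t(P1), P2 = t(P2), base = base)
}

.rect_sum <- function(P, r1, r2, c1, c2) {  # rows (r1, r2], cols (c1, c2], 0-based
  P[r2 + 1L, c2 + 1L] - P[r1 + 1L, c2 + 1L] -
    P[r2 + 1L, c1 + 1L] + P[r1 + 1L, c1 + 1L]
}

# log-likelihood of the whole matrix under the background parameter alone
.seg_base_loglik <- function(Z, mu0, distribution) {
  if (distribution == "gaussian") return(-0.5 * sum((Z - mu0)^2))
  if (distribution == "poisson")
    return(sum(ifelse(Z > 0, Z * log(mu0), 0)) - length(Z) * mu0)
  sum(.nb_loglik(as.numeric(Z), mean(Z), stats::var(as.numeric(Z))))
}

# gain of giving the cells of rectangle rows (r1,r2] x cols (c1,c2] their own
# parameter instead of the background one
.seg_rect_gain <- function(prep, r1, r2, c1, c2) {
  A <- (r2 - r1) * (c2 - c1)
  S <- .rect_sum(prep$P1, r1, r2, c1, c2)
  if (prep$distribution == "gaussian") {
    Q <- .rect_sum(prep$P2, r1, r2, c1, c2)
    rss_own <- Q - S^2 / A
    rss_bg <- Q - 2 * prep$mu0 * S + A * prep$mu0^2
    return(0.5 * (rss_bg - rss_own))
  }
  if (prep$distribution == "poisson") {
    mu <- S / A
    own <- if (S > 0) S * log(mu) - S else 0
    bg <- (if (S > 0) S * log(prep$mu0) else 0) - A * prep$mu0
    return(own - bg)
  }
  # negative binomial: needs the raw cells (sufficient stats do not reduce)
  x <- as.numeric(prep$Z[(r1 + 1L):r2, (c1 + 1L):c2])
  own <- sum(.nb_loglik(x, mean(x), stats::var(x)))
  bg <- sum(.nb_loglik(x, mean(prep$Z), stats::var(as.numeric(prep$Z))))
  own - bg
}

.seg_block_gain <- function(prep, u, v) .seg_rect_gain(prep, u, v, u, v)

# method-of-moments NB log-likelihood with Poisson fallback on
# under-dispersed or degenerate blocks
.nb_loglik <- function(x, mu, v) {
  if (length(x) < 2L || !is.finite(v) || v <= mu || mu <= 0)
    return(ifelse(x > 0, x * log(pmax(mu, 1e-300)), 0) - mu -
             lgamma(x + 1))
  size <- mu^2 / (v - mu)
  stats::dnbinom(round(x), size = size, mu = mu, log = TRUE)
}

.seg_dp_diag <- function(cost, n, Kmax) {
  D <- matrix(-Inf, Kmax, n)            # D[k, v] = best gain, first v bins, k segs
  back <- matrix(NA_integer_, Kmax, n)
  D[1, ] <- cost[1, 1 + seq_len(n)]
  if (Kmax > 1L) for (k in 2:Kmax) for (v in k:n) {
    u <- (k - 1L):(v - 1L)
    val <- D[k - 1L, u] + cost[u + 1L, v + 1L]
    best <- which.max(val)
    D[k, v] <- val[best]
    back[k, v] <- u[best]
  }
  breaks <- vector("list", Kmax)
  for (k in seq_len(Kmax)) {
    if (!is.finite(D[k, n])) next
    b <- n
    kk <- k; v <- n
    while (kk > 1L) {
      v <- back[kk, v]
      b <- c(v, b)
      kk <- kk - 1L
    }
    breaks[[k]] <- b
  }
  list(obj = D[, n], breaks = breaks)
}

# second-order DP: the transition cost depends on the previous segment too,
# because the off-diagonal rectangle between consecutive segments gets its
# own parameter (counted for both symmetric copies)
.seg_dp_extended <- function(prep, cost, n, Kmax) {
  rect <- function(w, u, v) 2 * .seg_rect_gain(prep, w, u, u, v)
  # D[[k]][u+1, v] = best gain when segment k is (u, v]
  D <- vector("list", Kmax)
  B <- vector("list", Kmax)
  D[[1]] <- matrix(-Inf, n + 1L, n)
  for (v in seq_len(n)) D[[1]][1, v] <- cost[1, v + 1L]
  if (Kmax > 1L) for (k in 2:Kmax) {
    D[[k]] <- matrix(-Inf, n + 1L, n)
    B[[k]] <- matrix(NA_integer_, n + 1L, n)
    for (u in (k - 1L):(n - 1L)) for (v in (u + 1L):n) {
      w <- (k - 2L):(u - 1L)
      val <- D[[k - 1L]][w + 1L, u] +
        vapply(w, function(ww) rect(ww, u, v), numeric(1))
      best <- which.max(val)
      if (is.finite(val[best])) {
        D[[k]][u + 1L, v] <- val[best] + cost[u + 1L, v + 1L]
        B[[k]][u + 1L, v] <- w[best]
      }
    }
  }
  obj <- numeric(Kmax)
  breaks <- vector("list", Kmax)
  obj[1] <- D[[1]][1, n]
  breaks[[1]] <- n
  if (Kmax > 1L) for (k in 2:Kmax) {
    col <- D[[k]][, n]
    u <- which.max(col) - 1L
    obj[k] <- col[u + 1L]
    if (!is.finite(obj[k])) next
    b <- c(u, n)
    kk <- k; vv <- n; uu <- u
    while (kk > 2L) {
      ww <- B[[kk]][uu + 1L, vv]
      b <- c(ww, b)
      vv <- uu; uu <- ww
      kk <- kk - 1L
    }
    breaks[[k]] <- b[b > 0L]
  }
  list(obj = obj, breaks = breaks)
}

#' Objective of an arbitrary segmentation
#'
#' Evaluates, for a given set of change points, the same log-likelihood
#' objective that [hicseg_call()] maximizes. Useful for comparing candidate
#' segmentations or validating optimality by enumeration at small n.
#'
#' @param M_chrom Square symmetric contact block.
#' @param breaks Increasing change points ending at \code{nrow(M_chrom)}
#'   (each value is the last bin of a segment).
#' @inheritParams hicseg_call
#' @return Scalar log-likelihood.
#' @export
segment_objective <- function(M_chrom, breaks,
                              distribution = c("gaussian", "poisson",
                                               "negbin"),
                              shape = c("block_diagonal", "extended")) {
  distribution <- match.arg(distribution)
  shape <- match.arg(shape)
  X <- matrix(as.numeric(M_chrom), nrow(M_chrom))
  n <- nrow(X)
  breaks <- as.integer(breaks)
  if (length(breaks) < 1L || breaks[length(breaks)] != n ||
      is.unsorted(breaks, strictly = TRUE) || any(breaks < 1L))
    stop("breaks must increase strictly and end at nrow(M_chrom)")
  prep <- .seg_prepare(X, distribution)
  starts <- c(0L, breaks[-length(breaks)])
  obj <- prep$base +
    sum(mapply(function(u, v) .seg_block_gain(prep, u, v), starts, breaks))
  if (shape == "extended" && length(breaks) > 1L) {
    for (k in 2:length(breaks))
      obj <- obj + 2 * .seg_rect_gain(prep, starts[k - 1L], starts[k],
                                      starts[k], breaks[k])
  }
  obj
}
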