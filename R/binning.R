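#' Build the genome bin table at a given resolution
#'
#' Tiles every chromosome with bins of nominal width \code{w_b}. Because
#' contacts are diagnosed at restriction-fragment level, nominal breakpoints
#' at multiples of \code{w_b} are snapped to the nearest restriction cut
#' position when the chromosome has any; the stored bins are disjoint and
#' contiguous, and the final bin absorbs a trailing remainder shorter than
#' \code{w_b / 2}.
#'
#' @param map A \code{RestrictionMap}.
#' @param w_b Bin width (resolution) in bp; must be > 0. There is no
#'   default — resolution is an explicit analysis choice.
#' @return A \code{BinTable}: data.frame with \code{bin} (1-based global
#'   index), \code{chrom}, \code{start}, \code{end} (0-based half-open),
#'   with attribute \code{w_b}.
#' @export
make_bins <- function(map, w_b) {
  stopifnot(inherits(map, "RestrictionMap"))
  w_b <- as.numeric(w_b)
  if (is.na(w_b) || w_b <= 0) stop("w_b must be > 0")
  rows <- lapply(names(map$chroms), function(nm) {
    ch <- map$chroms[[nm]]
    L <- ch$length
    nominal <- if (w_b <= L - 1) seq(w_b, L - 1, by = w_b) else numeric()
    nominal <- nominal[nominal < L]
    if (length(ch$cuts) > 0L && length(nominal) > 0L) {
      breaks <- vapply(nominal, function(b)
        ch$cuts[which.min(abs(ch$cuts - b))], numeric(1))
    } else breaks <- nominal
    breaks <- sort(unique(breaks))
    breaks <- breaks[breaks > 0 & breaks < L]
    if (length(breaks) > 0L && (L - breaks[length(breaks)]) < w_b / 2)
      breaks <- breaks[-length(breaks)]
    starts <- c(0, breaks)
    ends <- c(breaks, L)
    data.frame(chrom = nm, start = as.integer(starts), end = as.integer(ends))
  })
  out <- do.call(rbind, rows)
  out <- cbind(bin = seq_len(nrow(out)), out)
  attr(out, "w_b") <- w_b
  class(out) <- c("BinTable", "data.frame")
  out
}

#' Map genomic positions to bin indices
#'
#' @param bins A \code{BinTable}.
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s).
#' @return Global bin indices; error if a position falls beyond its
#'   chromosome's bins.
#' @export
assign_bin <- function(bins, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.numeric(pos), n)
  out <- integer(n)
  for (nm in unique(chrom)) {
    sub <- bins[bins$chrom == nm, ]
    if (nrow(sub) == 0L) stop("chromosome not in bin table: ", nm)
    sel <- which(chrom == nm)
    if (any(pos[sel] < sub$start[1] | pos[sel] >= sub$end[nrow(sub)]))
      stop("position beyond bins of chromosome ", nm)
    out[sel] <- sub$bin[findInterval(pos[sel], sub$start)]
  }
  out
}

#' Count filtered pairs into the raw contact matrix
#'
#' Each mate is assigned to the bin containing its 5' base. A pair between
#' bins i != j contributes symmetrically to \code{M[i, j]} and
#' \code{M[j, i]}; a within-bin pair increments the diagonal once, so the
#' total number of stored contacts (upper triangle plus diagonal) equals the
#' number of pairs. Inter-chromosomal pairs enter the global matrix;
#' per-chromosome analyses slice diagonal blocks with [chrom_block()].
#'
#' @param pairs Annotated, filtered pairs.
#' @param bins A \code{BinTable}.
#' @return A raw \code{ContactMatrix}.
#' @export
count_contacts <- function(pairs, bins) {
  n_b <- nrow(bins)
  M <- matrix(0L, n_b, n_b)
  if (nrow(pairs) > 0L) {
    fp1 <- if ("fp1" %in% names(pairs)) pairs$fp1 else
      .five_prime(pairs$pos1, pairs$strand1, pairs$width1)
    fp2 <- if ("fp2" %in% names(pairs)) pairs$fp2 else
      .five_prime(pairs$pos2, pairs$strand2, pairs$width2)
    b1 <- assign_bin(bins, pairs$chrom1, fp1)
    b2 <- assign_bin(bins, pairs$chrom2, fp2)
    for (k in seq_along(b1)) {
      i <- b1[k]; j <- b2[k]
      M[i, j] <- M[i, j] + 1L
      if (i != j) M[j, i] <- M[j, i] + 1L
    }
  }
  contact_matrix(M, bins, normalized = FALSE)
}

#' Construct a ContactMatrix from a matrix and bin table
#'
#' @param values Symmetric numeric matrix, one row/column per bin.
#' @param bins Matching \code{BinTable}.
#' @param normalized Logical; raw counts or normalized strengths.
#' @param biases Optional per-bin biases (normalized matrices only).
#' @export
contact_matrix <- function(values, bins, normalized = FALSE, biases = NULL) {
  stopifnot(nrow(values) == ncol(values), nrow(values) == nrow(bins))
  if (!isTRUE(all.equal(values, t(values), check.attributes = FALSE)))
    stop("contact matrix must be symmetric")
  structure(list(matrix = values, bins = bins,
                 normalized = isTRUE(normalized), biases = biases),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d bins, %s, total %s\n", nrow(x$matrix),
              if (x$normalized) "normalized" else "raw counts",
              format(sum(x$matrix[upper.tri(x$matrix, diag = TRUE)],
                         na.rm = TRUE))))
  invisible(x)
}

#' Extract the diagonal block of one chromosome
#'
#' @param cm A \code{ContactMatrix}.
#' @param chrom Chromosome name.
#' @return list with \code{matrix} (square block) and \code{bins} (the
#'   chromosome's rows of the bin table).
#' @export
chrom_block <- function(cm, chrom) {
  idx <- cm$bins$bin[cm$bins$chrom == chrom]
  if (length(idx) == 0L) stop("chromosome not in bin table: ", chrom)
  list(matrix = cm$matrix[idx, idx, drop = FALSE],
       bins = cm$bins[cm$bins$chrom == chrom, , drop = FALSE])
}

#' Restrict a contact matrix to a chromosome subset
#'
#' @param cm A \code{ContactMatrix}.
#' @param chromosomes Character vector of chromosome names to keep.
#' @export
subset_contacts <- function(cm, chromosomes) {
  known <- unique(cm$bins$chrom)
  bad <- setdiff(chromosomes, known)
  if (length(bad))
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(known, collapse = ", "))
  keep <- cm$bins$chrom %in% chromosomes
  idx <- cm$bins$bin[keep]
  bins <- cm$bins[keep, , drop = FALSE]
  bins$bin <- seq_len(nrow(bins))
  attr(bins, "w_b") <- attr(cm$bins, "w_b")
  class(bins) <- class(cm$bins)
  contact_matrix(cm$matrix[idx, idx, drop = FALSE], bins,
                 normalized = cm$normalized,
                 biases = if (!is.null(cm$biases)) cm$biases[idx])
}

#' Write bin coordinates as BED
#'
#' @param bins A \code{BinTable}.
#' @param path Output file.
#' @export
write_bins_bed <- function(bins, path) {
  df <- data.frame(bins$chrom, bins$start, bins$end,
                   paste0("bin_", bins$bin))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bin BED file back into a BinTable
#'
#' @param path BED file written by [write_bins_bed()].
#' @param w_b Optional nominal bin width to attach.
#' @export
read_bins_bed <- function(path, w_b = NULL) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(bin = seq_len(nrow(df)), chrom = df[[1]],
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]))
  attr(out, "w_b") <- w_b
  class(out) <- c("BinTable", "data.frame")
  out
}

#' Export a contact matrix as TSV
#'
#' Long format stores non-zero upper-triangle entries as
#' \code{bin_i <TAB> bin_j <TAB> value} with \code{i <= j}; dense format
#' stores the full square matrix. Integer raw counts round-trip bit-exactly.
#'
#' @param cm A \code{ContactMatrix}.
#' @param path Output file.
#' @param format \code{"long"} (default) or \code{"dense"}.
#' @export
write_contacts <- function(cm, path, format = c("long", "dense")) {
  format <- match.arg(format)
  M <- cm$matrix
  if (format == "dense") {
    utils::write.table(M, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    ut <- which(upper.tri(M, diag = TRUE) & (M != 0 | is.na(M)),
                arr.ind = TRUE)
    df <- data.frame(bin_i = ut[, 1], bin_j = ut[, 2],
                     value = M[ut])
    df <- df[order(df$bin_i, df$bin_j), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read a contact matrix TSV written by [write_contacts()]
#'
#' @param path Matrix file (long or dense; long is detected by its header).
#' @param bins The matching \code{BinTable}.
#' @param normalized Logical flag to set on the result.
#' @export
read_contacts <- function(path, bins, normalized = FALSE) {
  first <- readLines(path, n = 1L)
  n_b <- nrow(bins)
  if (grepl("^bin_i\t", first)) {
    df <- utils::read.table(path, sep = "\t", header = TRUE)
    M <- matrix(0, n_b, n_b)
    M[cbind(df$bin_i, df$bin_j)] <- df$value
    M[cbind(df$bin_j, df$bin_i)] <- df$value
  } else {
    M <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(M) <- NULL
    if (nrow(M) != n_b) stop("dense matrix size does not match bin table")
  }
  if (!normalized && !anyNA(M)) storage.mode(M) <- "integer"
  contact_matrix(M, bins, normalized = normalized)
}
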