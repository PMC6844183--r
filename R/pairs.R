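#' Read aligned Hi-C pairs from a SAM/BAM file
#'
#' Loads primary alignments of properly resolvable read pairs (both mates
#' mapped, secondary/supplementary records dropped) and returns one row per
#' pair. SAM input is converted to BAM on the fly. Positions are converted to
#' 0-based; the per-mate duplicate bit (0x400) is OR-combined into a single
#' pair-level flag, matching the convention that duplicates are only honored
#' when pre-marked upstream.
#'
#' @param path SAM or BAM file.
#' @return data.frame with columns \code{chrom1, pos1, strand1, width1,
#'   mapq1, chrom2, pos2, strand2, width2, mapq2, duplicate}. Widths are
#'   reference-space alignment widths from the CIGAR.
#' @export
read_pairs <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "mapq"),
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                  hasUnmappedMate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(rec$qname)
  if (n == 0L) return(.empty_pairs())
  width <- .cigar_ref_width(rec$cigar)
  df <- data.frame(qname = rec$qname, flag = rec$flag,
                   chrom = as.character(rec$rname),
                   strand = as.character(rec$strand),
                   pos = rec$pos - 1L, width = width,
                   mapq = rec$mapq, stringsAsFactors = FALSE)
  df$first <- bitwAnd(df$flag, 64L) > 0L
  df <- df[order(df$qname, !df$first), ]
  cnt <- table(df$qname)
  keep <- names(cnt)[cnt == 2L]
  df <- df[df$qname %in% keep, ]
  if (nrow(df) == 0L) return(.empty_pairs())
  i1 <- seq(1L, nrow(df), by = 2L)
  i2 <- i1 + 1L
  data.frame(chrom1 = df$chrom[i1], pos1 = df$pos[i1],
             strand1 = df$strand[i1], width1 = df$width[i1],
             mapq1 = df$mapq[i1],
             chrom2 = df$chrom[i2], pos2 = df$pos[i2],
             strand2 = df$strand[i2], width2 = df$width[i2],
             mapq2 = df$mapq[i2],
             duplicate = bitwAnd(df$flag[i1], 1024L) > 0L |
                         bitwAnd(df$flag[i2], 1024L) > 0L,
             stringsAsFactors = FALSE)
}

.empty_pairs <- function() {
  data.frame(chrom1 = character(), pos1 = integer(), strand1 = character(),
             width1 = integer(), mapq1 = integer(), chrom2 = character(),
             pos2 = integer(), strand2 = character(), width2 = integer(),
             mapq2 = integer(), duplicate = logical(),
             stringsAsFactors = FALSE)
}

# reference-space width of a CIGAR string (M/=/X/D/N consume reference)
.cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

.five_prime <- function(pos, strand, width) {
  ifelse(strand == "+", pos, pos + width - 1L)
}

#' Annotate read pairs with fragment, orientation and length estimates
#'
#' Derives, per pair: the restriction fragment of each mate (assigned by the
#' mate's 5' base), the orientation class of intra-chromosomal pairs
#' (\code{inward} when the leftmost mate is on + and the rightmost on -,
#' \code{outward} for the converse, \code{same} for equal strands), the
#' insert length (outermost span in bp), the estimated sequencing-fragment
#' length (sum of each mate's distance from its 5' base to the nearest
#' cut position in its reading direction) and the artifact category.
#'
#' Pairs whose mates sit on the same restriction fragment are artifacts:
#' outward orientation marks a circularized self-circle fragment, inward an
#' un-ligated dangling end; pairs on different fragments are valid products.
#'
#' @param pairs data.frame as returned by [read_pairs()].
#' @param map A \code{RestrictionMap}.
#' @return The input with added columns \code{fp1, fp2} (5' bases),
#'   \code{frag1, frag2}, \code{orientation}, \code{insert}, \code{fraglen},
#'   \code{category}.
#' @export
annotate_pairs <- function(pairs, map) {
  stopifnot(inherits(map, "RestrictionMap"))
  n <- nrow(pairs)
  fp1 <- .five_prime(pairs$pos1, pairs$strand1, pairs$width1)
  fp2 <- .five_prime(pairs$pos2, pairs$strand2, pairs$width2)
  frag1 <- if (n) assign_fragment(map, pairs$chrom1, fp1, pairs$strand1) else integer()
  frag2 <- if (n) assign_fragment(map, pairs$chrom2, fp2, pairs$strand2) else integer()

  intra <- pairs$chrom1 == pairs$chrom2
  # leftmost mate by leftmost aligned base
  left1 <- pairs$pos1 <= pairs$pos2
  s_left <- ifelse(left1, pairs$strand1, pairs$strand2)
  s_right <- ifelse(left1, pairs$strand2, pairs$strand1)
  orientation <- rep(NA_character_, n)
  orientation[intra & s_left == "+" & s_right == "-"] <- "inward"
  orientation[intra & s_left == "-" & s_right == "+"] <- "outward"
  orientation[intra & s_left == s_right] <- "same"

  insert <- ifelse(intra,
                   pmax(pairs$pos1 + pairs$width1, pairs$pos2 + pairs$width2) -
                     pmin(pairs$pos1, pairs$pos2),
                   NA_integer_)

  fraglen <- .mate_cut_distance(map, pairs$chrom1, fp1, pairs$strand1, frag1) +
             .mate_cut_distance(map, pairs$chrom2, fp2, pairs$strand2, frag2)

  category <- rep("valid", n)
  same_frag <- intra & frag1 == frag2
  category[same_frag & orientation == "outward"] <- "self_circle"
  category[same_frag & orientation == "inward"] <- "dangling_end"
  category[same_frag & orientation == "same"] <- "same_fragment_other"

  out <- pairs
  out$fp1 <- fp1; out$fp2 <- fp2
  out$frag1 <- frag1; out$frag2 <- frag2
  out$orientation <- orientation
  out$insert <- as.integer(insert)
  out$fraglen <- as.integer(fraglen)
  out$category <- category
  out
}

# distance from a mate's 5' base to the cut it reads toward: the end of its
# fragment for + mates, the start for - mates
.mate_cut_distance <- function(map, chrom, p5, strand, frag) {
  n <- length(p5)
  d <- integer(n)
  for (nm in unique(chrom)) {
    fr <- map$chroms[[nm]]$fragments
    sel <- which(chrom == nm)
    plus <- strand[sel] == "+"
    d[sel] <- ifelse(plus, fr$end[frag[sel]] - p5[sel],
                     p5[sel] - fr$start[frag[sel]])
  }
  d
}

#' Filter annotated Hi-C pairs and account for every removal
#'
#' Applies the artifact filters in a fixed priority so that each pair lands
#' in exactly one accounting category: pre-marked duplicates, then low
#' mapping quality, then same-fragment artifacts (self-circle, dangling-end,
#' same-strand), then the orientation-distance thresholds, then over-long
#' estimated fragments. Inward pairs closer than \code{min_inward} are
#' counted with the dangling ends and outward pairs closer than
#' \code{min_outward} with the self-circles, since those thresholds exist to
#' catch the respective artifact class when it leaks across a cut site.
#'
#' @param pairs Annotated pairs ([annotate_pairs()]), or raw pairs with
#'   \code{map} supplied.
#' @param map Optional \code{RestrictionMap}, used to annotate raw pairs.
#' @param min_inward,min_outward,max_frag_length Distance thresholds in bp;
#'   \code{NULL} disables the corresponding filter.
#' @param min_mapq Minimum mapping quality of both mates (default 10);
#'   \code{NULL} disables.
#' @param drop_duplicates Honor pre-set duplicate flags (default TRUE).
#' @return list with \code{pairs} (retained rows, all category
#'   \code{"valid"}) and \code{summary}, a one-row \code{FilterSummary}
#'   data.frame whose removal categories are disjoint and sum with
#'   \code{retained_valid} to \code{total}.
#' @export
filter_pairs <- function(pairs, map = NULL, min_inward = NULL,
                         min_outward = NULL, max_frag_length = NULL,
                         min_mapq = 10, drop_duplicates = TRUE) {
  for (thr in list(min_inward, min_outward, max_frag_length, min_mapq))
    if (!is.null(thr) && thr < 0) stop("thresholds must be >= 0 or NULL")
  if (!"category" %in% names(pairs)) {
    if (is.null(map)) stop("raw pairs need a RestrictionMap to annotate")
    pairs <- annotate_pairs(pairs, map)
  }
  n <- nrow(pairs)
  state <- rep("retained_valid", n)
  todo <- rep(TRUE, n)

  mark <- function(cond, label) {
    hit <- todo & cond & !is.na(cond)
    state[hit] <<- label
    todo[hit] <<- FALSE
  }
  if (isTRUE(drop_duplicates)) mark(pairs$duplicate, "removed_duplicate")
  if (!is.null(min_mapq))
    mark(pairs$mapq1 < min_mapq | pairs$mapq2 < min_mapq, "removed_low_mapq")
  mark(pairs$category == "self_circle", "removed_self_circle")
  mark(pairs$category == "dangling_end", "removed_dangling_end")
  mark(pairs$category == "same_fragment_other",
       "removed_same_fragment_same_strand")
  if (!is.null(min_inward))
    mark(pairs$orientation == "inward" & pairs$insert < min_inward,
         "removed_dangling_end")
  if (!is.null(min_outward))
    mark(pairs$orientation == "outward" & pairs$insert < min_outward,
         "removed_self_circle")
  if (!is.null(max_frag_length))
    mark(pairs$fraglen > max_frag_length, "removed_too_long")

  cats <- c("retained_valid", "removed_duplicate", "removed_low_mapq",
            "removed_self_circle", "removed_dangling_end",
            "removed_same_fragment_same_strand", "removed_too_long")
  counts <- vapply(cats, function(cc) sum(state == cc), integer(1))
  summary <- data.frame(total = n, t(counts))
  class(summary) <- c("FilterSummary", "data.frame")
  list(pairs = pairs[state == "retained_valid", , drop = FALSE],
       summary = summary)
}

#' Diagnostic insert-length distributions
#'
#' Computes the two read-pair diagnostics used to pick filtering thresholds:
#' a histogram of insert lengths of intra-chromosomal pairs on log2-spaced
#' bins (bin k covers inserts in [2^k, 2^(k+1)); a dangling-end spike at
#' ~256 bp lands in bin 8), and the same counts split by orientation class.
#'
#' @param pairs Annotated pairs.
#' @return list with \code{insert_hist} (data.frame \code{log2_bin},
#'   \code{count}) and \code{orientation_curves} (data.frame \code{log2_bin},
#'   \code{inward}, \code{outward}, \code{same}).
#' @export
diagnostic_distributions <- function(pairs) {
  intra <- pairs[!is.na(pairs$insert), , drop = FALSE]
  if (nrow(intra) == 0L) {
    return(list(
      insert_hist = data.frame(log2_bin = integer(), count = integer()),
      orientation_curves = data.frame(log2_bin = integer(),
                                      inward = integer(), outward = integer(),
                                      same = integer())))
  }
  b <- floor(log2(pmax(intra$insert, 1L)))
  bins <- seq(min(b), max(b))
  hist <- data.frame(log2_bin = bins,
                     count = vapply(bins, function(k) sum(b == k), integer(1)))
  curves <- data.frame(
    log2_bin = bins,
    inward = vapply(bins, function(k)
      sum(b == k & intra$orientation == "inward"), integer(1)),
    outward = vapply(bins, function(k)
      sum(b == k & intra$orientation == "outward"), integer(1)),
    same = vapply(bins, function(k)
      sum(b == k & intra$orientation == "same"), integer(1)))
  list(insert_hist = hist, orientation_curves = curves)
}
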