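#' Per-bin signal track
#'
#' @param bins A \code{BinTable}.
#' @param values One value (or NA) per bin.
#' @param label Track label.
#' @param kind One of \code{"eigenvector"}, \code{"directionality"},
#'   \code{"coverage"}, \code{"occupancy"}, \code{"other"}.
#' @export
bin_track <- function(bins, values, label = "track", kind = "other") {
  kind <- match.arg(kind, c("eigenvector", "directionality", "coverage",
                            "occupancy", "other"))
  stopifnot(length(values) == nrow(bins))
  structure(list(bins = bins, values = as.numeric(values),
                 label = label, kind = kind),
            class = "BinTrack")
}

#' @export
print.BinTrack <- function(x, ...) {
  cat(sprintf("BinTrack '%s' (%s): %d bins, %d NA\n", x$label, x$kind,
              length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Raw read coverage on the Hi-C bin grid
#'
#' Counts aligned reads of a ChIP-seq (or any) SAM/BAM file into the Hi-C
#' bins: each primary mapped read is assigned to the bin containing its 5'
#' base. Reads on chromosomes absent from the bin table are dropped and
#' counted. Secondary, supplementary and unmapped records are excluded.
#'
#' @param path SAM or BAM file.
#' @param bins A \code{BinTable} (non-empty).
#' @param label Track label.
#' @return A coverage \code{BinTrack} of integer counts, with attributes
#'   \code{n_assigned}, \code{n_dropped} and \code{n_total}.
#' @export
bin_coverage <- function(path, bins, label = "coverage") {
  if (nrow(bins) == 0L) stop("empty bin table")
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "strand", "pos", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  chrom <- as.character(rec$rname)
  n_total <- length(chrom)
  known <- chrom %in% unique(bins$chrom)
  n_dropped <- sum(!known)
  if (n_dropped > 0L)
    message(n_dropped, " read(s) on chromosomes absent from the bin table ",
            "were dropped")
  counts <- integer(nrow(bins))
  if (any(known)) {
    w <- .cigar_ref_width(rec$cigar[known])
    p5 <- .five_prime(rec$pos[known] - 1L, as.character(rec$strand)[known], w)
    b <- assign_bin(bins, chrom[known], p5)
    tab <- tabulate(b, nbins = nrow(bins))
    counts <- as.integer(tab)
  }
  tr <- bin_track(bins, counts, label = label, kind = "coverage")
  attr(tr, "n_assigned") <- sum(known)
  attr(tr, "n_dropped") <- n_dropped
  attr(tr, "n_total") <- n_total
  tr
}

#' Normalize a coverage track
#'
#' \code{"rpm"} rescales counts to reads per million mapped
#' (\code{count * 1e6 / total mapped reads in the file}); \code{"ratio"}
#' divides the ChIP counts by matched input-DNA counts bin by bin, with
#' zero-input bins yielding NA.
#'
#' @param counts Raw-count coverage \code{BinTrack} from [bin_coverage()].
#' @param method \code{"rpm"} or \code{"ratio"}.
#' @param input_counts Input-DNA \code{BinTrack} on the same bin table
#'   (required for \code{"ratio"}).
#' @return Normalized \code{BinTrack}.
#' @export
normalize_coverage <- function(counts, method = c("rpm", "ratio"),
                               input_counts = NULL) {
  method <- match.arg(method)
  if (method == "rpm") {
    total <- attr(counts, "n_total")
    if (is.null(total)) total <- sum(counts$values)
    vals <- counts$values * 1e6 / total
  } else {
    if (is.null(input_counts)) stop("ratio normalization needs input_counts")
    if (!identical(dim(counts$bins), dim(input_counts$bins)) ||
        !identical(counts$bins$start, input_counts$bins$start) ||
        !identical(counts$bins$chrom, input_counts$bins$chrom))
      stop("ChIP and input tracks are on different bin tables")
    vals <- ifelse(input_counts$values > 0,
                   counts$values / input_counts$values, NA_real_)
  }
  bin_track(counts$bins, vals, label = counts$label, kind = "coverage")
}

#' Convert BED intervals to a per-bin occupancy track
#'
#' @param path BED file (chrom, start, end, optional name, optional score),
#'   or a data.frame with those columns.
#' @param bins A \code{BinTable}.
#' @param score_mode \code{"binary"} (1 iff the bin intersects any interval
#'   by at least 1 bp) or \code{"max_score"} (maximum BED score among
#'   intersecting intervals, NA if none).
#' @param label Track label.
#' @return An occupancy \code{BinTrack}. Intervals on unknown chromosomes
#'   are dropped with a message.
#' @export
bed_to_bin_track <- function(path, bins, score_mode = c("binary", "max_score"),
                             label = "occupancy") {
  score_mode <- match.arg(score_mode)
  if (is.character(path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
    if (length(lines) == 0L) {
      iv <- data.frame(chrom = character(), start = integer(),
                       end = integer(), score = numeric())
    } else {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      nfield <- lengths(parts)
      bad <- which(nfield < 3L)
      if (length(bad))
        stop("malformed BED line ", bad[1], ": fewer than 3 fields")
      iv <- data.frame(
        chrom = vapply(parts, `[`, "", 1L),
        start = as.integer(vapply(parts, `[`, "", 2L)),
        end = as.integer(vapply(parts, `[`, "", 3L)),
        score = vapply(parts, function(p)
          if (length(p) >= 5L) suppressWarnings(as.numeric(p[5L]))
          else NA_real_, numeric(1)))
      if (anyNA(iv$start) || anyNA(iv$end))
        stop("malformed BED line ",
             which(is.na(iv$start) | is.na(iv$end))[1],
             ": non-numeric coordinates")
    }
  } else {
    iv <- path
    if (is.null(iv$score)) iv$score <- NA_real_
  }
  known <- iv$chrom %in% unique(bins$chrom)
  if (any(!known))
    message(sum(!known), " interval(s) on unknown chromosomes dropped")
  iv <- iv[known, , drop = FALSE]

  if (nrow(iv)) {
    gr_bins <- GenomicRanges::GRanges(
      bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
    gr_iv <- GenomicRanges::GRanges(
      iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
    hits <- GenomicRanges::findOverlaps(gr_bins, gr_iv)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
  } else qh <- sh <- integer()

  if (score_mode == "binary") {
    vals <- numeric(nrow(bins))
    vals[unique(qh)] <- 1
  } else {
    vals <- rep(NA_real_, nrow(bins))
    if (length(qh)) {
      agg <- tapply(iv$score[sh], qh, function(s)
        if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE))
      vals[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  bin_track(bins, vals, label = label, kind = "occupancy")
}

#' Write one or more BinTracks as a combined TSV table
#'
#' Columns: \code{chrom}, \code{start}, \code{end}, then one labeled column
#' per track.
#'
#' @param tracks A \code{BinTrack} or list of them (same bin table).
#' @param path Output file.
#' @export
write_tracks_tsv <- function(tracks, path) {
  if (inherits(tracks, "BinTrack")) tracks <- list(tracks)
  bins <- tracks[[1]]$bins
  df <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end)
  for (tr in tracks) df[[tr$label]] <- tr$values
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a combined track table written by [write_tracks_tsv()]
#'
#' @param path TSV file.
#' @param bins Matching \code{BinTable}.
#' @return Named list of \code{BinTrack}s.
#' @export
read_tracks_tsv <- function(path, bins) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  labs <- setdiff(names(df), c("chrom", "start", "end"))
  out <- lapply(labs, function(l) bin_track(bins, df[[l]], label = l))
  names(out) <- labs
  out
}
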