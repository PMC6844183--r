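#' Digest a genome into indexed restriction fragments
#'
#' Scans each chromosome for occurrences of the restriction-enzyme recognition
#' site and derives the fragment index used by all downstream steps. A cut is
#' placed in the middle of the recognition site, offset so that the sticky-end
#' overhang is shared symmetrically: for a site match starting at 0-based
#' position \code{p}, the cut offset is
#' \code{p + (nchar(cut_site) - overhang) / 2}. Fragment k ends at
#' (cut + overhang) and fragment k+1 starts at the cut, so consecutive
#' fragments overlap by exactly \code{overhang} bp (HindIII, \code{AAGCTT}
#' with a 4 bp overhang, is the canonical example).
#'
#' All coordinates are 0-based half-open. Site matching is case-insensitive
#' and overlapping occurrences are all honored; \code{N} bases never match.
#'
#' @param genome A named \code{character} vector of chromosome sequences, a
#'   \code{Biostrings::DNAStringSet}, or the path to a FASTA file.
#' @param cut_site Recognition site, uppercase/lowercase ACGT string.
#' @param overhang Overhang length in bp; \code{0 <= overhang <=
#'   nchar(cut_site)} and \code{nchar(cut_site) - overhang} must be even.
#' @return A \code{RestrictionMap}: a list with elements \code{cut_site},
#'   \code{overhang} and \code{chroms}, the latter a named list with, per
#'   chromosome, \code{length}, integer \code{cuts} (cut offsets) and a
#'   \code{fragments} data.frame (\code{start}, \code{end}).
#' @examples
#' map <- digest_genome(c(chrA = paste(rep("ACGT", 30), collapse = "")),
#'                      cut_site = "CGTA", overhang = 2)
#' restriction_fragments(map)
#' @export
digest_genome <- function(genome, cut_site, overhang) {
  cut_site <- toupper(as.character(cut_site))
  if (!nzchar(cut_site) || grepl("[^ACGT]", cut_site))
    stop("cut_site must be a non-empty string over the ACGT alphabet")
  overhang <- as.integer(overhang)
  site_len <- nchar(cut_site)
  if (is.na(overhang) || overhang < 0L || overhang > site_len)
    stop("overhang must lie in [0, nchar(cut_site)]")
  if ((site_len - overhang) %% 2L != 0L)
    stop("nchar(cut_site) - overhang must be even (symmetric cut)")

  seqs <- .as_dna_set(genome)
  half <- (site_len - overhang) %/% 2L

  chroms <- lapply(seq_along(seqs), function(i) {
    L <- Biostrings::nchar(seqs)[i]
    hits <- Biostrings::matchPattern(cut_site, seqs[[i]])
    p <- BiocGenerics::start(hits) - 1L        # 0-based match starts
    cuts <- sort(unique(p + half))
    cuts <- cuts[cuts > 0L & cuts < L]
    starts <- c(0L, cuts)
    ends <- c(pmin(cuts + overhang, L), L)
    list(length = L, cuts = cuts,
         fragments = data.frame(start = starts, end = ends))
  })
  names(chroms) <- names(seqs)
  structure(list(cut_site = cut_site, overhang = overhang, chroms = chroms),
            class = "RestrictionMap")
}

.as_dna_set <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- genome
  } else if (is.character(genome) && length(genome) == 1L &&
             is.null(names(genome)) && file.exists(genome)) {
    seqs <- Biostrings::readDNAStringSet(genome)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(genome)) {
    if (is.null(names(genome)) || any(!nzchar(names(genome))))
      stop("genome sequences must be named by chromosome")
    bad <- grepl("[^ACGTNacgtn]", genome)
    if (any(bad))
      stop("unknown characters in genome sequence(s): ",
           paste(names(genome)[bad], collapse = ", "))
    seqs <- Biostrings::DNAStringSet(toupper(genome))
  } else {
    stop("genome must be a DNAStringSet, a named character vector, ",
         "or a FASTA path")
  }
  if (anyDuplicated(names(seqs))) stop("duplicated chromosome names")
  seqs
}

#' @export
print.RestrictionMap <- function(x, ...) {
  nfrag <- vapply(x$chroms, function(ch) nrow(ch$fragments), integer(1))
  cat("RestrictionMap:", length(x$chroms), "chromosome(s), site",
      x$cut_site, "overhang", x$overhang, "bp\n")
  for (nm in names(x$chroms))
    cat(sprintf("  %s: %d bp, %d fragment(s)\n", nm,
                x$chroms[[nm]]$length, nfrag[[nm]]))
  invisible(x)
}

#' Restriction fragments as a single table
#'
#' @param map A \code{RestrictionMap}.
#' @return data.frame with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open) and \code{frag} (1-based index within the chromosome).
#' @export
restriction_fragments <- function(map) {
  stopifnot(inherits(map, "RestrictionMap"))
  do.call(rbind, lapply(names(map$chroms), function(nm) {
    fr <- map$chroms[[nm]]$fragments
    data.frame(chrom = nm, start = fr$start, end = fr$end,
               frag = seq_len(nrow(fr)))
  }))
}

#' Assign a genomic position to a restriction fragment
#'
#' Fragments overlap by the enzyme overhang, so a position inside an overlap
#' zone belongs to two fragments. The tie is resolved by the read direction:
#' a plus-strand read extends rightward into the downstream fragment, a
#' minus-strand read leftward into the upstream one.
#'
#' @param map A \code{RestrictionMap}.
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s) of the 5' base.
#' @param strand \code{"+"} or \code{"-"}, recycled.
#' @return Integer fragment indices (1-based within the chromosome).
#' @export
assign_fragment <- function(map, chrom, pos, strand) {
  stopifnot(inherits(map, "RestrictionMap"))
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  out <- integer(n)
  for (nm in unique(chrom)) {
    ch <- map$chroms[[nm]]
    if (is.null(ch)) stop("unknown chromosome: ", nm)
    sel <- which(chrom == nm)
    p <- pos[sel]
    if (any(p < 0L | p >= ch$length))
      stop("position outside chromosome ", nm)
    fr <- ch$fragments
    # index of the last fragment whose start <= p (downstream choice);
    # upstream choice is idx-1 when p falls before the previous fragment's end
    idx <- findInterval(p, fr$start)
    in_overlap <- idx > 1L & p < fr$end[pmax(idx - 1L, 1L)]
    take_upstream <- in_overlap & strand[sel] == "-"
    idx[take_upstream] <- idx[take_upstream] - 1L
    out[sel] <- idx
  }
  out
}
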