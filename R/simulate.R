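#' Simulate a toy genome with planted restriction sites
#'
#' Generates random ACGT chromosomes with the enzyme recognition site
#' planted at approximately exponentially spaced positions. The background
#' is screened so the motif occurs nowhere except at the planted positions,
#' hence digesting the result recovers exactly the returned truth sites.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param cut_site Recognition site to plant (ACGT).
#' @param spacing Mean distance between consecutive planted sites;
#'   \code{Inf} plants none. Must exceed \code{nchar(cut_site)}.
#' @param seed Random seed (the generators are seed-deterministic).
#' @return list with \code{sequences} (named character vector) and
#'   \code{sites} (named list of 0-based planted site start positions).
#' @export
simulate_genome <- function(chrom_lengths, cut_site, spacing = 500,
                            seed = NULL) {
  cut_site <- toupper(cut_site)
  len <- nchar(cut_site)
  if (!is.infinite(spacing) && spacing <= len)
    stop("spacing must exceed the cut-site length")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))

  seqs <- character(length(chrom_lengths))
  sites <- vector("list", length(chrom_lengths))
  names(seqs) <- names(sites) <- names(chrom_lengths)
  for (ci in seq_along(chrom_lengths)) {
    L <- chrom_lengths[ci]
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    pos <- integer()
    if (!is.infinite(spacing)) {
      gaps <- stats::rexp(ceiling(3 * L / spacing) + 5L, rate = 1 / spacing)
      pos <- floor(cumsum(pmax(gaps, len + 1)))
      pos <- pos[pos >= 1 & pos + len <= L - 1]
    }
    for (p in pos)
      base[(p + 1):(p + len)] <- strsplit(cut_site, "")[[1]]
    planted <- rep(FALSE, L)
    for (p in pos) planted[(p + 1):(p + len)] <- TRUE
    # screen out accidental motif occurrences in the background
    for (attempt in 1:100) {
      s <- paste(base, collapse = "")
      hits <- BiocGenerics::start(
        Biostrings::matchPattern(cut_site, Biostrings::DNAString(s))) - 1L
      stray <- setdiff(hits, pos)
      if (length(stray) == 0L) break
      for (p in stray) {
        span <- (p + 1):(p + len)
        free <- span[!planted[span]]
        if (length(free) == 0L)
          stop("spacing too small to screen accidental sites")
        base[free] <- sample(c("A", "C", "G", "T"), length(free),
                             replace = TRUE)
      }
      if (attempt == 100L)
        stop("spacing too small to screen accidental sites")
    }
    seqs[ci] <- paste(base, collapse = "")
    sites[[ci]] <- as.integer(pos)
  }
  list(sequences = seqs, sites = sites)
}

#' Write named sequences as FASTA
#'
#' @param sequences Named character vector or \code{DNAStringSet}.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Simulate labeled Hi-C read pairs
#'
#' Draws read pairs over a restriction map with controlled composition:
#' valid products between two distinct fragments, same-fragment artifacts
#' with the orientation that defines them (self-circles outward, dangling
#' ends inward, with insert lengths log-normal around
#' \code{artifact_insert} — 256 bp by default, the spike the orientation
#' diagnostics are designed to expose), and exact duplicate copies of valid
#' pairs carrying the duplicate flag. The truth label of every pair is
#' returned in the \code{label} column.
#'
#' @param map A \code{RestrictionMap}.
#' @param n_pairs Total number of pairs.
#' @param fractions Named numeric vector over \code{valid, self_circle,
#'   dangling_end, duplicate}, summing to 1.
#' @param read_length Aligned read length in bp (default 50).
#' @param artifact_insert Modal insert length of same-fragment artifacts.
#' @param insert_sdlog Log-normal sdlog of artifact inserts (default 0.03).
#' @param mapq Mapping quality assigned to every mate (default 60).
#' @param seed Random seed.
#' @return data.frame in [read_pairs()] layout plus a \code{label} column.
#' @export
simulate_pairs <- function(map, n_pairs,
                           fractions = c(valid = 1, self_circle = 0,
                                         dangling_end = 0, duplicate = 0),
                           read_length = 50, artifact_insert = 256,
                           insert_sdlog = 0.03, mapq = 60, seed = NULL) {
  stopifnot(inherits(map, "RestrictionMap"))
  fr <- stats::setNames(numeric(4),
                        c("valid", "self_circle", "dangling_end",
                          "duplicate"))
  bad <- setdiff(names(fractions), names(fr))
  if (length(bad)) stop("unknown fraction name(s): ",
                        paste(bad, collapse = ", "))
  fr[names(fractions)] <- fractions
  if (abs(sum(fr) - 1) > 1e-9) stop("fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  counts <- floor(fr * n_pairs)
  rem <- n_pairs - sum(counts)
  if (rem > 0) counts[order(fr * n_pairs - counts,
                            decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(fr * n_pairs - counts, decreasing = TRUE)[seq_len(rem)]] + 1

  frags <- restriction_fragments(map)
  ov <- map$overhang
  # interior span of each fragment, where a 5' base maps unambiguously
  frags$int_start <- frags$start + ifelse(frags$frag > 1L, ov, 0L)
  frags$int_end <- frags$end - ov
  lens <- vapply(names(map$chroms), function(nm) map$chroms[[nm]]$length,
                 numeric(1))
  rl <- as.integer(read_length)

  draw_pos <- function(fi) {   # 5' base inside fragment interior, read on-chrom
    lo <- max(frags$int_start[fi], rl - 1L)
    hi <- min(frags$int_end[fi] - 1L, lens[[frags$chrom[fi]]] - rl)
    if (hi < lo) return(NA_integer_)
    as.integer(sample(lo:hi, 1L))
  }

  # preallocated columns; add_row fills slot k
  n_tot <- n_pairs
  col <- list(chrom1 = character(n_tot), pos1 = integer(n_tot),
              strand1 = character(n_tot), chrom2 = character(n_tot),
              pos2 = integer(n_tot), strand2 = character(n_tot),
              duplicate = logical(n_tot), label = character(n_tot))
  k <- 0L
  add_row <- function(chrom1, p51, s1, chrom2, p52, s2, dup, label) {
    k <<- k + 1L
    col$chrom1[k] <<- chrom1
    col$pos1[k] <<- if (s1 == "+") p51 else p51 - rl + 1L
    col$strand1[k] <<- s1
    col$chrom2[k] <<- chrom2
    col$pos2[k] <<- if (s2 == "+") p52 else p52 - rl + 1L
    col$strand2[k] <<- s2
    col$duplicate[k] <<- dup
    col$label[k] <<- label
  }

  ok_frags <- which(frags$int_end - frags$int_start >= 2L * rl)
  if (length(ok_frags) < 2L) stop("fragments too short for requested reads")
  valid_rows <- integer()
  for (vk in seq_len(counts[["valid"]])) {
    for (try in 1:50) {
      fi <- sample(ok_frags, 2L)
      if (frags$chrom[fi[1]] == frags$chrom[fi[2]] &&
          frags$frag[fi[1]] == frags$frag[fi[2]]) next
      p1 <- draw_pos(fi[1]); p2 <- draw_pos(fi[2])
      if (is.na(p1) || is.na(p2)) next
      s1 <- sample(c("+", "-"), 1L); s2 <- sample(c("+", "-"), 1L)
      add_row(frags$chrom[fi[1]], p1, s1, frags$chrom[fi[2]], p2, s2,
              FALSE, "valid")
      valid_rows <- c(valid_rows, k)
      break
    }
  }

  plant_artifact <- function(kind) {
    inward <- kind == "dangling_end"
    for (try in 1:200) {
      ins <- as.integer(round(stats::rlnorm(1, log(artifact_insert),
                                            insert_sdlog)))
      span_needed <- if (inward) ins else ins - 2L * rl + 2L
      cand <- which(frags$int_end - frags$int_start >= span_needed + 2L)
      if (length(cand) == 0L) next
      fi <- if (length(cand) == 1L) cand else sample(cand, 1L)
      if (inward) {
        # leftmost mate +, rightmost mate -; the 5' ends are the outer ends
        lo <- max(frags$int_start[fi], 0L)
        hi <- frags$int_end[fi] - ins
        if (hi < lo) next
        p <- as.integer(sample(lo:hi, 1L))
        q <- p + ins - 1L
        if (p + rl > lens[[frags$chrom[fi]]] || q - rl + 1L < 0L) next
        add_row(frags$chrom[fi], p, "+", frags$chrom[fi], q, "-",
                FALSE, kind)
      } else {
        # leftmost mate -, rightmost mate +; the 5' ends are the inner ends
        gap <- ins - 2L * rl
        if (gap < 2L) next
        lo <- max(frags$int_start[fi], rl - 1L)
        hi <- frags$int_end[fi] - gap - 2L
        if (hi < lo) next
        p <- as.integer(sample(lo:hi, 1L))
        q <- p + gap + 1L
        if (p - rl + 1L < 0L || q + rl > lens[[frags$chrom[fi]]]) next
        add_row(frags$chrom[fi], p, "-", frags$chrom[fi], q, "+",
                FALSE, kind)
      }
      return(invisible(TRUE))
    }
    stop("could not place a ", kind, " artifact; fragments too short")
  }
  for (sk in seq_len(counts[["self_circle"]])) plant_artifact("self_circle")
  for (sk in seq_len(counts[["dangling_end"]])) plant_artifact("dangling_end")

  for (dk in seq_len(counts[["duplicate"]])) {
    src <- if (length(valid_rows) == 1L) valid_rows else
      sample(valid_rows, 1L)
    add_row(col$chrom1[src], .five_prime(col$pos1[src], col$strand1[src], rl),
            col$strand1[src], col$chrom2[src],
            .five_prime(col$pos2[src], col$strand2[src], rl),
            col$strand2[src], TRUE, "duplicate")
  }

  data.frame(chrom1 = col$chrom1[seq_len(k)], pos1 = col$pos1[seq_len(k)],
             strand1 = col$strand1[seq_len(k)], width1 = rl, mapq1 = mapq,
             chrom2 = col$chrom2[seq_len(k)], pos2 = col$pos2[seq_len(k)],
             strand2 = col$strand2[seq_len(k)], width2 = rl, mapq2 = mapq,
             duplicate = col$duplicate[seq_len(k)],
             label = col$label[seq_len(k)], stringsAsFactors = FALSE)
}

#' Write simulated pairs as a SAM file
#'
#' Emits two primary alignment records per pair (50M-style CIGAR, sequence
#' omitted), with mate information and the duplicate flag set, plus @SQ
#' header lines, so the file round-trips through [read_pairs()].
#'
#' @param pairs data.frame from [simulate_pairs()] (or [read_pairs()]
#'   layout).
#' @param chrom_lengths Named chromosome lengths for the header (or a
#'   \code{RestrictionMap}).
#' @param path Output SAM file.
#' @export
write_sam <- function(pairs, chrom_lengths, path) {
  if (inherits(chrom_lengths, "RestrictionMap"))
    chrom_lengths <- vapply(chrom_lengths$chroms, `[[`, numeric(1), "length")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(chrom_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm,
                       as.integer(chrom_lengths[[nm]])), con)
  if (nrow(pairs) == 0L) return(invisible(path))
  flag_of <- function(strand, mate_strand, first, dup) {
    f <- 1L + (if (first) 64L else 128L)
    if (strand == "-") f <- f + 16L
    if (mate_strand == "-") f <- f + 32L
    if (dup) f <- f + 1024L
    f
  }
  for (i in seq_len(nrow(pairs))) {
    qn <- sprintf("pair_%06d", i)
    cg1 <- sprintf("%dM", pairs$width1[i])
    cg2 <- sprintf("%dM", pairs$width2[i])
    rnext1 <- if (pairs$chrom1[i] == pairs$chrom2[i]) "=" else pairs$chrom2[i]
    rnext2 <- if (pairs$chrom1[i] == pairs$chrom2[i]) "=" else pairs$chrom1[i]
    writeLines(paste(
      qn, flag_of(pairs$strand1[i], pairs$strand2[i], TRUE,
                  pairs$duplicate[i]),
      pairs$chrom1[i], pairs$pos1[i] + 1L, pairs$mapq1[i], cg1,
      rnext1, pairs$pos2[i] + 1L, 0L, "*", "*", sep = "\t"), con)
    writeLines(paste(
      qn, flag_of(pairs$strand2[i], pairs$strand1[i], FALSE,
                  pairs$duplicate[i]),
      pairs$chrom2[i], pairs$pos2[i] + 1L, pairs$mapq2[i], cg2,
      rnext2, pairs$pos1[i] + 1L, 0L, "*", "*", sep = "\t"), con)
  }
  invisible(path)
}

#' Simulate a contact matrix with planted TADs and compartments
#'
#' Builds the expected intensity
#' \code{mu[i,j] = base * (1 + |i-j|)^(-decay) * tad * comp}, where
#' \code{tad = tad_factor} when i and j fall in the same planted domain and
#' 1 otherwise, and \code{comp = comp_factor} when the planted compartment
#' labels of i and j agree and 1 otherwise; the observed matrix is Poisson
#' around mu (or mu itself without noise) and symmetric by construction.
#'
#' @param n_bins Matrix dimension.
#' @param tad_boundaries Increasing bin indices, each the last bin of a
#'   domain (the final domain is implicit); empty for no TADs.
#' @param compartment_labels Optional vector of +1/-1 per bin.
#' @param base Baseline intensity (default 10).
#' @param decay Distance-decay exponent (default 1).
#' @param tad_factor Within-domain enrichment (default 1 = none).
#' @param comp_factor Within-compartment enrichment (default 1 = none).
#' @param noise Poisson noise flag (default TRUE).
#' @param seed Random seed.
#' @return list with \code{matrix}, \code{mu}, \code{boundaries},
#'   \code{labels}.
#' @export
simulate_contact_matrix <- function(n_bins, tad_boundaries = integer(),
                                    compartment_labels = NULL, base = 10,
                                    decay = 1, tad_factor = 1,
                                    comp_factor = 1, noise = TRUE,
                                    seed = NULL) {
  if (base <= 0 || tad_factor <= 0 || comp_factor <= 0)
    stop("intensity factors must be > 0")
  tad_boundaries <- as.integer(tad_boundaries)
  if (length(tad_boundaries) &&
      (is.unsorted(tad_boundaries, strictly = TRUE) ||
       any(tad_boundaries < 1L) || any(tad_boundaries >= n_bins)))
    stop("tad_boundaries must increase strictly within 1..n_bins-1")
  if (!is.null(seed)) set.seed(seed)

  domain <- findInterval(seq_len(n_bins) - 1L, c(0L, tad_boundaries))
  i <- row(matrix(0, n_bins, n_bins))
  j <- col(matrix(0, n_bins, n_bins))
  mu <- base * (1 + abs(i - j))^(-decay)
  if (length(tad_boundaries) || tad_factor != 1) {
    same_tad <- matrix(domain[i] == domain[j], n_bins)
    mu[same_tad] <- mu[same_tad] * tad_factor
  }
  if (!is.null(compartment_labels)) {
    stopifnot(length(compartment_labels) == n_bins)
    lab <- sign(compartment_labels)
    same_comp <- matrix(lab[i] * lab[j] > 0, n_bins)
    mu[same_comp] <- mu[same_comp] * comp_factor
  }
  if (noise) {
    M <- matrix(0, n_bins, n_bins)
    ut <- upper.tri(M, diag = TRUE)
    M[ut] <- stats::rpois(sum(ut), mu[ut])
    M <- M + t(M) - diag(diag(M))
  } else M <- mu
  list(matrix = M, mu = mu, boundaries = tad_boundaries,
       labels = compartment_labels)
}

#' Simulate a toy gene annotation
#'
#' Draws non-overlapping genes uniformly over the chromosomes and writes
#' them in GTF if a path is given.
#'
#' @param chrom_lengths Named chromosome lengths (or a
#'   \code{RestrictionMap}).
#' @param n_genes Number of genes.
#' @param gene_length Mean gene length in bp (default 300).
#' @param seed Random seed.
#' @param path Optional GTF output path.
#' @return data.frame with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open), \code{strand}, \code{gene_id}, \code{gene_name}.
#' @export
simulate_genes <- function(chrom_lengths, n_genes, gene_length = 300,
                           seed = NULL, path = NULL) {
  if (inherits(chrom_lengths, "RestrictionMap"))
    chrom_lengths <- vapply(chrom_lengths$chroms, `[[`, numeric(1), "length")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  used <- lapply(chrom_lengths, function(L) logical(L))
  for (g in seq_len(n_genes)) {
    for (try in 1:200) {
      ci <- sample(seq_along(chrom_lengths), 1L)
      L <- chrom_lengths[[ci]]
      glen <- max(50L, as.integer(round(stats::rexp(1, 1 / gene_length))))
      if (glen >= L) next
      s <- as.integer(sample(0:(L - glen - 1L), 1L))
      span <- (s + 1L):(s + glen)
      if (any(used[[ci]][span])) next
      used[[ci]][span] <- TRUE
      rows[[g]] <- data.frame(chrom = names(chrom_lengths)[ci], start = s,
                              end = s + glen,
                              strand = sample(c("+", "-"), 1L),
                              gene_id = sprintf("gene%03d", g),
                              gene_name = sprintf("GENE%03d", g))
      break
    }
    if (length(rows) < g) stop("could not place gene ", g,
                               "; genome too crowded")
  }
  genes <- do.call(rbind, rows)
  if (!is.null(path)) write_gtf(genes, path)
  genes
}

#' Write gene records as GTF
#'
#' @param genes data.frame from [simulate_genes()] (0-based half-open).
#' @param path Output file.
#' @export
write_gtf <- function(genes, path) {
  lines <- sprintf(
    "%s\thicekit\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$strand,
    genes$gene_id, genes$gene_name)
  writeLines(lines, path)
  invisible(path)
}
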