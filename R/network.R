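#' Map annotated genes onto the Hi-C bin grid
#'
#' Overlaps gene bodies with bin coordinates. A gene's body is the span
#' min(start)..max(end) over its records (gene-level GTF features are
#' preferred when present, otherwise the union of the gene's transcripts and
#' exons). Strand is ignored for the overlap; a bin may carry several genes
#' and a gene wider than the resolution spans several bins.
#'
#' @param annotation Path to a GTF file, or a data.frame with columns
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open),
#'   \code{gene_id} and optionally \code{gene_name}.
#' @param bins A \code{BinTable}.
#' @return A \code{GeneBinMap}: data.frame of associations with columns
#'   \code{gene_id}, \code{gene_name}, \code{bin}, \code{overlap_bp}; only
#'   bins with at least one gene appear.
#' @export
map_genes_to_bins <- function(annotation, bins) {
  genes <- if (is.character(annotation)) .read_gtf_genes(annotation)
           else annotation
  if (is.null(genes$gene_id)) stop("annotation lacks gene identifiers")
  if (is.null(genes$gene_name)) genes$gene_name <- genes$gene_id
  if (nrow(genes) == 0L) {
    out <- data.frame(gene_id = character(), gene_name = character(),
                      bin = integer(), overlap_bp = integer())
    class(out) <- c("GeneBinMap", "data.frame")
    return(out)
  }
  gr_bins <- GenomicRanges::GRanges(
    bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_bins, ignore.strand = TRUE)
  gi <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_genes)[gi], IRanges::ranges(gr_bins)[bi]))
  out <- data.frame(gene_id = genes$gene_id[gi],
                    gene_name = genes$gene_name[gi],
                    bin = bins$bin[bi], overlap_bp = ov)
  out <- out[order(out$bin, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("GeneBinMap", "data.frame")
  out
}

# gene-level records from a GTF: prefer "gene" features, else the span of
# each gene_id's records; GTF is 1-based inclusive, converted to 0-based
# half-open
.read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id)) stop("GTF lacks gene_id attributes")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   type = as.character(md$type),
                   gene_id = as.character(md$gene_id),
                   gene_name = if (!is.null(md$gene_name))
                     as.character(md$gene_name) else
                     as.character(md$gene_id))
  if (any(df$type == "gene")) {
    out <- df[df$type == "gene", c("chrom", "start", "end", "gene_id",
                                   "gene_name")]
  } else {
    sp <- split(df, df$gene_id)
    out <- do.call(rbind, lapply(sp, function(g)
      data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
                 gene_id = g$gene_id[1], gene_name = g$gene_name[1])))
  }
  rownames(out) <- NULL
  out
}

.parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("region must look like 'chr2:51902204-71950291'")
  list(chrom = m[2],
       start = as.numeric(gsub(",", "", m[3])),
       end = as.numeric(gsub(",", "", m[4])))
}

#' Interaction table for a region of interest
#'
#' Ranks and annotates interacting bin pairs: seed bins are those
#' overlapping the requested region; partners are either every bin of the
#' matrix (\code{global_scope = TRUE}) or the region bins themselves. A pair
#' is kept when its normalized interaction strength is at least
#' \code{norm_value}; with \code{intra_only}, inter-chromosomal pairs and
#' intra-chromosomal pairs closer than \code{min_bin_distance} bins are
#' dropped (nearby bins interact trivially).
#'
#' @param cm Normalized \code{ContactMatrix}.
#' @param region \code{"chrom:start-end"} string or list with those fields
#'   (1-based inclusive coordinates as written in genome browsers).
#' @param genes Optional \code{GeneBinMap} for gene annotation.
#' @param norm_value Minimum interaction strength (default 0.01).
#' @param min_bin_distance Minimum |i - j| for intra-chromosomal pairs kept
#'   under \code{intra_only} (default 0).
#' @param intra_only Drop inter-chromosomal and near-diagonal pairs.
#' @param global_scope Partners span the whole matrix, not only the region.
#' @return An \code{InteractionTable}: data.frame with bin pair, genomic
#'   coordinates, \code{strength}, comma-separated gene lists and
#'   \code{bin_distance} (NA for inter-chromosomal pairs), sorted by
#'   decreasing strength.
#' @export
build_interaction_table <- function(cm, region, genes = NULL,
                                    norm_value = 0.01, min_bin_distance = 0,
                                    intra_only = FALSE, global_scope = TRUE) {
  bins <- cm$bins
  if (is.character(region)) region <- .parse_region(region)
  rsel <- bins$chrom == region$chrom &
    bins$start < region$end & bins$end > (region$start - 1)
  seeds <- bins$bin[rsel]
  if (length(seeds) == 0L)
    stop("region overlaps no bin of the contact matrix")
  partners <- if (global_scope) bins$bin else seeds

  grid <- expand.grid(i = seeds, j = partners)
  ij <- cbind(pmin(grid$i, grid$j), pmax(grid$i, grid$j))
  ij <- unique(ij)
  strength <- cm$matrix[ij]
  keep <- !is.na(strength) & strength >= norm_value
  ij <- ij[keep, , drop = FALSE]
  strength <- strength[keep]

  same_chrom <- bins$chrom[ij[, 1]] == bins$chrom[ij[, 2]]
  dist <- ifelse(same_chrom, ij[, 2] - ij[, 1], NA_integer_)
  if (isTRUE(intra_only)) {
    keep <- same_chrom & dist >= min_bin_distance
    ij <- ij[keep, , drop = FALSE]
    strength <- strength[keep]
    dist <- dist[keep]
  }

  gene_list <- function(b) {
    if (is.null(genes)) return(rep("", length(b)))
    vapply(b, function(bb)
      paste(sort(unique(genes$gene_name[genes$bin == bb])), collapse = ","),
      character(1))
  }
  out <- data.frame(
    bin_i = ij[, 1], bin_j = ij[, 2],
    chrom_i = bins$chrom[ij[, 1]], start_i = bins$start[ij[, 1]],
    end_i = bins$end[ij[, 1]],
    chrom_j = bins$chrom[ij[, 2]], start_j = bins$start[ij[, 2]],
    end_j = bins$end[ij[, 2]],
    strength = strength,
    genes_i = gene_list(ij[, 1]), genes_j = gene_list(ij[, 2]),
    bin_distance = dist)
  out <- out[order(-out$strength, out$bin_i, out$bin_j), ]
  rownames(out) <- NULL
  class(out) <- c("InteractionTable", "data.frame")
  out
}

#' Interaction network graph
#'
#' Builds an undirected weighted graph from an interaction table: vertices
#' are the distinct bins (carrying coordinates and gene lists), edges the
#' retained interactions with weight equal to the interaction strength.
#'
#' @param table An \code{InteractionTable}.
#' @return An \code{igraph} graph.
#' @export
build_network <- function(table) {
  if (nrow(table) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  vb <- unique(c(table$bin_i, table$bin_j))
  vmeta <- do.call(rbind, lapply(vb, function(b) {
    r <- which(table$bin_i == b | table$bin_j == b)[1]
    if (table$bin_i[r] == b)
      data.frame(name = as.character(b), chrom = table$chrom_i[r],
                 start = table$start_i[r], end = table$end_i[r],
                 genes = table$genes_i[r])
    else
      data.frame(name = as.character(b), chrom = table$chrom_j[r],
                 start = table$start_j[r], end = table$end_j[r],
                 genes = table$genes_j[r])
  }))
  edges <- data.frame(from = as.character(table$bin_i),
                      to = as.character(table$bin_j),
                      weight = table$strength)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vmeta)
}

#' Export a network as JSON node/edge lists
#'
#' @param graph igraph graph from [build_network()].
#' @param path Output JSON file.
#' @export
write_network_json <- function(graph, path) {
  if (igraph::vcount(graph) == 0L) {
    nodes <- list(); edges <- list()
  } else {
    nodes <- igraph::as_data_frame(graph, what = "vertices")
    edges <- igraph::as_data_frame(graph, what = "edges")
  }
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Join expression values onto a gene table
#'
#' @param gene_table data.frame with a \code{gene_id} column (e.g. distinct
#'   genes of a \code{GeneBinMap}).
#' @param expression Two-column data.frame (gene id, expression value) or a
#'   TSV path. Duplicate identifiers keep the first occurrence with a
#'   warning. Join is by exact identifier; absent genes get NA.
#' @return The gene table with an added \code{expression} column.
#' @export
join_expression <- function(gene_table, expression) {
  if (is.character(expression))
    expression <- utils::read.table(expression, sep = "\t", header = FALSE,
                                    stringsAsFactors = FALSE)
  expression <- expression[, 1:2]
  names(expression) <- c("gene_id", "expression")
  if (anyDuplicated(expression$gene_id)) {
    warning("duplicate identifiers in expression table; keeping first")
    expression <- expression[!duplicated(expression$gene_id), ]
  }
  gene_table$expression <-
    expression$expression[match(gene_table$gene_id, expression$gene_id)]
  gene_table
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: per line, set name, description, then member genes,
#'   tab-separated.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param description Per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Local gene-set over-representation test
#'
#' For each collection set, tests whether the query genes over-represent the
#' set by the hypergeometric upper tail P(X >= k) with k the overlap size,
#' drawing |query| genes from a universe of |universe| genes of which
#' |set ∩ universe| are successes. P-values are Benjamini-Hochberg adjusted
#' across sets.
#'
#' @param query Character vector of gene ids (must be a subset of
#'   \code{universe}).
#' @param collections Named list of gene sets (e.g. [read_gmt()]).
#' @param universe Character vector of all testable gene ids.
#' @return data.frame with \code{term}, \code{set_size}, \code{overlap},
#'   \code{intersection} (comma-separated overlap genes), \code{p_value},
#'   \code{p_adjusted}, sorted by ascending p-value. Empty query gives an
#'   empty table.
#' @export
enrich <- function(query, collections, universe) {
  if (length(collections) == 0L) stop("collections must be non-empty")
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe))
    stop("query contains genes outside the universe")
  if (length(query) == 0L) {
    return(data.frame(term = character(), set_size = integer(),
                      overlap = integer(), intersection = character(),
                      p_value = numeric(), p_adjusted = numeric()))
  }
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(collections), function(nm) {
    set <- intersect(collections[[nm]], universe)
    m <- length(set)
    hit <- intersect(query, set)
    k <- length(hit)
    p <- stats::phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    data.frame(term = nm, set_size = m, overlap = k,
               intersection = paste(sort(hit), collapse = ","),
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  out
}
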