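#' Run the full Hi-C analysis pipeline from a config
#'
#' Executes digest -> filter -> bin -> normalize and the configured
#' downstream stages (compartments, TADs, ChIP coverage, BED tracks,
#' interaction network) over a project directory layout
#' \code{<project>/<sample>/<bin_size>/Results/<stage>/} with logs under
#' \code{SysOut/} and a JSON run manifest recording every stage's
#' parameters and output checksums. A stage whose parameters and outputs
#' are unchanged since the last run is skipped unless \code{force = TRUE}.
#'
#' Config keys (YAML file or list): \code{project_dir}, \code{sample},
#' \code{genome} (FASTA), \code{pairs} (SAM/BAM), \code{cut_site},
#' \code{overhang}, \code{bin_size}, \code{seed}, and optional blocks
#' \code{chromosomes}, \code{filter} (\code{min_inward}, \code{min_outward},
#' \code{max_frag_length}, \code{min_mapq}), \code{normalize}
#' (\code{method} ice|wavsis, \code{winsor_high}, \code{ignore_low},
#' \code{na_policy}), \code{compartments} (\code{n_components}, \code{mode}),
#' \code{tads} (\code{methods}, \code{di_window}, \code{window_size},
#' \code{p_threshold}, \code{Kmax}, \code{distribution}, \code{shape}),
#' \code{coverage} (list of \code{bam}, \code{label}, \code{norm},
#' \code{input}), \code{bed_tracks} (list of \code{bed}, \code{label},
#' \code{mode}), \code{network} (\code{region}, \code{norm_value},
#' \code{min_bin_distance}, \code{intra_only}, \code{global},
#' \code{gtf}, \code{expression}, \code{gmt}).
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @param force Re-run every stage even when outputs are current.
#' @return Invisibly, a list with the manifest and the key in-memory results.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .check_config(config)
  root <- file.path(config$project_dir, config$sample,
                    as.character(config$bin_size))
  res_dir <- file.path(root, "Results")
  log_dir <- file.path(root, "SysOut")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(log_dir, "pipeline.log")
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    paste0(...))
    cat(line, "\n", file = log_file, append = TRUE)
    message(line)
  }
  manifest_path <- file.path(root, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()

  if (!is.null(config$seed)) set.seed(config$seed)

  stage_dir <- function(stage) {
    d <- file.path(res_dir, stage)
    dir.create(d, showWarnings = FALSE)
    d
  }
  strip_nulls <- function(x) if (is.list(x)) x[!vapply(x, is.null, TRUE)]
                             else x
  current <- function(stage, params, outputs) {
    rec <- manifest[[stage]]
    if (force || is.null(rec)) return(FALSE)
    same <- identical(jsonlite::toJSON(strip_nulls(params),
                                       auto_unbox = TRUE),
                      jsonlite::toJSON(strip_nulls(rec$params),
                                       auto_unbox = TRUE))
    same && all(file.exists(unlist(outputs)))
  }
  record <- function(stage, params, outputs) {
    manifest[[stage]] <<- list(
      params = strip_nulls(params), outputs = unlist(outputs),
      checksums = as.list(tools::md5sum(unlist(outputs))),
      timestamp = format(Sys.time()))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  ## digest --------------------------------------------------------------
  d <- stage_dir("preprocess")
  frag_file <- file.path(d, "fragments.tsv")
  par_digest <- list(genome = config$genome, cut_site = config$cut_site,
                     overhang = config$overhang)
  map <- digest_genome(config$genome, config$cut_site, config$overhang)
  if (!current("digest", par_digest, frag_file)) {
    logf("digest: indexing restriction fragments")
    utils::write.table(restriction_fragments(map), frag_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("digest", par_digest, frag_file)
  } else logf("digest: outputs current, skipped")

  ## filter --------------------------------------------------------------
  d <- stage_dir("filtering")
  fcfg <- config$filter
  par_filter <- list(pairs = config$pairs, min_inward = fcfg$min_inward,
                     min_outward = fcfg$min_outward,
                     max_frag_length = fcfg$max_frag_length,
                     min_mapq = if (is.null(fcfg$min_mapq)) 10
                                else fcfg$min_mapq)
  out_filter <- file.path(d, c("pairs.tsv", "filter_summary.tsv",
                               "orientation_curves.tsv"))
  raw <- annotate_pairs(read_pairs(config$pairs), map)
  flt <- filter_pairs(raw, min_inward = fcfg$min_inward,
                      min_outward = fcfg$min_outward,
                      max_frag_length = fcfg$max_frag_length,
                      min_mapq = par_filter$min_mapq)
  if (!current("filter", par_filter, out_filter)) {
    logf("filter: ", flt$summary$retained_valid, "/", flt$summary$total,
         " pairs retained")
    utils::write.table(flt$pairs[, c("chrom1", "fp1", "strand1", "frag1",
                                     "chrom2", "fp2", "strand2", "frag2")],
                       out_filter[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(flt$summary, out_filter[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(diagnostic_distributions(flt$pairs)$orientation_curves,
                       out_filter[3], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("filter", par_filter, out_filter)
  } else logf("filter: outputs current, skipped")

  ## bin -----------------------------------------------------------------
  d <- stage_dir("binning")
  par_bin <- list(bin_size = config$bin_size,
                  chromosomes = config$chromosomes)
  out_bin <- file.path(d, c("bins.bed", "raw_matrix.tsv"))
  bins <- make_bins(map, config$bin_size)
  cm <- count_contacts(flt$pairs, bins)
  if (!is.null(config$chromosomes)) {
    cm <- subset_contacts(cm, config$chromosomes)
    bins <- cm$bins
  }
  if (!current("bin", par_bin, out_bin)) {
    logf("bin: ", nrow(bins), " bins at ", config$bin_size, " bp")
    write_bins_bed(bins, out_bin[1])
    write_contacts(cm, out_bin[2])
    record("bin", par_bin, out_bin)
  } else logf("bin: outputs current, skipped")

  ## normalize -----------------------------------------------------------
  d <- stage_dir("normalization")
  ncfg <- config$normalize
  method <- if (is.null(ncfg$method)) "ice" else ncfg$method
  par_norm <- list(method = method, winsor_high = ncfg$winsor_high,
                   ignore_low = ncfg$ignore_low, na_policy = ncfg$na_policy)
  out_norm <- file.path(d, "normalized_matrix.tsv")
  if (method == "ice") {
    ice <- ice_normalize(
      cm,
      winsor_high = if (is.null(ncfg$winsor_high)) 0.02 else ncfg$winsor_high,
      ignore_low = if (is.null(ncfg$ignore_low)) 0 else ncfg$ignore_low,
      na_policy = if (is.null(ncfg$na_policy)) "keep_na" else ncfg$na_policy)
    ncm <- ice$matrix
  } else {
    Mn <- matrix(NA_real_, nrow(bins), nrow(bins))
    for (ch in unique(bins$chrom)) {
      blk <- chrom_block(cm, ch)
      idx <- blk$bins$bin
      Mn[idx, idx] <- wavsis_normalize(
        blk$matrix,
        remove_uncovered = isTRUE(ncfg$remove_uncovered))
    }
    ncm <- contact_matrix(Mn, bins, normalized = TRUE)
  }
  if (!current("normalize", par_norm, out_norm)) {
    logf("normalize: method ", method)
    write_contacts(ncm, out_norm)
    record("normalize", par_norm, out_norm)
  } else logf("normalize: outputs current, skipped")

  ## compartments --------------------------------------------------------
  results <- list(map = map, summary = flt$summary, bins = bins, raw = cm,
                  normalized = ncm)
  ccfg <- config$compartments
  if (!is.null(ccfg)) {
    d <- stage_dir("pca")
    out_pca <- file.path(d, "eigenvectors.tsv")
    par_pca <- ccfg
    if (!current("compartments", par_pca, out_pca)) {
      logf("compartments: eigenvector analysis per chromosome")
      tracks <- list()
      for (ch in unique(bins$chrom)) {
        blk <- chrom_block(ncm, ch)
        pca <- compartment_pca(
          blk$matrix,
          n_components = if (is.null(ccfg$n_components)) 2
                         else ccfg$n_components,
          mode = if (is.null(ccfg$mode)) "oe_correlation" else ccfg$mode)
        for (j in seq_len(ncol(pca$vectors))) {
          vals <- rep(NA_real_, nrow(bins))
          vals[blk$bins$bin] <- pca$vectors[, j]
          tracks[[paste0(ch, "_PC", j)]] <-
            bin_track(bins, vals, label = paste0(ch, "_PC", j),
                      kind = "eigenvector")
        }
      }
      write_tracks_tsv(tracks, out_pca)
      record("compartments", par_pca, out_pca)
      results$compartments <- tracks
    } else logf("compartments: outputs current, skipped")
  }

  ## tads ----------------------------------------------------------------
  tcfg <- config$tads
  if (!is.null(tcfg)) {
    d <- stage_dir("tads")
    methods <- if (is.null(tcfg$methods)) "di" else unlist(tcfg$methods)
    par_tads <- tcfg
    out_tads <- character()
    if ("di" %in% methods) out_tads <- c(out_tads, file.path(d, "di.tsv"))
    if ("topdom" %in% methods)
      out_tads <- c(out_tads, file.path(d, "topdom_boundaries.bed"))
    if ("hicseg" %in% methods)
      out_tads <- c(out_tads, file.path(d, "hicseg_boundaries.bed"))
    if (!current("tads", par_tads, out_tads)) {
      logf("tads: methods ", paste(methods, collapse = ", "))
      segs <- list()
      di_tracks <- list()
      for (ch in unique(bins$chrom)) {
        blk <- chrom_block(cm, ch)
        nb <- nrow(blk$matrix)
        if ("di" %in% methods) {
          w <- if (!is.null(tcfg$di_window)) tcfg$di_window
               else min(di_window_bins(attr(bins, "w_b") %||% config$bin_size),
                        nb - 1L)
          vals <- rep(NA_real_, nrow(bins))
          vals[blk$bins$bin] <- directionality_index(blk$matrix, w)
          di_tracks[[ch]] <- bin_track(bins, vals, label = paste0(ch, "_di"),
                                       kind = "directionality")
        }
        if ("topdom" %in% methods)
          segs[[paste0("topdom_", ch)]] <- topdom_call(
            blk$matrix,
            window_size = if (is.null(tcfg$window_size)) 5
                          else tcfg$window_size,
            p_threshold = if (is.null(tcfg$p_threshold)) 0.05
                          else tcfg$p_threshold,
            chrom = ch)
        if ("hicseg" %in% methods)
          segs[[paste0("hicseg_", ch)]] <- hicseg_call(
            blk$matrix,
            Kmax = if (is.null(tcfg$Kmax)) max(1L, nb %/% 10L) else tcfg$Kmax,
            distribution = if (is.null(tcfg$distribution)) "poisson"
                           else tcfg$distribution,
            shape = if (is.null(tcfg$shape)) "block_diagonal" else tcfg$shape,
            chrom = ch)
      }
      if (length(di_tracks))
        write_tracks_tsv(di_tracks, file.path(d, "di.tsv"))
      for (m in c("topdom", "hicseg")) {
        if (!m %in% methods) next
        sel <- segs[grepl(paste0("^", m, "_"), names(segs))]
        write_boundaries_bed(sel, bins,
                             file.path(d, paste0(m, "_boundaries.bed")))
      }
      record("tads", par_tads, out_tads)
      results$tads <- segs
    } else logf("tads: outputs current, skipped")
  }

  ## coverage ------------------------------------------------------------
  vcfg <- config$coverage
  if (!is.null(vcfg)) {
    d <- stage_dir("epigenetics")
    out_cov <- file.path(d, "coverage.tsv")
    par_cov <- vcfg
    if (!current("coverage", par_cov, out_cov)) {
      tracks <- list()
      for (tc in vcfg) {
        logf("coverage: ", tc$label)
        cnt <- bin_coverage(tc$bam, bins, label = tc$label)
        norm <- if (is.null(tc$norm)) "rpm" else tc$norm
        tracks[[tc$label]] <- if (norm == "ratio")
          normalize_coverage(cnt, "ratio",
                             bin_coverage(tc$input, bins, label = "input"))
        else normalize_coverage(cnt, "rpm")
      }
      write_tracks_tsv(tracks, out_cov)
      record("coverage", par_cov, out_cov)
      results$coverage <- tracks
    } else logf("coverage: outputs current, skipped")
  }

  ## bed2track -----------------------------------------------------------
  bcfg <- config$bed_tracks
  if (!is.null(bcfg)) {
    d <- stage_dir("bed2track")
    out_bt <- file.path(d, "bed_tracks.tsv")
    if (!current("bed2track", bcfg, out_bt)) {
      tracks <- lapply(bcfg, function(tc)
        bed_to_bin_track(tc$bed, bins,
                         score_mode = if (is.null(tc$mode)) "binary"
                                      else tc$mode,
                         label = tc$label))
      write_tracks_tsv(tracks, out_bt)
      record("bed2track", bcfg, out_bt)
      results$bed_tracks <- tracks
    } else logf("bed2track: outputs current, skipped")
  }

  ## network -------------------------------------------------------------
  kcfg <- config$network
  if (!is.null(kcfg)) {
    d <- stage_dir("network")
    out_net <- file.path(d, c("interactions.tsv", "genes.tsv",
                              "network.json"))
    if (!is.null(kcfg$gmt)) out_net <- c(out_net, file.path(d, "enrich.tsv"))
    if (!current("network", kcfg, out_net)) {
      logf("network: region ", kcfg$region)
      genes <- if (!is.null(kcfg$gtf)) map_genes_to_bins(kcfg$gtf, bins)
               else NULL
      tab <- build_interaction_table(
        ncm, kcfg$region, genes = genes,
        norm_value = if (is.null(kcfg$norm_value)) 0.01 else kcfg$norm_value,
        min_bin_distance = if (is.null(kcfg$min_bin_distance)) 0
                           else kcfg$min_bin_distance,
        intra_only = isTRUE(kcfg$intra_only),
        global_scope = !isFALSE(kcfg$global))
      utils::write.table(tab, out_net[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      gene_tab <- if (!is.null(genes) && nrow(genes)) {
        gt <- unique(genes[genes$bin %in% c(tab$bin_i, tab$bin_j),
                           c("gene_id", "gene_name")])
        if (!is.null(kcfg$expression)) gt <- join_expression(
          gt, kcfg$expression)
        gt
      } else data.frame(gene_id = character(), gene_name = character())
      utils::write.table(gene_tab, out_net[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_network_json(build_network(tab), out_net[3])
      if (!is.null(kcfg$gmt)) {
        sets <- read_gmt(kcfg$gmt)
        universe <- unique(genes$gene_id)
        q <- intersect(gene_tab$gene_id, universe)
        utils::write.table(enrich(q, sets, universe), out_net[4],
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      record("network", kcfg, out_net)
      results$interactions <- tab
    } else logf("network: outputs current, skipped")
  }

  logf("pipeline complete")
  invisible(list(manifest = manifest, results = results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_config <- function(config) {
  required <- c("project_dir", "sample", "genome", "pairs", "cut_site",
                "overhang", "bin_size")
  optional <- c("seed", "chromosomes", "filter", "normalize", "compartments",
                "tads", "coverage", "bed_tracks", "network")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("config is missing required key(s): ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(names(config), c(required, optional))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (f in c(config$genome, config$pairs))
    if (!file.exists(f)) stop("input file does not exist: ", f)
  invisible(TRUE)
}

#' Write TAD boundaries of one or more segmentations as BED
#'
#' @param segs A \code{Segmentation} or list of them (each with its
#'   \code{chrom} set).
#' @param bins The \code{BinTable} the segmentations refer to.
#' @param path Output BED file.
#' @export
write_boundaries_bed <- function(segs, bins, path) {
  if (inherits(segs, "Segmentation")) segs <- list(segs)
  rows <- list()
  for (sg in segs) {
    cb <- bins[bins$chrom == sg$chrom, , drop = FALSE]
    for (b in sg$boundaries) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = sg$chrom, start = cb$start[b], end = cb$end[b],
        name = paste0(sg$method, "_boundary"))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
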