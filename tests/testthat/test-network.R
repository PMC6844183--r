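make_bins_plain <- function(L = 1000, w = 100) {
  map <- digest_genome(c(c1 = paste(rep("A", L), collapse = "")),
                       "GAATTC", 0)
  make_bins(map, w)
}

test_that("gene-bin overlap follows the half-open convention", {
  bins <- make_bins_plain()
  genes <- data.frame(chrom = "c1", start = 120, end = 480,
                      gene_id = "g1", gene_name = "G1")
  gb <- map_genes_to_bins(genes, bins)
  expect_equal(gb$bin, 2:5)               # 0-based bins 1..4
  expect_equal(gb$overlap_bp, c(80L, 100L, 100L, 80L))
  # gene inside one bin -> a single association
  g2 <- data.frame(chrom = "c1", start = 210, end = 240, gene_id = "g2",
                   gene_name = "G2")
  expect_equal(nrow(map_genes_to_bins(g2, bins)), 1L)
  # two genes in one bin -> both listed
  g3 <- rbind(g2, data.frame(chrom = "c1", start = 250, end = 270,
                             gene_id = "g3", gene_name = "G3"))
  gb3 <- map_genes_to_bins(g3, bins)
  expect_setequal(gb3$gene_id[gb3$bin == 3], c("g2", "g3"))
})

test_that("GTF files parse to gene-level associations", {
  bins <- make_bins_plain()
  genes <- data.frame(chrom = "c1", start = c(120, 510), end = c(480, 560),
                      strand = c("+", "-"), gene_id = c("g1", "g2"),
                      gene_name = c("G1", "G2"))
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(genes, gtf)
  gb <- map_genes_to_bins(gtf, bins)
  expect_equal(sort(unique(gb$gene_id)), c("g1", "g2"))
  expect_equal(gb$bin[gb$gene_id == "g2"], 6L)
})

test_that("interaction table keeps exactly the supra-threshold pairs", {
  bins <- make_bins_plain()
  M <- matrix(0.001, 10, 10)
  M[2, 9] <- M[9, 2] <- 0.02              # the planted strong pair
  diag(M) <- 0.05
  cm <- contact_matrix(M, bins, normalized = TRUE)
  tab <- build_interaction_table(cm, "c1:1-1000", norm_value = 0.01,
                                 min_bin_distance = 2, intra_only = TRUE)
  expect_equal(nrow(tab), 1L)
  expect_equal(c(tab$bin_i, tab$bin_j), c(2L, 9L))
  expect_equal(tab$strength, 0.02)
  expect_equal(tab$bin_distance, 7L)
  # a threshold above the maximum empties the table
  empty <- build_interaction_table(cm, "c1:1-1000", norm_value = 1)
  expect_equal(nrow(empty), 0L)
  expect_error(build_interaction_table(cm, "c2:1-100"), "no bin")
})

test_that("interaction filters are monotone in their thresholds", {
  set.seed(51)
  bins <- make_bins_plain()
  M <- matrix(stats::runif(100, 0, 0.03), 10)
  M <- (M + t(M)) / 2
  cm <- contact_matrix(M, bins, normalized = TRUE)
  n_rows <- function(nv, md) nrow(build_interaction_table(
    cm, "c1:1-1000", norm_value = nv, min_bin_distance = md,
    intra_only = TRUE))
  for (nv in c(0, 0.005, 0.01, 0.02)) {
    expect_gte(n_rows(nv, 0), n_rows(nv + 0.005, 0))
  }
  for (md in 0:5) expect_gte(n_rows(0.005, md), n_rows(0.005, md + 1))
  # min_bin_distance = 8 leaves no pair closer than 8 bins
  t8 <- build_interaction_table(cm, "c1:1-1000", norm_value = 0,
                                min_bin_distance = 8, intra_only = TRUE)
  if (nrow(t8)) expect_true(all(t8$bin_distance >= 8))
})

test_that("the network mirrors the interaction table exactly", {
  bins <- make_bins_plain()
  M <- matrix(0, 10, 10)
  M[1, 4] <- M[4, 1] <- 0.03
  M[4, 7] <- M[7, 4] <- 0.02
  M[1, 7] <- M[7, 1] <- 0.05
  cm <- contact_matrix(M, bins, normalized = TRUE)
  tab <- build_interaction_table(cm, "c1:1-1000", norm_value = 0.01,
                                 min_bin_distance = 1, intra_only = TRUE)
  g <- build_network(tab)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 3L)
  ed <- igraph::as_data_frame(g)
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  tkey <- paste(tab$bin_i, tab$bin_j)
  expect_equal(ed$weight[match(tkey, key)], tab$strength)
  # empty table -> empty graph; JSON export round-trips the edge count
  expect_equal(igraph::vcount(build_network(tab[0, ])), 0L)
  f <- tempfile(fileext = ".json")
  write_network_json(g, f)
  js <- jsonlite::read_json(f)
  expect_length(js$edges, 3L)
  expect_length(js$nodes, 3L)
})

test_that("expression joins by exact identifier with NA for absentees", {
  gt <- data.frame(gene_id = c("g1", "g2", "g3"),
                   gene_name = c("G1", "G2", "G3"))
  ex <- data.frame(id = c("g3", "g1"), value = c(7, 2))
  j <- join_expression(gt, ex)
  expect_equal(j$expression, c(2, NA, 7))
  # duplicates keep the first with a warning; join is order-independent
  ex2 <- data.frame(id = c("g1", "g1", "g3"), value = c(2, 99, 7))
  expect_warning(j2 <- join_expression(gt, ex2), "duplicate")
  expect_equal(j2$expression, c(2, NA, 7))
  set.seed(52)
  big <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    gene_name = sprintf("G%03d", 1:100))
  exb <- data.frame(id = big$gene_id, value = stats::runif(100))
  perm <- exb[sample.int(100), ]
  expect_equal(join_expression(big, exb)$expression,
               join_expression(big, perm)$expression)
})

test_that("hypergeometric enrichment matches the closed form", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(hit = universe[1:5], miss = universe[6:10])
  res <- enrich(universe[1:5], sets, universe)
  expect_equal(res$p_value[res$term == "hit"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$term == "miss"], 1)
  expect_equal(res$overlap[res$term == "hit"], 5L)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # BH adjustment is monotone in rank
  expect_true(all(diff(res$p_adjusted[order(res$p_value)]) >= -1e-15))
  expect_equal(nrow(enrich(character(), sets, universe)), 0L)
  expect_error(enrich("zzz", sets, universe), "outside")
})

test_that("GMT collections round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
})
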