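test_that("pair classification follows fragment identity and orientation", {
  fx <- toy_genome_map(seed = 2)
  frags <- restriction_fragments(fx$map)
  fA <- frags[frags$chrom == "chrA", ]
  # pick two distinct roomy fragments
  roomy <- fA[fA$end - fA$start > 400, ]
  f1 <- roomy[1, ]; f2 <- roomy[3, ]
  mid <- function(f) as.integer((f$start + f$end) / 2)

  valid <- make_pair(pos1 = mid(f1), strand1 = "+", pos2 = mid(f2),
                     strand2 = "-", chrom1 = "chrA", chrom2 = "chrA")
  self_c <- make_pair(pos1 = mid(f1) + 59, strand1 = "-",
                      pos2 = mid(f1) + 100, strand2 = "+",
                      chrom1 = "chrA", chrom2 = "chrA")
  dangl <- make_pair(pos1 = mid(f1), strand1 = "+",
                     pos2 = mid(f1) + 100, strand2 = "-",
                     chrom1 = "chrA", chrom2 = "chrA")
  same_s <- make_pair(pos1 = mid(f1), strand1 = "+",
                      pos2 = mid(f1) + 100, strand2 = "+",
                      chrom1 = "chrA", chrom2 = "chrA")
  ann <- annotate_pairs(rbind(valid, self_c, dangl, same_s), fx$map)
  expect_equal(ann$category,
               c("valid", "self_circle", "dangling_end",
                 "same_fragment_other"))
  expect_equal(ann$orientation[2:4], c("outward", "inward", "same"))
})

test_that("fragment length estimate sums each mate's distance to its cut", {
  map <- toy_map_one_site()   # fragments [0,45) end cut 45, [41,100)
  # plus mate 5' at 10 -> 35 to the fragment end; minus mate 5' at 90
  # (pos 81, width 10) -> 49 from the fragment start; total 84
  p <- make_pair(pos1 = 10, strand1 = "+", pos2 = 81, strand2 = "-")
  ann <- annotate_pairs(p, map)
  expect_equal(ann$fraglen, 84L)
  # both mates' 5' bases exactly at their cut positions -> estimate 0
  g <- paste(rep("T", 30), collapse = "")
  substr(g, 6, 11) <- "GAATTC"
  substr(g, 16, 21) <- "GAATTC"
  map0 <- digest_genome(c(chr1 = g), "GAATTC", 0)  # cuts at 8 and 18
  p0 <- make_pair(pos1 = 8, strand1 = "-", pos2 = 18, strand2 = "-",
                  width = 1L)
  expect_equal(annotate_pairs(p0, map0)$fraglen, 0L)
})

test_that("filtering accounts for every pair exactly once and is idempotent", {
  fx <- toy_genome_map(seed = 5)
  pr <- simulate_pairs(fx$map, 1000,
                       c(valid = 0.7, self_circle = 0.1,
                         dangling_end = 0.1, duplicate = 0.1), seed = 8)
  ann <- annotate_pairs(pr, fx$map)
  fl <- filter_pairs(ann)
  s <- fl$summary
  removed <- s$removed_duplicate + s$removed_low_mapq +
    s$removed_self_circle + s$removed_dangling_end +
    s$removed_same_fragment_same_strand + s$removed_too_long
  expect_equal(s$retained_valid + removed, s$total)
  expect_equal(s$total, 1000L)
  # generator truth recovered exactly
  expect_equal(s$removed_self_circle, sum(pr$label == "self_circle"))
  expect_equal(s$removed_dangling_end, sum(pr$label == "dangling_end"))
  expect_equal(s$removed_duplicate, sum(pr$label == "duplicate"))
  expect_true(all(fl$pairs$category == "valid"))
  # idempotence: filtering the retained set again removes nothing
  fl2 <- filter_pairs(fl$pairs)
  expect_equal(nrow(fl2$pairs), nrow(fl$pairs))
  expect_equal(fl2$summary$retained_valid, fl2$summary$total)
})

test_that("all-valid input with no thresholds passes through unchanged", {
  fx <- toy_genome_map(seed = 9)
  pr <- simulate_pairs(fx$map, 10, c(valid = 1), seed = 1)
  fl <- filter_pairs(annotate_pairs(pr, fx$map), min_mapq = NULL)
  expect_equal(fl$summary$retained_valid, 10L)
  expect_equal(fl$summary$total - fl$summary$retained_valid, 0L)
})

test_that("orientation-distance thresholds remove close pairs of that class", {
  fx <- toy_genome_map(seed = 3)
  frags <- restriction_fragments(fx$map)
  fA <- frags[frags$chrom == "chrA" & frags$end - frags$start > 150, ]
  # inward pair across adjacent fragments with insert ~256
  f1 <- fA[1, ]
  p <- make_pair(pos1 = f1$end - 60, strand1 = "+",
                 pos2 = f1$end + 186, strand2 = "-", width = 10L,
                 chrom1 = "chrA", chrom2 = "chrA")
  ann <- annotate_pairs(p, fx$map)
  expect_equal(ann$category, "valid")
  expect_equal(ann$orientation, "inward")
  expect_equal(ann$insert, 256L)
  fl <- filter_pairs(ann, min_inward = 1000)
  expect_equal(fl$summary$removed_dangling_end, 1L)
  expect_equal(nrow(fl$pairs), 0L)
  # without the threshold it survives
  expect_equal(filter_pairs(ann)$summary$retained_valid, 1L)
})

test_that("negative thresholds are rejected", {
  expect_error(filter_pairs(make_pair(pos1 = 1, strand1 = "+", pos2 = 50,
                                      strand2 = "-"),
                            toy_map_one_site(), min_inward = -1), ">= 0")
})

test_that("diagnostics bin inserts on a log2 axis split by orientation", {
  fx <- toy_genome_map(seed = 6)
  pr <- simulate_pairs(fx$map, 600,
                       c(valid = 0.5, dangling_end = 0.5), seed = 2)
  ann <- annotate_pairs(pr, fx$map)
  dd <- diagnostic_distributions(ann)
  expect_equal(sum(dd$insert_hist$count), sum(!is.na(ann$insert)))
  # the planted inward artifact spike sits in the log2 bin of 256 bp
  inw <- dd$orientation_curves
  expect_equal(inw$log2_bin[which.max(inw$inward)], 8)
  # after min_inward = 1000 the inward curve vanishes below log2(1000)
  fl <- filter_pairs(ann, min_inward = 1000)
  dd2 <- diagnostic_distributions(fl$pairs)
  low <- 2^(dd2$orientation_curves$log2_bin + 1) <= 1000
  expect_true(all(dd2$orientation_curves$inward[low] == 0))
  # empty input yields empty histograms, not an error
  dd0 <- diagnostic_distributions(ann[0, ])
  expect_equal(nrow(dd0$insert_hist), 0L)
})

test_that("simulated pairs round-trip through SAM", {
  fx <- toy_genome_map(seed = 7)
  pr <- simulate_pairs(fx$map, 200,
                       c(valid = 0.8, self_circle = 0.1, duplicate = 0.1),
                       seed = 4)
  sam <- tempfile(fileext = ".sam")
  write_sam(pr, fx$map, sam)
  rp <- read_pairs(sam)
  expect_equal(nrow(rp), nrow(pr))
  expect_equal(sum(rp$duplicate), sum(pr$duplicate))
  # categories identical whether annotated from memory or from disk
  ann_mem <- annotate_pairs(pr, fx$map)
  ann_sam <- annotate_pairs(rp, fx$map)
  expect_equal(sort(table(ann_sam$category)), sort(table(ann_mem$category)))
})
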