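test_that("read coverage counts 5' bases into bins and conserves reads", {
  fx <- toy_genome_map(seed = 41)
  bins <- make_bins(fx$map, 5000)
  pr <- simulate_pairs(fx$map, 300, c(valid = 1), seed = 6)
  sam <- tempfile(fileext = ".sam")
  write_sam(pr, fx$map, sam)
  tr <- bin_coverage(sam, bins, label = "H3K9Ac")
  expect_equal(sum(tr$values), 600)            # two mates per pair
  expect_equal(attr(tr, "n_assigned") + attr(tr, "n_dropped"),
               attr(tr, "n_total"))
  expect_equal(attr(tr, "n_dropped"), 0L)
  expect_equal(tr$kind, "coverage")
})

test_that("reads on chromosomes absent from the bin table are dropped", {
  fx <- toy_genome_map(seed = 42)
  bins <- make_bins(fx$map, 5000)
  bins_a <- bins[bins$chrom == "chrA", ]
  bins_a$bin <- seq_len(nrow(bins_a))
  class(bins_a) <- class(bins)
  pr <- simulate_pairs(fx$map, 200, c(valid = 1), seed = 2)
  sam <- tempfile(fileext = ".sam")
  write_sam(pr, fx$map, sam)
  expect_message(tr <- bin_coverage(sam, bins_a), "dropped")
  expect_equal(sum(tr$values) + attr(tr, "n_dropped"), 400)
})

test_that("RPM and ratio normalization follow their definitions", {
  fx <- toy_genome_map(seed = 43)
  bins <- make_bins(fx$map, 5000)
  chip <- bin_track(bins, rep(10, nrow(bins)), kind = "coverage")
  attr(chip, "n_total") <- 1e6
  rpm <- normalize_coverage(chip, "rpm")
  expect_equal(rpm$values, rep(10, nrow(bins)))
  input <- bin_track(bins, rep(5, nrow(bins)), kind = "coverage")
  rat <- normalize_coverage(chip, "ratio", input)
  expect_equal(rat$values, rep(2, nrow(bins)))
  # zero input -> NA, not infinity
  input$values[3] <- 0
  expect_true(is.na(normalize_coverage(chip, "ratio", input)$values[3]))
  expect_error(normalize_coverage(chip, "ratio"), "input_counts")
})

test_that("RPM totals reflect the assigned fraction and linearity", {
  fx <- toy_genome_map(seed = 44)
  bins <- make_bins(fx$map, 5000)
  set.seed(4)
  counts <- bin_track(bins, stats::rpois(nrow(bins), 20), kind = "coverage")
  attr(counts, "n_total") <- sum(counts$values) * 2   # half assigned
  rpm <- normalize_coverage(counts, "rpm")
  expect_equal(sum(rpm$values), 1e6 * 0.5)
  double <- counts; double$values <- 2 * counts$values
  attr(double, "n_total") <- attr(counts, "n_total")
  expect_equal(normalize_coverage(double, "rpm")$values, 2 * rpm$values)
})

test_that("BED intervals convert to occupancy on the half-open convention", {
  map <- digest_genome(c(c1 = paste(rep("A", 1000), collapse = "")),
                       "GAATTC", 0)
  bins <- make_bins(map, 100)
  bed <- tempfile(fileext = ".bed")
  writeLines("c1\t120\t480\tregion1\t7.5", bed)
  tr <- bin_track(bins, rep(0, 10))
  occ <- bed_to_bin_track(bed, bins)
  expect_equal(which(occ$values == 1), 2:5)       # bins 1..4 in 0-based terms
  # an interval exactly equal to one bin touches only that bin
  writeLines("c1\t300\t400\tb\t1", bed)
  occ2 <- bed_to_bin_track(bed, bins)
  expect_equal(which(occ2$values == 1), 4L)
  # max_score keeps the maximum score among intersecting intervals
  writeLines(c("c1\t120\t480\ta\t7.5", "c1\t150\t250\tb\t9"), bed)
  sc <- bed_to_bin_track(bed, bins, "max_score")
  expect_equal(sc$values[2], 9)
  expect_equal(sc$values[5], 7.5)
  expect_true(is.na(sc$values[1]))
  # empty BED -> all-zero occupancy; malformed line -> error with its number
  writeLines(character(), bed)
  expect_true(all(bed_to_bin_track(bed, bins)$values == 0))
  writeLines("c1\t120", bed)
  expect_error(bed_to_bin_track(bed, bins), "line 1")
})

test_that("occupancy grows monotonically as intervals are added", {
  map <- digest_genome(c(c1 = paste(rep("A", 1000), collapse = "")),
                       "GAATTC", 0)
  bins <- make_bins(map, 100)
  iv1 <- data.frame(chrom = "c1", start = 120, end = 180)
  iv2 <- rbind(iv1, data.frame(chrom = "c1", start = 700, end = 910))
  v1 <- bed_to_bin_track(iv1, bins)$values
  v2 <- bed_to_bin_track(iv2, bins)$values
  expect_true(all(v2 >= v1))
})

test_that("combined track tables round-trip", {
  fx <- toy_genome_map(seed = 45)
  bins <- make_bins(fx$map, 8000)
  t1 <- bin_track(bins, seq_len(nrow(bins)), label = "a")
  t2 <- bin_track(bins, rev(seq_len(nrow(bins))), label = "b")
  f <- tempfile()
  write_tracks_tsv(list(t1, t2), f)
  back <- read_tracks_tsv(f, bins)
  expect_equal(back$a$values, t1$values)
  expect_equal(back$b$values, t2$values)
})
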