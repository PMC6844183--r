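test_that("directionality index matches hand-evaluated cases", {
  # middle bin sees a = 10 upstream, b = 30 downstream -> d = +10
  M <- matrix(0, 3, 3)
  M[2, 1] <- M[1, 2] <- 10
  M[2, 3] <- M[3, 2] <- 30
  d <- directionality_index(M, 1)
  expect_equal(d[2], 10)
  # symmetric neighbours -> 0 by the a = b convention
  Ms <- matrix(5, 4, 4); diag(Ms) <- 0
  expect_equal(directionality_index(Ms, 1)[2:3], c(0, 0))
  expect_error(directionality_index(Ms, 4), "smaller")
  expect_error(directionality_index(Ms, 0), ">= 1")
})

test_that("directionality index is anti-symmetric under bin reversal", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    M <- matrix(stats::rpois(n * n, 5), n)
    M <- M + t(M)
    w <- sample(1:4, 1)
    d <- directionality_index(M, w)
    rev_idx <- n:1
    d_rev <- directionality_index(M[rev_idx, rev_idx], w)
    expect_equal(d_rev, -rev(d), tolerance = 1e-12)
  }
})

test_that("directionality index scales linearly with the matrix", {
  set.seed(32)
  M <- matrix(stats::rpois(100, 8), 10); M <- M + t(M)
  expect_equal(directionality_index(3 * M, 2),
               3 * directionality_index(M, 2))
})

test_that("compartment eigenvector recovers a planted checkerboard", {
  lab <- rep(c(1, -1), each = 20)   # two 20-bin compartment groups
  sim <- simulate_contact_matrix(40, compartment_labels = lab, base = 1,
                                 decay = 0, comp_factor = 10, noise = FALSE)
  for (mode in c("oe_correlation", "direct")) {
    p <- compartment_pca(sim$matrix, 1, mode = mode)
    agree <- mean(sign(p$vectors[, 1]) == lab)
    expect_true(agree == 1 || agree == 0)  # perfect up to a global flip
  }
})

test_that("noisy checkerboards are recovered with high sign agreement", {
  lab <- rep(c(1, -1), each = 20)
  rates <- sapply(1:20, function(s) {
    sim <- simulate_contact_matrix(40, compartment_labels = lab, base = 1,
                                   decay = 0, comp_factor = 10, noise = TRUE,
                                   seed = 1000 + s)
    p <- compartment_pca(sim$matrix, 1)
    agree <- mean(sign(p$vectors[, 1]) == lab)
    max(agree, 1 - agree)
  })
  expect_gte(mean(rates), 0.95)
})

test_that("degenerate and NA-bearing blocks are handled", {
  expect_true(all(is.na(compartment_pca(matrix(3, 10, 10), 1,
                                        "direct")$vectors)))
  set.seed(33)
  M <- matrix(stats::runif(100, 1, 3), 10); M <- (M + t(M)) / 2
  M[4, ] <- NA; M[, 4] <- NA
  p <- compartment_pca(M, 1)
  expect_true(is.na(p$vectors[4, 1]))
  expect_false(anyNA(p$vectors[-4, 1]))
  lb <- compartment_labels(p)
  expect_true(is.na(lb[4]))
  expect_true(all(lb[-4] %in% c("A", "B")))
})

test_that("window-signal caller finds no boundary in a flat matrix", {
  sg <- topdom_call(matrix(5, 30, 30), 3)
  expect_length(sg$boundaries, 0L)
  expect_equal(sg$domains$start_bin, 1L)
  expect_equal(sg$domains$end_bin, 30L)
})

test_that("window-signal caller finds a clean two-block junction", {
  M <- matrix(0, 20, 20)
  M[1:10, 1:10] <- 10
  M[11:20, 11:20] <- 10
  sg <- topdom_call(M, 3)
  expect_equal(sg$boundaries, 10L)
  expect_equal(nrow(sg$domains), 2L)
  # domains tile the block
  expect_equal(sg$domains$start_bin, c(1L, 11L))
  expect_equal(sg$domains$end_bin, c(10L, 20L))
})

test_that("window-signal caller recovers planted TAD boundaries", {
  truth <- seq(20, 180, by = 20)
  sim <- simulate_contact_matrix(200, tad_boundaries = truth, base = 2,
                                 decay = 0, tad_factor = 6, noise = TRUE,
                                 seed = 7)
  sg <- topdom_call(sim$matrix, 5)
  hit <- vapply(truth, function(b) any(abs(sg$boundaries - b) <= 1),
                logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("short blocks give an empty segmentation with a warning", {
  expect_warning(sg <- topdom_call(matrix(1, 5, 5), 5), "shorter")
  expect_length(sg$boundaries, 0L)
})

test_that("DP segmentation finds the planted change point", {
  M <- matrix(0, 4, 4)
  M[1:2, 1:2] <- 9
  M[3:4, 3:4] <- 5
  sg <- hicseg_call(M, 2, "gaussian", K = 2)
  expect_equal(sg$boundaries, 2L)
  # brute force over the 3 single-change-point segmentations agrees
  objs <- sapply(1:3, function(t)
    segment_objective(M, c(t, 4), "gaussian"))
  expect_equal(which.max(objs), 2L)
})

test_that("DP equals exhaustive enumeration at small n", {
  set.seed(34)
  for (rep in 1:15) {
    n <- sample(6:12, 1)
    M <- matrix(stats::rnorm(n * n), n)
    M <- (M + t(M)) / 2
    for (K in 1:3) {
      sg <- hicseg_call(M, 3, "gaussian", K = K)
      obj_dp <- segment_objective(M, c(sg$boundaries, n), "gaussian")
      best <- if (K == 1) segment_objective(M, n, "gaussian") else {
        cmb <- utils::combn(seq_len(n - 1), K - 1)
        max(apply(cmb, 2, function(b)
          segment_objective(M, c(b, n), "gaussian")))
      }
      expect_equal(obj_dp, best, tolerance = 1e-9)
    }
  }
})

test_that("extended shape DP also matches enumeration", {
  set.seed(35)
  for (rep in 1:5) {
    n <- 8
    M <- matrix(stats::rnorm(n * n), n)
    M <- (M + t(M)) / 2
    for (K in 2:3) {
      sg <- hicseg_call(M, 3, "gaussian", shape = "extended", K = K)
      obj_dp <- segment_objective(M, c(sg$boundaries, n), "gaussian",
                                  "extended")
      cmb <- utils::combn(seq_len(n - 1), K - 1)
      best <- max(apply(cmb, 2, function(b)
        segment_objective(M, c(b, n), "gaussian", "extended")))
      expect_equal(obj_dp, best, tolerance = 1e-9)
    }
  }
})

test_that("homogeneous Poisson matrices select a single segment", {
  ks <- sapply(1:20, function(s) {
    set.seed(400 + s)
    X <- matrix(stats::rpois(900, 8), 30)
    X <- floor((X + t(X)) / 2)
    hicseg_call(X, 5, "poisson")$parameters$K
  })
  expect_gt(mean(ks == 1L), 0.5)
})

test_that("Poisson DP recovers strong planted blocks with free K", {
  sim <- simulate_contact_matrix(60, tad_boundaries = c(20, 40), base = 2,
                                 decay = 0, tad_factor = 8, noise = TRUE,
                                 seed = 12)
  sg <- hicseg_call(sim$matrix, 6, "poisson")
  expect_equal(sg$parameters$K, 3L)
  expect_true(all(abs(sort(sg$boundaries) - c(20, 40)) <= 1))
})

test_that("segmentations tile and boundary calls are scale-invariant", {
  sim <- simulate_contact_matrix(50, tad_boundaries = c(15, 30), base = 3,
                                 decay = 0.3, tad_factor = 6, noise = TRUE,
                                 seed = 3)
  M <- sim$matrix
  for (sg in list(topdom_call(M, 4), hicseg_call(M, 5, "poisson", K = 3))) {
    d <- sg$domains
    expect_equal(d$start_bin[1], 1L)
    expect_equal(d$end_bin[nrow(d)], 50L)
    expect_equal(d$start_bin[-1], d$end_bin[-nrow(d)] + 1L)
  }
  # positive rescaling does not move TopDom or standardized-Gaussian calls
  sg1 <- topdom_call(M, 4)
  sg2 <- topdom_call(7 * M, 4)
  expect_equal(sg1$boundaries, sg2$boundaries)
  g1 <- hicseg_call(M, 5, "gaussian", K = 3)
  g2 <- hicseg_call(4 * M, 5, "gaussian", K = 3)
  expect_equal(g1$boundaries, g2$boundaries)
  expect_equal(directionality_index(2 * M, 3),
               2 * directionality_index(M, 3))
})

test_that("DP input validation", {
  M <- matrix(1, 5, 5)
  expect_error(hicseg_call(M, 9, "poisson"), "exceed")
  expect_error(hicseg_call(M, 3, "poisson", K = 5), "1..Kmax")
  expect_error(segment_objective(M, c(3, 2, 5), "poisson"), "strictly")
})
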