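# shared toy fixtures, all built in code

# chromosome of length 100 with one AAGCTT site at 0-based position 40;
# overhang 4 gives the cut at 41 and fragments [0,45) / [41,100)
toy_map_one_site <- function() {
  g <- paste(rep("T", 100), collapse = "")
  substr(g, 41, 46) <- "AAGCTT"
  digest_genome(c(chr1 = g), "AAGCTT", 4)
}

# one pair in read_pairs() layout
make_pair <- function(chrom1 = "chr1", pos1, strand1, chrom2 = "chr1",
                      pos2, strand2, width = 10L, mapq = 60L,
                      duplicate = FALSE) {
  data.frame(chrom1 = chrom1, pos1 = as.integer(pos1), strand1 = strand1,
             width1 = width, mapq1 = mapq, chrom2 = chrom2,
             pos2 = as.integer(pos2), strand2 = strand2, width2 = width,
             mapq2 = mapq, duplicate = duplicate, stringsAsFactors = FALSE)
}

# independent symmetric balancing oracle: finds x with equal row sums of
# diag(x) %*% M %*% diag(x) by plain damped fixed-point iteration
oracle_balance <- function(M, iters = 20000, tol = 1e-14) {
  x <- rep(1, nrow(M))
  for (k in seq_len(iters)) {
    s <- x * as.numeric(M %*% x)
    r <- s / mean(s)
    if (max(abs(r - 1)) < tol) break
    x <- x / sqrt(r)
  }
  B <- outer(x, x) * M
  B / mean(rowSums(B))     # normalized to mean row sum 1
}

# genome + map used by several module tests
toy_genome_map <- function(seed = 11, lengths = c(chrA = 60000, chrB = 40000),
                           spacing = 1200) {
  gen <- simulate_genome(lengths, "AAGCTT", spacing = spacing, seed = seed)
  list(gen = gen, map = digest_genome(gen$sequences, "AAGCTT", 4))
}
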