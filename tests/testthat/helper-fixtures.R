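# Shared fixtures and independent oracles used across test files.
# Oracles deliberately avoid package internals.

# symmetric control sample: exact mirror pairs so histogram mirroring is exact
symmetric_control <- function(n = 2000, seed = 1) {
  set.seed(seed)
  z <- abs(rnorm(n / 2))
  m <- cbind(f1 = c(z, -z))
  m
}

# brute-force entropy (natural log) from a plain table — independent of the
# package's entropy helper
oracle_entropy <- function(x) {
  p <- as.vector(table(x))
  p <- p[p > 0] / length(x)
  -sum(p * log(p))
}

oracle_su <- function(x, y) {
  hx <- oracle_entropy(x)
  hy <- oracle_entropy(y)
  hxy <- oracle_entropy(paste(x, y))
  if (hx + hy == 0) return(0)
  2 * (hx + hy - hxy) / (hx + hy)
}

# literal FCBF-by-definition: rank by SU with class, drop below threshold,
# then walk the ranking removing features predominated by a kept
# higher-ranked feature (ties broken lexicographically)
oracle_fcbf <- function(mat, labels, threshold) {
  su_c <- sapply(colnames(mat), function(f) oracle_su(mat[, f], labels))
  ids <- names(su_c)[su_c > threshold]
  ids <- ids[order(-su_c[ids], ids)]
  kept <- character(0)
  for (f in ids) {
    predominated <- FALSE
    for (g in kept) {
      if (oracle_su(mat[, f], mat[, g]) >= su_c[[f]]) {
        predominated <- TRUE
        break
      }
    }
    if (!predominated) kept <- c(kept, f)
  }
  kept
}

# adjusted Rand index between two labelings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# a tiny MS feature table with explicit intensities
toy_ms_table <- function() {
  data.frame(
    feature_id = c("1.00_100.0000", "2.00_200.0000", "3.00_300.0000"),
    rt = 1:3, mz = c(100, 200, 300),
    S1 = c(10, 0, 5), S2 = c(20, 0, 0), S3 = c(0, 7, 1),
    check.names = FALSE, stringsAsFactors = FALSE)
}
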