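test_that("detect_presence thresholds strictly and sweeps monotonically", {
  tab <- toy_ms_table()
  pres0 <- detect_presence(tab, 0)
  expect_identical(pres0[["1.00_100.0000"]], c("S1", "S2"))
  expect_identical(pres0[["3.00_300.0000"]], c("S1", "S3"))
  zero <- tab
  zero[, c("S1", "S2", "S3")] <- 0
  expect_true(all(lengths(detect_presence(zero, 0)) == 0))
  # monotone: higher threshold gives subset containment sets
  for (thr in c(1, 5, 10, 25)) {
    hi <- detect_presence(tab, thr)
    for (f in names(pres0)) expect_true(all(hi[[f]] %in% pres0[[f]]))
  }
})

test_that("activity_score matches bounds and the direct-summation oracle", {
  prof <- rbind(S1 = c(0, 0, 0, 0), S2 = c(1, 1, 1, 1),
                S3 = c(0.2, 0.4, 0.6, 0.8))
  pres <- list(zero = "S1", ones = "S2", multi = c("S1", "S2", "S3"))
  expect_identical(activity_score("zero", prof, pres), 0)
  expect_identical(activity_score("ones", prof, pres), 1)
  # brute force: mean over extracts of mean of squares
  brute <- mean(c(mean(prof["S1", ]^2), mean(prof["S2", ]^2),
                  mean(prof["S3", ]^2)))
  expect_equal(activity_score("multi", prof, pres), brute, tolerance = 1e-12)
  # literal sum-over-extracts reading behind the flag
  expect_equal(activity_score("multi", prof, pres, aggregate = "sum"),
               3 * brute, tolerance = 1e-12)
  expect_message(na <- activity_score("zero", prof, list(zero = character(0))),
                 "absent", class = "cpbionet_notice")
  expect_true(is.na(na))
})

test_that("cluster_score matches the pairwise Pearson oracle", {
  prof <- rbind(A = c(1, 2, 3, 4), B = c(2, 4, 6, 8),
                C = c(4, 3, 2, 1), D = c(1, 3, 2, 5))
  pres <- list(same = c("A", "B"), anti = c("A", "C"),
               all4 = c("A", "B", "C", "D"), single = "D")
  expect_equal(cluster_score("same", prof, pres), 1, tolerance = 1e-12)
  expect_equal(cluster_score("anti", prof, pres), -1, tolerance = 1e-12)
  pairs <- combn(c("A", "B", "C", "D"), 2)
  brute <- mean(apply(pairs, 2, function(p) cor(prof[p[1], ], prof[p[2], ])))
  expect_equal(cluster_score("all4", prof, pres), brute, tolerance = 1e-12)
  expect_identical(cluster_score("single", prof, pres), 1)
  expect_identical(cluster_score("single", prof, pres, singleton_score = 0), 0)
  # constant fingerprint in a pair contributes 0 with a notice
  profc <- rbind(A = c(1, 1, 1, 1), B = c(1, 2, 3, 4))
  expect_message(cs <- cluster_score("f", profc, list(f = c("A", "B"))),
                 "constant", class = "cpbionet_notice")
  expect_identical(cs, 0)
})

test_that("scores are invariant to sample ordering", {
  set.seed(8)
  prof <- matrix(runif(40), 5, 8,
                 dimnames = list(paste0("S", 1:5), NULL))
  pres <- list(f = c("S2", "S4", "S5"))
  perm <- prof[sample(rownames(prof)), ]
  expect_equal(activity_score("f", perm, pres),
               activity_score("f", prof, pres), tolerance = 1e-12)
  expect_equal(cluster_score("f", perm, pres),
               cluster_score("f", prof, pres), tolerance = 1e-12)
})

test_that("build_network applies both thresholds and drops isolated samples", {
  scores <- data.frame(
    feature_id = c("keep", "lowclust", "lowact"),
    activity_score = c(0.04, 0.04, 0.02),
    cluster_score = c(0.6, 0.4, 0.9),
    n_samples = c(2L, 2L, 2L), stringsAsFactors = FALSE)
  pres <- list(keep = c("S1", "S2"), lowclust = c("S1", "S3"),
               lowact = c("S4", "S5"))
  g <- build_network(scores, pres)
  expect_setequal(igraph::V(g)$name, c("S1", "S2", "keep"))
  expect_equal(igraph::ecount(g), 2)
  kept <- igraph::V(g)[igraph::V(g)$kind == "feature"]
  expect_equal(kept$activity_score, 0.04)
  # all features below threshold -> empty graph
  g0 <- build_network(scores, pres, min_activity = 0.5)
  expect_equal(igraph::vcount(g0), 0)
  # raising either threshold never adds nodes
  base <- igraph::vcount(build_network(scores, pres, 0.01, 0))
  for (ma in c(0.03, 0.05)) for (mc in c(0.3, 0.7)) {
    expect_lte(igraph::vcount(build_network(scores, pres, ma, mc)), base)
  }
  expect_error(build_network(scores, pres, min_cluster = 1.1))
})

test_that("community detection resolves disjoint stars and planted blocks", {
  mk_scores <- function(ids, ns) data.frame(
    feature_id = ids, activity_score = 1, cluster_score = 1,
    n_samples = ns, stringsAsFactors = FALSE)
  pres <- list(fA = c("S1", "S2", "S3"), fB = c("S4", "S5", "S6"))
  g <- build_network(mk_scores(c("fA", "fB"), c(3L, 3L)), pres)
  comm <- detect_communities(g, seed = 1)
  expect_equal(length(unique(comm)), 2)
  expect_length(unique(comm[c("S1", "S2", "S3", "fA")]), 1)
  # single edge -> one community
  g1 <- build_network(mk_scores("fA", 2L), list(fA = c("S1", "S2")))
  expect_equal(length(unique(detect_communities(g1, 1))), 1)
  expect_error(detect_communities(build_network(mk_scores("fA", 1L),
                                                list(fA = character(0)))),
               "empty")

  # planted two-block incidence recovered with ARI >= 0.9 across 20 seeds
  blockA <- paste0("A", 1:6); blockB <- paste0("B", 1:6)
  set.seed(99)
  pres2 <- c(lapply(1:8, function(i) sample(blockA, 4)),
             lapply(1:8, function(i) sample(blockB, 4)))
  names(pres2) <- paste0("f", 1:16)
  g2 <- build_network(mk_scores(names(pres2), rep(4L, 16)), pres2)
  truth <- setNames(c(rep(1, 6), rep(2, 6), rep(1, 8), rep(2, 8)),
                    c(blockA, blockB, names(pres2)))
  ari <- vapply(1:20, function(s) {
    comm <- detect_communities(g2, seed = s)
    oracle_ari(comm[names(truth)], truth)
  }, 0)
  expect_gte(median(ari), 0.9)
})

test_that("feature_scores composes presence and both scores", {
  tab <- toy_ms_table()
  prof <- rbind(S1 = c(0.5, 0.5), S2 = c(1, 0), S3 = c(0, 1))
  fs <- suppressMessages(feature_scores(tab, prof))
  expect_setequal(fs$feature_id, tab$feature_id)
  f1 <- fs[fs$feature_id == "1.00_100.0000", ]
  expect_equal(f1$activity_score, mean(c(mean(c(0.25, 0.25)), mean(c(1, 0)))),
               tolerance = 1e-12)
  expect_equal(f1$n_samples, 2L)
})

test_that("export_network round-trips GraphML and writes CSV twins", {
  scores <- data.frame(feature_id = "f1", activity_score = 0.25,
                       cluster_score = 0.75, n_samples = 2L,
                       stringsAsFactors = FALSE)
  g <- build_network(scores, list(f1 = c("S1", "S2")))
  comm <- detect_communities(g, 1)
  paths <- export_network(g, file.path(tempdir(), "net"), comm)
  back <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  f <- which(igraph::V(back)$name == "f1")
  expect_equal(igraph::V(back)$activity_score[f], 0.25) # numeric preserved
  nodes <- read.csv(paths[["nodes"]], stringsAsFactors = FALSE)
  expect_setequal(nodes$id, c("S1", "S2", "f1"))
  expect_true(is.numeric(nodes$activity_score))
  edges <- read.csv(paths[["edges"]], stringsAsFactors = FALSE)
  expect_equal(nrow(edges), 2)
  # empty network still exports a valid (empty) GraphML
  p0 <- export_network(build_network(scores, list(f1 = character(0))),
                       file.path(tempdir(), "net0"))
  back0 <- igraph::read_graph(p0[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(back0), 0)
})
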