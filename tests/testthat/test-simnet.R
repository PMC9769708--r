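params <- scoring_params()

test_that("score_pair matches self-alignment arithmetic and the E-value closed form", {
  a <- protein_record("a", strrep("A", 100))
  hit <- score_pair(a, a, params)
  expect_equal(hit$raw_score, 500)  # 100 aligned A:A pairs at BLOSUM45 +5
  # closed-form oracle evaluated independently of the implementation
  expect_equal(hit$evalue,
               params$K * 100 * 100 * exp(-params$lambda * 500),
               tolerance = 1e-12)
  expect_equal(hit$pvalue, 1 - exp(-hit$evalue), tolerance = 1e-12)
})

test_that("all-negative substitution pairs yield no hit", {
  w <- protein_record("w", strrep("W", 60))
  p <- protein_record("p", strrep("P", 60))
  expect_null(score_pair(w, p, params))
})

test_that("score_pair rejects nucleotide and malformed input", {
  nt <- list(id = "n", residues = "ACGT", alphabet = "nucleotide")
  a <- protein_record("a", "MKVMKV")
  expect_error(score_pair(nt, a, params), "protein")
  bad <- protein_record("b", "MKB1")
  expect_error(score_pair(bad, a, params), "outside")
})

test_that("evalue_to_pvalue implements 1 - exp(-E)", {
  expect_equal(evalue_to_pvalue(0), 0)
  expect_lt(abs(evalue_to_pvalue(0.01) - 0.00995), 1e-5)
  expect_lt(abs(evalue_to_pvalue(10) - 0.9999546), 1e-6)
  e <- c(1e-8, 0.5, 3)
  expect_true(all(diff(evalue_to_pvalue(e)) > 0))  # monotone
  expect_error(evalue_to_pvalue(-1), "non-negative")
})

test_that("build_network thresholds, merges reciprocals, keeps isolated nodes", {
  mk <- function(q, s, p) data.frame(query_id = q, subject_id = s,
                                     raw_score = 100, evalue = -log(1 - p),
                                     pvalue = p, attraction = 0.5,
                                     stringsAsFactors = FALSE)
  hits <- rbind(mk("a", "b", 1e-5), mk("b", "c", 0.5))
  net <- build_network(hits, c("a", "b", "c"), 1e-2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$a, "a"); expect_equal(net$edges$b, "b")
  expect_true("c" %in% net$ids)

  recip <- rbind(mk("a", "b", 0.3), mk("b", "a", 0.001))
  net2 <- build_network(recip, c("a", "b"), 1e-2)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$pvalue, 0.001)

  empty <- build_network(mk("a", "b", 1)[0, ], c("a", "b", "c"), 1e-2)
  expect_equal(nrow(empty$edges), 0)
  expect_length(empty$ids, 3)

  expect_error(build_network(mk("a", "zz", 0.001), c("a", "b"), 1e-2),
               "zz")
})

test_that("edge set is invariant under hit order (min-pvalue merge is commutative)", {
  set.seed(31)
  ids <- letters[1:6]
  pairs <- t(combn(ids, 2))
  hits <- data.frame(query_id = pairs[, 1], subject_id = pairs[, 2],
                     raw_score = 50, evalue = runif(nrow(pairs), 0, 0.05),
                     stringsAsFactors = FALSE)
  hits$pvalue <- evalue_to_pvalue(hits$evalue)
  hits$attraction <- 0.1
  # add reciprocal duplicates with different pvalues, then shuffle
  dup <- hits
  names(dup)[1:2] <- c("subject_id", "query_id")
  dup$evalue <- runif(nrow(dup), 0, 0.05)
  dup$pvalue <- evalue_to_pvalue(dup$evalue)
  all_hits <- rbind(hits, dup[, names(hits)])
  n1 <- build_network(all_hits, ids, 1e-2)
  n2 <- build_network(all_hits[sample(nrow(all_hits)), ], ids, 1e-2)
  expect_identical(n1$edges, n2$edges)
})

test_that("layout is deterministic per seed and separates planted families", {
  fam <- gen_protein_families(3, 6, 120, 0.05, seed = 21)
  hits <- all_pairwise_hits(fam$records, params)
  net <- build_network(hits, fam$records$id, 1e-2)
  l1 <- layout_network(net, dims = 2, rounds = 400, seed = 7)
  l2 <- layout_network(net, dims = 2, rounds = 400, seed = 7)
  expect_identical(l1$coords, l2$coords)
  expect_true(all(is.finite(l1$coords)))

  coords <- l1$coords[fam$truth$id, ]
  d <- as.matrix(dist(coords))
  same <- outer(fam$truth$family, fam$truth$family, "==")
  diag(same) <- NA
  expect_lt(mean(d[same & upper.tri(d)], na.rm = TRUE),
            mean(d[!same & upper.tri(d)], na.rm = TRUE))
})

test_that("two disconnected nodes repel monotonically", {
  net <- build_network(
    data.frame(query_id = character(), subject_id = character(),
               raw_score = numeric(), evalue = numeric(), pvalue = numeric(),
               attraction = numeric()),
    c("a", "b"), 1e-2)
  dists <- vapply(1:8, function(r) {
    l <- layout_network(net, dims = 2, rounds = r * 25, seed = 3)
    sqrt(sum((l$coords[1, ] - l$coords[2, ])^2))
  }, numeric(1))
  expect_true(all(diff(dists) > -1e-9))
  expect_error(layout_network(net, dims = 4, rounds = 10, seed = 1), "dims")
})

test_that("min-size rule routes small cliques to unclustered", {
  ids <- c(sprintf("big%02d", 1:10), sprintf("sm%02d", 1:9))
  clique_hits <- function(members) {
    pairs <- t(combn(members, 2))
    data.frame(query_id = pairs[, 1], subject_id = pairs[, 2],
               raw_score = 500, evalue = 1e-10, pvalue = 1e-10,
               attraction = 1, stringsAsFactors = FALSE)
  }
  hits <- rbind(clique_hits(ids[1:10]), clique_hits(ids[11:19]))
  net <- build_network(hits, ids, 1e-2)
  cl <- extract_clusters(net, "components", min_size = 10)
  expect_length(cl$clusters, 1)
  expect_setequal(cl$clusters[[1]], ids[1:10])
  expect_setequal(cl$unclustered, ids[11:19])

  # fully connected graph -> one cluster with everything
  all_net <- build_network(clique_hits(ids), ids, 1e-2)
  one <- extract_clusters(all_net, "components", min_size = 10)
  expect_length(one$clusters, 1)
  expect_setequal(one$clusters[[1]], ids)

  expect_error(extract_clusters(net, "nonsense"), "arg")
})

test_that("clusters plus unclustered partition the node set exactly", {
  fam <- gen_protein_families(4, 4, 100, 0.1, seed = 13)
  net <- build_network(all_pairwise_hits(fam$records, params),
                       fam$records$id, 1e-2)
  for (min_size in c(1, 3, 5)) {
    cl <- extract_clusters(net, "components", min_size = min_size)
    got <- c(unlist(cl$clusters, use.names = FALSE), cl$unclustered)
    expect_setequal(got, net$ids)
    expect_equal(length(got), length(net$ids))  # disjoint
    expect_true(all(lengths(cl$clusters) >= min_size))
  }
})

test_that("raising the p-threshold never shrinks components", {
  fam <- gen_protein_families(3, 5, 100, 0.15, seed = 77)
  hits <- all_pairwise_hits(fam$records, params)
  comp_sizes <- function(thr) {
    net <- build_network(hits, fam$records$id, thr)
    cl <- extract_clusters(net, "components", min_size = 1)
    sort(lengths(cl$clusters), decreasing = TRUE)
  }
  thresholds <- c(1e-10, 1e-5, 1e-2, 0.5)
  largest <- vapply(thresholds, function(t) comp_sizes(t)[1], numeric(1))
  expect_true(all(diff(largest) >= 0))
})

test_that("components method agrees with brute-force connected components", {
  fam <- gen_protein_families(4, 5, 150, 0.08, seed = 55)
  hits <- all_pairwise_hits(fam$records, params)
  net <- build_network(hits, fam$records$id, 1e-2)
  cl <- extract_clusters(net, "components", min_size = 1)
  # oracle: union-find over the edge list, written independently
  parent <- stats::setNames(net$ids, net$ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(net$edges)))
    parent[[find(net$edges$a[k])]] <- find(net$edges$b[k])
  roots <- vapply(net$ids, find, character(1))
  oracle <- unname(split(net$ids, roots))
  got <- unname(cl$clusters)
  key <- function(g) paste(sort(vapply(g, function(s) paste(sort(s), collapse = ","),
                                       character(1))), collapse = ";")
  expect_equal(key(got), key(oracle))
})

test_that("adjusted Rand index agrees with the mclust reference", {
  set.seed(17)
  for (i in 1:5) {
    a <- sample(letters[1:4], 40, TRUE)
    b <- sample(letters[1:3], 40, TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(rep(1:3, 5), rep(1:3, 5)), 1)
})

test_that("network_offset reassignment reproduces clean planted families", {
  fam <- gen_protein_families(3, 6, 150, 0.05, seed = 9)
  net <- build_network(all_pairwise_hits(fam$records, params),
                       fam$records$id, 1e-2)
  cl <- extract_clusters(net, "network_offset", min_size = 2, offset = 1.0)
  m <- merge(cluster_table(cl), fam$truth)
  expect_equal(adjusted_rand_index(m$cluster, m$family), 1)
})
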