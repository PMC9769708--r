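code <- genetic_code()

mk_cds <- function(codons, id = "g") {
  structure(list(id = id, codons = codons, genetic_code_id = 1L,
                 n_excluded_ambiguous = 0L, terminal_stop_trimmed = FALSE),
            class = "coding_sequence")
}

test_that("base composition counts match direct arithmetic", {
  comp <- base_composition(mk_cds(c("ATG", "AAA")), code)
  expect_equal(unname(comp$base_fractions),
               c(4 / 6, 1 / 6, 1 / 6, 0))             # A, T, G, C
  expect_equal(sum(comp$base_fractions), 1)
  expect_equal(comp$gc1, 0); expect_equal(comp$gc2, 0)
  expect_equal(comp$gc3, 50); expect_equal(comp$gc12, 0)
  # GC3s: ATG (Met) excluded as non-synonymous, AAA third base A -> 0
  expect_equal(comp$gc3s, 0)

  gg <- base_composition(mk_cds(c("GGC", "GGC")), code)
  expect_equal(gg$gc, 100); expect_equal(gg$gc3, 100); expect_equal(gg$gc12, 100)
})

test_that("PR2 site sets and coordinates behave per definition", {
  p <- codon_usage_profile(mk_cds(c("GGA", "GGT", "GGG", "GGC")), code)
  expect_equal(unname(p$pr2), c(0.5, 0.5))  # A3=T3, G3=C3
  counts <- list(third_counts = c(A3 = 5, T3 = 15, G3 = 30, C3 = 10))
  expect_equal(unname(pr2_point(counts)), c(0.75, 0.25))
  zero <- list(third_counts = c(A3 = 2, T3 = 2, G3 = 0, C3 = 0))
  expect_true(is.na(pr2_point(zero)[["x"]]))
  expect_equal(pr2_point(zero)[["y"]], 0.5)
  # fourfold-only site set ignores third positions of 2-fold codons
  cds <- mk_cds(c("GGA", "AAA"))   # Gly (4-fold), Lys (2-fold)
  ff <- base_composition(cds, code, pr2_sites = "fourfold")
  expect_equal(unname(ff$third_counts), c(1, 0, 0, 0))
  al <- base_composition(cds, code, pr2_sites = "all")
  expect_equal(unname(al$third_counts), c(2, 0, 0, 0))
})

test_that("RSCU follows the observed/expected definition with NA policy", {
  counts <- stats::setNames(rep(0L, 61), code$sense_codons)
  counts["AAA"] <- 3; counts["AAG"] <- 1
  r <- rscu(counts, code)
  expect_equal(unname(r["AAA"]), 1.5)
  expect_equal(unname(r["AAG"]), 0.5)
  expect_true(all(is.na(r[code$families[["G"]]])))   # unobserved family
  expect_false(any(c("ATG", "TGG") %in% names(r)))   # singletons excluded
  expect_error(rscu(stats::setNames(rep(-1, 61), code$sense_codons), code),
               "negative")
})

test_that("uniform usage within every family gives RSCU 1 everywhere", {
  counts <- stats::setNames(rep(7L, 61), code$sense_codons)
  r <- rscu(counts, code)
  expect_true(all(abs(r - 1) < 1e-12))
})

test_that("family RSCU sums equal family size for observed families", {
  set.seed(42)
  for (rep_i in 1:5) {
    counts <- stats::setNames(rpois(61, 10), code$sense_codons)
    r <- rscu(counts, code)
    for (fam in code$families) {
      if (length(fam) < 2) next
      if (sum(counts[fam]) == 0) next
      expect_equal(sum(r[fam]), length(fam), tolerance = 1e-12)
    }
  }
})

test_that("ENc hits its defining anchor values", {
  # one codon per amino acid forces every family homozygosity to 1 -> 20
  one <- stats::setNames(rep(0L, 61), code$sense_codons)
  for (fam in code$families) one[fam[1]] <- 10L
  expect_equal(enc(one, code)$enc, 20)

  # uniform usage at count 100: raw Wright value 61.41, capped to 61
  unif <- stats::setNames(rep(100L, 61), code$sense_codons)
  e <- enc(unif, code)
  expect_equal(e$enc, 61)
  raw <- 2 + 9 / e$fbar[["2"]] + 1 / e$fbar[["3"]] + 5 / e$fbar[["4"]] +
    3 / e$fbar[["6"]]
  expect_equal(raw, 61.41, tolerance = 0.005)
  expect_equal(e$fbar[["2"]], 99 / 199, tolerance = 1e-12)
  expect_equal(e$fbar[["6"]], 99 / 599, tolerance = 1e-12)

  # families all singleton-observed -> undefined
  sparse <- stats::setNames(rep(0L, 61), code$sense_codons)
  sparse[c("AAA", "GGG", "TTA")] <- 1L
  expect_true(is.na(enc(sparse, code)$enc))
})

test_that("ENc is scale-invariant and converges to the proportion limit", {
  set.seed(7)
  counts <- stats::setNames(rpois(61, 60) + 50L, code$sense_codons)
  base <- enc(counts, code)$enc
  # proportion-limit oracle: as counts grow, F -> sum(p^2) per family
  fams <- code$families[lengths(code$families) >= 2]
  f_inf <- vapply(fams, function(fam) {
    p <- counts[fam] / sum(counts[fam]); sum(p^2)
  }, numeric(1))
  k <- lengths(fams)
  limit <- 2 + sum(vapply(c(2, 3, 4, 6), function(kk)
    sum(k == kk) / mean(f_inf[k == kk]), numeric(1)))
  # the finite-sample correction decays like 1/n: scaling the counts moves
  # the estimate monotonically toward the proportion limit, and the shift
  # shrinks with depth
  prev_diff <- abs(base - limit)
  prev_shift <- Inf
  for (mult in c(2L, 5L, 10L)) {
    scaled <- enc(counts * mult, code)$enc
    shift <- abs(scaled - base)
    expect_lt(shift, prev_shift + 1e-12)
    expect_lt(abs(scaled - limit), prev_diff + 1e-12)
    prev_diff <- abs(scaled - limit)
    prev_shift <- shift + 1
  }
  expect_lt(abs(enc(counts * 50L, code)$enc - limit), 0.02)
})

test_that("expected ENc curve matches its closed form and symmetry", {
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(1), 32)
  s <- seq(0, 1, by = 0.05)
  expect_equal(expected_enc(s) - s, expected_enc(1 - s) - (1 - s),
               tolerance = 1e-12)
  expect_error(expected_enc(1.2), "0, 1")
})

test_that("neutrality regression matches the covariance-quotient oracle", {
  set.seed(11)
  for (i in 1:10) {
    gc3 <- runif(30, 20, 80)
    gc12 <- 0.4 * gc3 + rnorm(30, 0, 5)
    fit <- neutrality_regression(gc3, gc12)
    expect_equal(fit$slope, slope_oracle(gc3, gc12), tolerance = 1e-12)
    expect_equal(fit$mutation_pct + fit$selection_pct, 100)
    expect_equal(fit$pearson_r, cor(gc3, gc12), tolerance = 1e-12)
  }
  ident <- neutrality_regression(c(10, 20, 30, 40), c(10, 20, 30, 40))
  expect_equal(ident$slope, 1); expect_equal(ident$pearson_r, 1)
  flat <- neutrality_regression(c(10, 20, 30, 40), c(5, 5, 5, 5))
  expect_equal(flat$slope, 0); expect_equal(flat$pearson_r, 0)
  expect_error(neutrality_regression(c(5, 5, 5), c(1, 2, 3)), "variance")
  expect_error(neutrality_regression(c(1, 2), c(1, 2)), "3")
})

test_that("dataset summary aggregates means, SD and pooled RSCU cutoffs", {
  g1 <- codon_usage_profile(mk_cds(rep(c("GGG", "GGC"), 30), "g1"), code)
  g2 <- codon_usage_profile(mk_cds(rep(c("GGG", "AAA", "AAT", "TTT"), 15),
                                   "g2"), code)
  s <- summarize_dataset(list(g1, g2), code)
  expect_equal(s$n_genes, 2)
  expect_equal(s$gc_mean, mean(c(g1$gc, g2$gc)))
  expect_equal(s$gc_sd, sd(c(g1$gc, g2$gc)))
  # two genes at GC 40 and 50: mean 45, sd 7.071 shape check
  expect_equal(sd(c(40, 50)), 7.0711, tolerance = 1e-4)
  ok <- !is.na(s$pooled_rscu)
  expect_equal(s$n_rscu_gt1 + s$n_rscu_lt1 +
                 sum(s$pooled_rscu[ok] == 1), sum(ok))
  expect_error(summarize_dataset(list()), "empty")
})

test_that("pooled RSCU cutoff counts come from summed counts, not gene means", {
  # Lys heavily biased in one gene only; pooled counts decide the cutoff
  g1 <- codon_usage_profile(mk_cds(c(rep("AAA", 9), "AAG"), "g1"), code)
  g2 <- codon_usage_profile(mk_cds(rep(c("GGG", "GGC", "GGA", "GGT"), 5),
                                   "g2"), code)
  s <- summarize_dataset(list(g1, g2), code)
  expect_equal(unname(s$pooled_rscu["AAA"]), 1.8)  # 9/10 * 2
  expect_equal(s$n_rscu_gt1.5, 1)
})

test_that("per-gene profile table carries the ENc-GC3s expected curve", {
  gen <- gen_cds(20, 150, c(0.3, 0.7), w = 0.5, seed = 5)
  ds <- profile_dataset(gen$cds)
  expect_equal(nrow(ds$table), 20)
  ok <- !is.na(ds$table$gc3s) & !is.na(ds$table$enc)
  expect_true(any(ok))
  expect_equal(ds$table$expected_enc[ok],
               expected_enc(ds$table$gc3s[ok] / 100))
  expect_equal(ds$table$enc_residual[ok],
               ds$table$enc[ok] - ds$table$expected_enc[ok])
  expect_true(all(ds$table$enc[ok] >= 20 & ds$table$enc[ok] <= 61))
})
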