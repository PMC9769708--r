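#' Codon counts over the sense codons of a genetic code
#'
#' @param cds a [validate_cds()] result.
#' @param code a [genetic_code()].
#' @return named integer vector over the code's sense codons.
#' @export
codon_counts <- function(cds, code = genetic_code()) {
  counts <- table(factor(cds$codons, levels = code$sense_codons))
  stats::setNames(as.integer(counts), names(counts))
}

#' Base and positional GC composition of a coding sequence
#'
#' Overall A/T/G/C fractions over all retained codon bases; GC1/GC2/GC3 the
#' percent G+C at codon positions 1/2/3 over sense codons; GC12 their
#' first/second-position mean; GC3s the percent G+C over synonymous third
#' positions only (codons whose amino acid has at least two synonymous
#' codons, so Met and Trp are excluded, stops never enter); and the
#' third-position A3/T3/G3/C3 counts used by the PR2-bias plot, taken over
#' all sense codons (`pr2_sites = "all"`, matching the output convention of
#' codon-usage toolchains) or over fourfold-degenerate families only
#' (`"fourfold"`, Sueoka's original site set).
#'
#' @param cds a [validate_cds()] result.
#' @param code a [genetic_code()].
#' @param pr2_sites `"all"` (default) or `"fourfold"`.
#' @return list with `base_fractions` (named, sums to 1), `gc`, `gc1`,
#'   `gc2`, `gc3`, `gc12`, `gc3s` (percent scale), and `third_counts`
#'   (named counts A3/T3/G3/C3).
#' @export
base_composition <- function(cds, code = genetic_code(),
                             pr2_sites = c("all", "fourfold")) {
  pr2_sites <- match.arg(pr2_sites)
  codons <- cds$codons
  if (!length(codons)) stop("empty codon list")
  p1 <- substr(codons, 1, 1)
  p2 <- substr(codons, 2, 2)
  p3 <- substr(codons, 3, 3)
  all_bases <- c(p1, p2, p3)
  base_fractions <- vapply(c(A = "A", T = "T", G = "G", C = "C"),
                           function(b) mean(all_bases == b), numeric(1))
  pct_gc <- function(x) 100 * mean(x %in% c("G", "C"))
  gc1 <- pct_gc(p1); gc2 <- pct_gc(p2); gc3 <- pct_gc(p3)
  deg <- codon_degeneracy(code)[codons]
  syn3 <- p3[deg >= 2]
  gc3s <- if (length(syn3)) pct_gc(syn3) else NA_real_
  sites <- if (pr2_sites == "all") p3 else p3[deg == 4]
  third_counts <- vapply(c(A3 = "A", T3 = "T", G3 = "G", C3 = "C"),
                         function(b) sum(sites == b), numeric(1))
  list(base_fractions = base_fractions,
       gc = 100 * mean(all_bases %in% c("G", "C")),
       gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2,
       gc3s = gc3s, third_counts = third_counts)
}

#' Relative synonymous codon usage
#'
#' RSCU_j = x_j / (N / k) for codon j in a synonymous family of size k with
#' family total N: the observed count over the count expected under uniform
#' usage within the family. 1 means no bias; values above/below 1 mark
#' abundant/less-abundant codons. Families never observed give NA; the
#' singleton families (Met, Trp under the standard code) are excluded.
#'
#' @param counts named codon count vector (as from [codon_counts()]).
#' @param code a [genetic_code()].
#' @return named numeric vector over the codons of degenerate families,
#'   in code order.
#' @export
rscu <- function(counts, code = genetic_code()) {
  if (any(counts < 0)) stop("negative codon count")
  out <- numeric(0)
  for (fam in code$families) {
    k <- length(fam)
    if (k < 2) next
    x <- counts[fam]
    x[is.na(x)] <- 0
    N <- sum(x)
    vals <- if (N == 0) rep(NA_real_, k) else as.numeric(x) * k / N
    out <- c(out, stats::setNames(vals, fam))
  }
  out
}

#' Effective number of codons (ENc)
#'
#' Wright's homozygosity-based estimator. Per synonymous family with total
#' count n >= 2 the homozygosity is F = (n * sum(p_i^2) - 1) / (n - 1) with
#' p_i the within-family codon proportions; families with F <= 0 or n < 2
#' are treated as missing. F-bar_k averages F over the families of
#' degeneracy k; for the standard code
#' ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 (the leading 2 counts Met and Trp;
#' the generalization uses the code's family counts per class). A missing
#' F-bar_3 is imputed as (F-bar_2 + F-bar_4)/2; the result is capped at the
#' number of sense codons (61). NA when F-bar_2, F-bar_4 or F-bar_6 is
#' undefined. Range 20 (one codon per amino acid) to 61 (uniform usage).
#'
#' @param counts named codon count vector.
#' @param code a [genetic_code()].
#' @return list with `enc` (value or NA) and `fbar` (named numeric, mean
#'   homozygosity per degeneracy class).
#' @export
enc <- function(counts, code = genetic_code()) {
  if (any(counts < 0)) stop("negative codon count")
  fam_F <- numeric(0)
  fam_k <- integer(0)
  for (fam in code$families) {
    k <- length(fam)
    if (k < 2) next
    x <- counts[fam]
    x[is.na(x)] <- 0
    n <- sum(x)
    if (n < 2) { F <- NA_real_ } else {
      p <- x / n
      F <- (n * sum(p^2) - 1) / (n - 1)
      if (F <= 0) F <- NA_real_
    }
    fam_F <- c(fam_F, F)
    fam_k <- c(fam_k, k)
  }
  classes <- sort(unique(fam_k))
  fbar <- vapply(classes, function(k) {
    v <- fam_F[fam_k == k]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  names(fbar) <- as.character(classes)
  n_fam <- stats::setNames(vapply(classes, function(k) sum(fam_k == k),
                                  numeric(1)), as.character(classes))
  n_single <- sum(lengths(code$families) == 1)
  if (is.na(fbar["2"]) || is.na(fbar["4"]) ||
      ("6" %in% names(fbar) && is.na(fbar["6"])))
    return(list(enc = NA_real_, fbar = fbar))
  if ("3" %in% names(fbar) && is.na(fbar["3"]))
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  value <- n_single + sum(n_fam / fbar)
  value <- min(value, length(code$sense_codons))
  list(enc = value, fbar = fbar)
}

#' Expected ENc under mutation pressure alone
#'
#' The null curve for the ENc-GC3s plot: the ENc a gene would show if its
#' codon bias were caused only by its third-position G+C content s,
#' ENc(s) = 2 + s + 29 / (s^2 + (1 - s)^2). Genes lying well below this
#' curve indicate selection (or other factors) beyond mutation pressure.
#'
#' @param gc3s synonymous third-position G+C content, fraction in \[0, 1\]
#'   (vectorized).
#' @return expected ENc value(s).
#' @export
expected_enc <- function(gc3s) {
  if (any(gc3s < 0 | gc3s > 1, na.rm = TRUE))
    stop("gc3s must lie in [0, 1]")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Full per-gene codon usage profile
#'
#' Assembles everything the dataset-level analyses need: composition and
#' positional GC (percent scale), codon counts, RSCU, ENc with family
#' homozygosities, and the PR2 coordinates.
#'
#' @param cds a [validate_cds()] result.
#' @param code a [genetic_code()].
#' @param pr2_sites `"all"` or `"fourfold"` (see [base_composition()]).
#' @return object of class `codon_usage_profile`.
#' @export
codon_usage_profile <- function(cds, code = genetic_code(),
                                pr2_sites = c("all", "fourfold")) {
  pr2_sites <- match.arg(pr2_sites)
  comp <- base_composition(cds, code, pr2_sites)
  counts <- codon_counts(cds, code)
  e <- enc(counts, code)
  profile <- structure(
    c(list(id = cds$id, n_codons = length(cds$codons),
           n_excluded_ambiguous = cds$n_excluded_ambiguous,
           counts = counts, rscu = rscu(counts, code),
           enc = e$enc, fbar = e$fbar, pr2_sites = pr2_sites),
      comp),
    class = "codon_usage_profile")
  profile$pr2 <- pr2_point(profile)
  profile
}

#' PR2-bias coordinates of a gene
#'
#' Parity-rule-2 plot point: x = G3/(G3+C3) (GC bias) against
#' y = A3/(A3+T3) (AT bias) at third codon positions. (0.5, 0.5) means
#' A = T and G = C, i.e. no asymmetry from mutation or selection pressure;
#' a coordinate is NA when its denominator is zero.
#'
#' @param profile a [codon_usage_profile()] (or any list with a
#'   `third_counts` element).
#' @return named numeric vector `c(x, y)`.
#' @export
pr2_point <- function(profile) {
  tc <- profile$third_counts
  if (is.null(tc)) stop("profile lacks third-position counts")
  gcd <- tc[["G3"]] + tc[["C3"]]
  atd <- tc[["A3"]] + tc[["T3"]]
  c(x = if (gcd > 0) tc[["G3"]] / gcd else NA_real_,
    y = if (atd > 0) tc[["A3"]] / atd else NA_real_)
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 (mean percent G+C at codon positions 1
#' and 2) on GC3 (percent G+C at position 3) across genes. Under pure
#' mutation pressure all three positions track the same mutational bias and
#' the slope approaches 1; selection on positions 1-2 flattens it, so
#' 100 * slope is read as the relative contribution of mutation pressure
#' and 100 * (1 - slope) as that of selection.
#'
#' @param gc3,gc12 numeric vectors on the percent (0-100) scale, or `gc3` a
#'   data frame with `gc3` and `gc12` columns.
#' @return object of class `neutrality_result`: list with `slope`,
#'   `intercept`, `pearson_r`, `p_value` (two-sided, t distribution with
#'   n - 2 df), `n_genes`, `mutation_pct`, `selection_pct`.
#' @export
neutrality_regression <- function(gc3, gc12 = NULL) {
  if (is.data.frame(gc3)) { gc12 <- gc3$gc12; gc3 <- gc3$gc3 }
  keep <- is.finite(gc3) & is.finite(gc12)
  gc3 <- gc3[keep]; gc12 <- gc12[keep]
  n <- length(gc3)
  if (n < 3) stop("need at least 3 genes for the neutrality regression")
  if (stats::var(gc3) == 0) stop("GC3 has zero variance")
  fit <- stats::lm(gc12 ~ gc3)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (stats::var(gc12) == 0) {
    r <- 0; p <- 1
  } else {
    ct <- stats::cor.test(gc3, gc12)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(slope = slope, intercept = intercept, pearson_r = r,
                 p_value = p, n_genes = n,
                 mutation_pct = 100 * slope,
                 selection_pct = 100 * (1 - slope)),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf(
    "<neutrality_result> GC12 = %.4f * GC3 + %.2f  (r = %.3f, p = %.3g, n = %d)\n",
    x$slope, x$intercept, x$pearson_r, x$p_value, x$n_genes))
  cat(sprintf("  mutation pressure %.1f%% vs selection %.1f%%\n",
              x$mutation_pct, x$selection_pct))
  invisible(x)
}

#' Per-gene profile rows for a set of coding sequences
#'
#' @param cds_list list of [validate_cds()] results.
#' @param code a [genetic_code()].
#' @param pr2_sites see [base_composition()].
#' @return list with `profiles` (list of [codon_usage_profile()]) and
#'   `table` (one row per gene: composition, GC metrics, ENc, expected ENc
#'   and residual, PR2 coordinates).
#' @export
profile_dataset <- function(cds_list, code = genetic_code(),
                            pr2_sites = c("all", "fourfold")) {
  pr2_sites <- match.arg(pr2_sites)
  profiles <- lapply(cds_list, codon_usage_profile, code = code,
                     pr2_sites = pr2_sites)
  rows <- lapply(profiles, function(p) {
    exp_enc <- if (is.na(p$gc3s)) NA_real_ else expected_enc(p$gc3s / 100)
    data.frame(id = p$id, n_codons = p$n_codons,
               A = p$base_fractions[["A"]], T = p$base_fractions[["T"]],
               G = p$base_fractions[["G"]], C = p$base_fractions[["C"]],
               gc = p$gc, gc1 = p$gc1, gc2 = p$gc2, gc3 = p$gc3,
               gc12 = p$gc12, gc3s = p$gc3s, enc = p$enc,
               expected_enc = exp_enc,
               enc_residual = p$enc - exp_enc,
               pr2_x = p$pr2[["x"]], pr2_y = p$pr2[["y"]],
               stringsAsFactors = FALSE)
  })
  list(profiles = profiles, table = do.call(rbind, rows))
}

#' Dataset-level codon usage summary
#'
#' Mean and SD (n - 1 denominator) of GC and ENc over genes with defined
#' values, the pooled-dataset RSCU computed from summed codon counts, and
#' the counts of codons with pooled RSCU above/below the conventional
#' cutoffs. Genes with more than `max_excluded_frac` of their codons
#' excluded as ambiguous are dropped from the aggregates with a warning.
#'
#' @param profiles list of [codon_usage_profile()] objects.
#' @param code a [genetic_code()].
#' @param max_excluded_frac drop threshold on the excluded-codon fraction
#'   (default 0.10).
#' @return list with `n_genes`, `n_dropped`, `gc_mean`, `gc_sd`,
#'   `enc_mean`, `enc_sd`, `n_enc_na`, `pooled_rscu` (named vector),
#'   `n_rscu_gt1`, `n_rscu_lt1`, `n_rscu_lt0.7`, `n_rscu_gt1.5`.
#' @export
summarize_dataset <- function(profiles, code = genetic_code(),
                              max_excluded_frac = 0.10) {
  if (!length(profiles)) stop("empty profile list")
  excl_frac <- vapply(profiles, function(p) {
    p$n_excluded_ambiguous / (p$n_codons + p$n_excluded_ambiguous)
  }, numeric(1))
  drop <- excl_frac > max_excluded_frac
  if (any(drop)) {
    warning(sum(drop), " gene(s) dropped from aggregates (>",
            100 * max_excluded_frac, "% codons excluded as ambiguous)")
    profiles <- profiles[!drop]
    if (!length(profiles)) stop("all genes dropped from aggregates")
  }
  gc <- vapply(profiles, `[[`, numeric(1), "gc")
  enc_v <- vapply(profiles, `[[`, numeric(1), "enc")
  pooled <- Reduce(`+`, lapply(profiles, `[[`, "counts"))
  pooled_rscu <- rscu(pooled, code)
  ok <- !is.na(pooled_rscu)
  list(n_genes = length(profiles), n_dropped = sum(drop),
       gc_mean = mean(gc), gc_sd = stats::sd(gc),
       enc_mean = mean(enc_v, na.rm = TRUE),
       enc_sd = stats::sd(enc_v[!is.na(enc_v)]),
       n_enc_na = sum(is.na(enc_v)),
       pooled_rscu = pooled_rscu,
       n_rscu_gt1 = sum(pooled_rscu[ok] > 1),
       n_rscu_lt1 = sum(pooled_rscu[ok] < 1),
       `n_rscu_lt0.7` = sum(pooled_rscu[ok] < 0.7),
       `n_rscu_gt1.5` = sum(pooled_rscu[ok] > 1.5))
}
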