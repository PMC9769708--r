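AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate protein families with controlled divergence
#'
#' Each family gets an independent uniform-random consensus sequence; each
#' member is the consensus with i.i.d. substitutions at probability `q`, the
#' substituted residue drawn uniformly from the 19 alternatives. The
#' expected pairwise identity within a family is (1-q)^2 + q^2/19, between
#' families 1/20. Pure function of (params, seed).
#'
#' @param n_families number of families.
#' @param members_per_family members per family (>= 2).
#' @param length sequence length (>= 50).
#' @param q per-site substitution probability within a family.
#' @param seed integer RNG seed.
#' @return list with `records` (protein record table; ids `F<f>_M<m>`),
#'   `truth` (data frame `id`, `family`), `consensus` (character vector).
#' @export
gen_protein_families <- function(n_families, members_per_family, length,
                                 q, seed) {
  stopifnot(n_families >= 1, members_per_family >= 2, length >= 50,
            q >= 0, q <= 1)
  with_seed(seed, {
    recs <- list(); truth <- list(); consensus <- character(n_families)
    for (f in seq_len(n_families)) {
      cons <- sample(AA20, length, replace = TRUE)
      consensus[f] <- paste(cons, collapse = "")
      for (m in seq_len(members_per_family)) {
        res <- cons
        mut <- stats::runif(length) < q
        if (any(mut)) {
          res[mut] <- vapply(res[mut], function(a)
            sample(setdiff(AA20, a), 1), character(1))
        }
        id <- sprintf("F%d_M%d", f, m)
        recs[[id]] <- paste(res, collapse = "")
        truth[[id]] <- f
      }
    }
    list(
      records = data.frame(id = names(recs), description = "",
                           residues = unlist(recs, use.names = FALSE),
                           alphabet = "protein", stringsAsFactors = FALSE),
      truth = data.frame(id = names(truth),
                         family = sprintf("F%d", unlist(truth, use.names = FALSE)),
                         stringsAsFactors = FALSE),
      consensus = consensus
    )
  })
}

#' Generate coding sequences under a tunable mutation-selection mixture
#'
#' The generator's model of the neutrality-plot logic: per gene a
#' mutational G+C pressure m is drawn uniformly from `m_range`. Codon
#' positions 1 and 2 (the protein-constraint proxy) are G or C with
#' probability (1-w)*m + w*anchor -- a mixture of the gene's mutational
#' pressure and a selective optimum `anchor` weighted by the selection
#' strength w -- while position 3 tracks mutation alone (G/C with
#' probability m). G vs C and A vs T are equiprobable. Stop codons are
#' rejected and redrawn so every gene has exactly `codons_per_gene` sense
#' codons. The population regression of GC12 on GC3 then has expected
#' slope (1-w) (up to binomial attenuation of about 0.96 at 300 codons),
#' making the selection share of the neutrality analysis directly tunable.
#'
#' @param n_genes number of genes.
#' @param codons_per_gene codons per gene.
#' @param m_range length-2 vector (lo, hi), 0 <= lo < hi <= 1.
#' @param w selection weight in \[0, 1\].
#' @param anchor selective GC optimum for positions 1-2 (default 0.5).
#' @param seed integer RNG seed.
#' @param code a [genetic_code()] (stops to reject).
#' @return list with `cds` (list of `coding_sequence` objects; ids
#'   `gene<i>`) and `truth` (data frame `id`, `m`).
#' @export
gen_cds <- function(n_genes, codons_per_gene, m_range, w, anchor = 0.5,
                    seed = 1, code = genetic_code()) {
  stopifnot(n_genes >= 1, codons_per_gene >= 1,
            length(m_range) == 2, m_range[1] >= 0, m_range[2] <= 1,
            m_range[1] < m_range[2], w >= 0, w <= 1,
            anchor >= 0, anchor <= 1)
  with_seed(seed, {
    m_values <- stats::runif(n_genes, m_range[1], m_range[2])
    cds <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      m <- m_values[g]
      p12 <- (1 - w) * m + w * anchor
      L <- codons_per_gene
      draw <- function(k, p_gc) {
        gc <- stats::runif(k) < p_gc
        strong <- stats::runif(k) < 0.5
        ifelse(gc, ifelse(strong, "G", "C"), ifelse(strong, "A", "T"))
      }
      codons <- paste0(draw(L, p12), draw(L, p12), draw(L, m))
      repeat {
        bad <- codons %in% code$stops
        if (!any(bad)) break
        k <- sum(bad)
        codons[bad] <- paste0(draw(k, p12), draw(k, p12), draw(k, m))
      }
      cds[[g]] <- structure(
        list(id = sprintf("gene%d", g), codons = codons,
             genetic_code_id = code$id, n_excluded_ambiguous = 0L,
             terminal_stop_trimmed = FALSE),
        class = "coding_sequence")
    }
    list(cds = cds,
         truth = data.frame(id = sprintf("gene%d", seq_len(n_genes)),
                            m = m_values, stringsAsFactors = FALSE))
  })
}

#' Plant motif strings into a motif-free random backbone
#'
#' Builds a random protein backbone, repair-samples it until it contains no
#' match of any pattern in `motifs` (matched stretches are overwritten with
#' glutamine, which no default pattern requires, and the scan repeats until
#' clean), then copies each plant string at its stated 0-based position.
#' The truth table lists each plant so motif-scanner round trips can be
#' checked exactly.
#'
#' @param backbone_length backbone length in residues.
#' @param plants data frame with columns `seq` (motif string) and `start`
#'   (0-based position); plants must be in bounds and non-overlapping.
#' @param seed integer RNG seed.
#' @param motifs a [motif_set()] the backbone must avoid
#'   (default [default_motif_set()]).
#' @param id record id (default `"planted"`).
#' @return list with `record` (one-row protein record table) and `truth`
#'   (data frame `seq`, `start`, `end` half-open).
#' @export
plant_motifs <- function(backbone_length, plants, seed,
                         motifs = default_motif_set(), id = "planted") {
  plants <- as.data.frame(plants)
  if (nrow(plants)) {
    stopifnot(all(c("seq", "start") %in% names(plants)))
    ends <- plants$start + nchar(plants$seq)
    if (any(plants$start < 0) || any(ends > backbone_length))
      stop("plant out of bounds")
    ord <- order(plants$start)
    if (nrow(plants) > 1 &&
        any(plants$start[ord][-1] < ends[ord][-nrow(plants)]))
      stop("overlapping plants")
  }
  backbone <- with_seed(seed, {
    res <- sample(AA20, backbone_length, replace = TRUE)
    for (iter in 1:200) {
      s <- paste(res, collapse = "")
      hit <- FALSE
      for (i in seq_len(nrow(motifs))) {
        m <- gregexpr(motifs$pattern[i], s, perl = TRUE)[[1]]
        if (m[1] == -1) next
        hit <- TRUE
        for (j in seq_along(m)) {
          idx <- seq(as.integer(m[j]),
                     length.out = attr(m, "match.length")[j])
          res[idx] <- "Q"
        }
      }
      if (!hit) break
    }
    if (hit) stop("could not clear backbone of default motifs")
    res
  })
  truth <- data.frame(seq = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(plants))) {
    chars <- strsplit(plants$seq[i], "")[[1]]
    backbone[plants$start[i] + seq_along(chars)] <- chars
    truth <- rbind(truth, data.frame(
      seq = plants$seq[i], start = plants$start[i],
      end = plants$start[i] + length(chars), stringsAsFactors = FALSE))
  }
  list(record = data.frame(id = id, description = "synthetic planted-motif backbone",
                           residues = paste(backbone, collapse = ""),
                           alphabet = "protein", stringsAsFactors = FALSE),
       truth = truth)
}
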