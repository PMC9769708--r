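#' Pairwise alignment-identity distance matrix
#'
#' Distances for tree building: d(i,j) = 1 - (identical aligned residue
#' pairs / aligned columns) from the optimal Smith-Waterman local alignment
#' of i and j under `params`; pairs with no positive-scoring alignment
#' saturate at d = 1.
#'
#' @param records protein record table (>= 3 rows).
#' @param params a [scoring_params()].
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
distance_matrix_from_hits <- function(records, params = scoring_params()) {
  n <- nrow(records)
  if (n < 3) stop("need at least 3 records for a distance matrix")
  ids <- records$id
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  seqs <- Biostrings::AAStringSet(records$residues)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    aln <- Biostrings::pairwiseAlignment(
      seqs[j], Biostrings::AAString(records$residues[i]),
      type = "local", substitutionMatrix = params$matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    dij <- ifelse(Biostrings::score(aln) > 0, 1 - ident, 1)
    d[i, j] <- dij
    d[j, i] <- dij
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion neighbor joining with negative branch lengths
#' clamped to zero. Taxa are pre-sorted lexicographically so tie-breaking
#' in the agglomeration order is deterministic.
#'
#' @param dm symmetric non-negative matrix with zero diagonal and
#'   row/column names.
#' @return unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || is.null(rownames(dm)))
    stop("dm must be a named matrix")
  if (nrow(dm) < 3) stop("need at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(!is.finite(dm)) || any(dm < 0)) stop("distances must be finite and non-negative")
  ord <- order(rownames(dm))
  tree <- ape::nj(dm[ord, ord])
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Concordance between a tree and a cluster assignment
#'
#' A cluster is concordant with the tree when some single edge separates
#' exactly its members from all other leaves (i.e. the cluster is one side
#' of a bipartition). Singleton clusters are concordant by definition and
#' excluded from the fraction, which is computed over clusters of size >= 2.
#'
#' @param tree `ape::phylo` tree.
#' @param clusters a [extract_clusters()] result, or a named list of member
#'   id vectors.
#' @return list with `fraction` (NaN when no cluster has size >= 2) and
#'   `flags` (named logical, per cluster).
#' @export
cluster_concordance <- function(tree, clusters) {
  members <- if (inherits(clusters, "cluster_assignment")) clusters$clusters
             else clusters
  tips <- tree$tip.label
  missing <- setdiff(unlist(members), tips)
  if (length(missing))
    stop("cluster member(s) absent from tree: ", paste(missing, collapse = ", "))
  # every split of the unrooted tree appears as a clade for some rooting;
  # prop.part enumerates the clades of the current (arbitrary) rooting, and
  # we accept either side of each bipartition.
  parts <- ape::prop.part(tree)
  sides <- lapply(parts, function(i) tips[i])
  flags <- vapply(members, function(mem) {
    if (length(mem) <= 1) return(TRUE)
    if (length(mem) == length(tips)) return(FALSE)
    any(vapply(sides, function(s) {
      setequal(mem, s) || setequal(mem, setdiff(tips, s))
    }, logical(1)))
  }, logical(1))
  big <- lengths(members) >= 2
  list(fraction = if (any(big)) mean(flags[big]) else NaN, flags = flags)
}

#' Cross-tabulate Cap clusters against Rep groups
#'
#' Recombination screen: genomes are counted over the ids present in both
#' label maps; a Cap cluster whose members carry more than one distinct Rep
#' group is flagged as incongruent, which is the signature expected under
#' recombination between the two genes.
#'
#' @param cap_labels named character vector, genome id -> Cap cluster label.
#' @param rep_labels named character vector, genome id -> Rep group label.
#' @return object of class `rep_cap_crosstab`: list with `counts`
#'   (contingency table, Cap rows x Rep columns), `distinct` (named integer,
#'   distinct Rep groups per Cap cluster), `flagged` (named logical,
#'   distinct > 1), `n_shared`.
#' @export
rep_cap_crosstab <- function(cap_labels, rep_labels) {
  shared <- intersect(names(cap_labels), names(rep_labels))
  if (!length(shared)) stop("no genome ids shared between the two label maps")
  counts <- table(cap = cap_labels[shared], rep = rep_labels[shared])
  distinct <- apply(counts > 0, 1, sum)
  structure(list(counts = counts, distinct = distinct,
                 flagged = distinct > 1, n_shared = length(shared)),
            class = "rep_cap_crosstab")
}

#' @export
print.rep_cap_crosstab <- function(x, ...) {
  cat("<rep_cap_crosstab>", nrow(x$counts), "Cap clusters x",
      ncol(x$counts), "Rep groups over", x$n_shared, "genomes;",
      sum(x$flagged), "cluster(s) flagged incongruent\n")
  invisible(x)
}

#' Crosstab as a long table
#'
#' @param x a [rep_cap_crosstab()] result.
#' @return data frame with `cap_cluster`, `rep_group`, `count`,
#'   `distinct_rep_groups`, `flagged` (zero-count cells omitted).
#' @export
crosstab_table <- function(x) {
  df <- as.data.frame(x$counts, stringsAsFactors = FALSE)
  names(df) <- c("cap_cluster", "rep_group", "count")
  df <- df[df$count > 0, , drop = FALSE]
  df$distinct_rep_groups <- x$distinct[df$cap_cluster]
  df$flagged <- x$flagged[df$cap_cluster]
  df <- df[order(df$cap_cluster, df$rep_group), , drop = FALSE]
  rownames(df) <- NULL
  df
}
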