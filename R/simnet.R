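#' Scoring parameters for pairwise protein comparison
#'
#' Bundles the substitution matrix, affine gap penalties, and the
#' Karlin–Altschul parameters used to turn raw Smith–Waterman scores into
#' E-values via E = K * m * n * exp(-lambda * S), with m, n the raw
#' sequence lengths (no edge-effect correction).
#'
#' lambda/K defaults come from a small built-in table for supported
#' matrix/gap combinations and can be overridden. The ungapped rows carry
#' the classical Karlin–Altschul estimates. The gapped rows are deliberately
#' conservative (decay rate below the asymptotic simulation estimate):
#' unlike seeded BLAST, exact Smith–Waterman produces a scored local
#' alignment for every pair, and the finite-length random-score
#' distribution has a heavy right tail, so an exactly calibrated per-pair
#' E-value would let about 1% of unrelated pairs through any P = 1e-2
#' network threshold. The conservative decay keeps chance alignments
#' between unrelated ~300-residue proteins well above the threshold while
#' related pairs (scores an order of magnitude higher) remain maximally
#' significant; the absolute E-value scale is absorbed by the threshold
#' parameter.
#'
#' @param matrix substitution matrix name (default `"BLOSUM45"`).
#' @param gap_open,gap_extend positive affine gap penalties.
#' @param lambda,K Karlin–Altschul parameters; looked up when `NULL`.
#' @return object of class `scoring_params`.
#' @export
scoring_params <- function(matrix = "BLOSUM45", gap_open = 15, gap_extend = 2,
                           lambda = NULL, K = NULL) {
  stopifnot(gap_open > 0, gap_extend > 0)
  if (is.null(lambda) || is.null(K)) {
    ka <- ka_lookup(matrix, gap_open, gap_extend)
    if (is.null(lambda)) lambda <- ka$lambda
    if (is.null(K)) K <- ka$K
  }
  stopifnot(lambda > 0, K > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_params")
}

# built-in Karlin-Altschul table; ungapped rows are the classical values,
# gapped rows a conservative pair-statistics calibration (see scoring_params).
ka_lookup <- function(matrix, gap_open, gap_extend) {
  tab <- data.frame(
    matrix = c("BLOSUM45", "BLOSUM45", "BLOSUM62", "BLOSUM62"),
    gap_open = c(NA, 15, NA, 11),
    gap_extend = c(NA, 2, NA, 1),
    lambda = c(0.2291, 0.10, 0.3176, 0.13),
    K = c(0.0924, 0.05, 0.134, 0.05),
    stringsAsFactors = FALSE
  )
  hit <- tab$matrix == matrix & !is.na(tab$gap_open) &
    tab$gap_open == gap_open & tab$gap_extend == gap_extend
  if (any(hit)) return(as.list(tab[which(hit)[1], c("lambda", "K")]))
  ung <- tab$matrix == matrix & is.na(tab$gap_open)
  if (any(ung)) return(as.list(tab[which(ung)[1], c("lambda", "K")]))
  stop("no built-in Karlin-Altschul parameters for matrix '", matrix,
       "'; supply lambda and K explicitly")
}

#' Convert an E-value to the CLANS P-value
#'
#' P = 1 - exp(-E): the probability of at least one chance hit when the
#' expected number of chance hits is E (Poisson).
#'
#' @param evalue non-negative E-value(s).
#' @return P-value(s) in \[0, 1).
#' @export
evalue_to_pvalue <- function(evalue) {
  if (any(evalue < 0)) stop("evalue must be non-negative")
  -expm1(-evalue)
}

# attraction used by the force-directed layout: 0 at P = 1, saturating at 1
# for P <= 1e-200; linear in -log10 P with normalization constant 200.
attraction_from_pvalue <- function(pvalue, norm = 200) {
  pmin(1, -log10(pmax(pvalue, 1e-200)) / norm)
}

#' Score one pair of protein sequences
#'
#' Optimal Smith–Waterman local alignment under the configured substitution
#' matrix and affine gap penalties, with BLAST-style HSP statistics:
#' E = K * m * n * exp(-lambda * S) and P = 1 - exp(-E). Returns `NULL`
#' when no positive-scoring local alignment exists (no hit).
#'
#' @param a,b protein records (rows of a [read_fasta()] table).
#' @param params a [scoring_params()].
#' @return one-row data frame with `query_id`, `subject_id`, `raw_score`,
#'   `evalue`, `pvalue`, `attraction`, or `NULL` for no hit.
#' @export
score_pair <- function(a, b, params = scoring_params()) {
  for (r in list(a, b)) {
    if (!identical(r$alphabet, "protein"))
      stop("score_pair requires protein records")
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", r$residues))
      stop("record '", r$id, "' contains residues outside the protein alphabet")
  }
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
  if (s <= 0) return(NULL)
  hit_row(a$id, b$id, s, nchar(a$residues), nchar(b$residues), params)
}

hit_row <- function(qid, sid, score, m, n, params) {
  evalue <- params$K * m * n * exp(-params$lambda * score)
  pvalue <- evalue_to_pvalue(evalue)
  data.frame(query_id = qid, subject_id = sid, raw_score = score,
             evalue = evalue, pvalue = pvalue,
             attraction = attraction_from_pvalue(pvalue),
             stringsAsFactors = FALSE)
}

#' All-vs-all pairwise hits for a protein record table
#'
#' Runs [score_pair()] over every unordered pair, batched per subject for
#' speed. Pairs with no positive-scoring local alignment are omitted.
#'
#' @param records protein record table from [read_fasta()].
#' @param params a [scoring_params()].
#' @return hit data frame (possibly 0 rows) in [score_pair()] layout.
#' @export
all_pairwise_hits <- function(records, params = scoring_params()) {
  n <- nrow(records)
  out <- vector("list", max(0L, n - 1L))
  if (n >= 2L) {
    seqs <- Biostrings::AAStringSet(records$residues)
    lens <- nchar(records$residues)
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      sc <- Biostrings::pairwiseAlignment(
        seqs[j], Biostrings::AAString(records$residues[i]),
        type = "local", substitutionMatrix = params$matrix,
        gapOpening = params$gap_open, gapExtension = params$gap_extend,
        scoreOnly = TRUE)
      keep <- sc > 0
      if (any(keep)) {
        out[[i]] <- hit_row(records$id[i], records$id[j][keep], sc[keep],
                            lens[i], lens[j][keep], params)
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      raw_score = numeric(), evalue = numeric(),
                      pvalue = numeric(), attraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build a thresholded similarity network from pairwise hits
#'
#' Reciprocal hits for the same unordered pair are merged keeping the
#' smaller P-value; edges above the P-value threshold are dropped;
#' self-hits are ignored; isolated nodes are retained.
#'
#' @param hits hit data frame ([score_pair()] layout).
#' @param ids complete node id vector (every hit endpoint must be listed).
#' @param p_threshold edge-retention P-value cutoff (default 1e-2).
#' @return object of class `similarity_network`: list with `ids`, `edges`
#'   (data frame `a`, `b`, `raw_score`, `evalue`, `pvalue`, `attraction`
#'   with `a < b`), `p_threshold`.
#' @export
build_network <- function(hits, ids, p_threshold = 1e-2) {
  if (anyDuplicated(ids)) stop("duplicate node ids")
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), ids)
  if (length(unknown))
    stop("hit endpoint(s) not in node list: ", paste(unknown, collapse = ", "))
  edges <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(edges)) {
    key <- pair_key(edges$query_id, edges$subject_id)
    ord <- order(key, edges$pvalue)   # best (smallest) pvalue first per pair
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(key[ord]), , drop = FALSE]
    edges <- edges[edges$pvalue <= p_threshold, , drop = FALSE]
  }
  edges <- data.frame(
    a = pmin(edges$query_id, edges$subject_id),
    b = pmax(edges$query_id, edges$subject_id),
    raw_score = edges$raw_score, evalue = edges$evalue,
    pvalue = edges$pvalue, attraction = edges$attraction,
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(ids = ids, edges = edges, p_threshold = p_threshold),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("<similarity_network>", length(x$ids), "nodes,", nrow(x$edges),
      "edges (P <=", format(x$p_threshold), ")\n")
  invisible(x)
}

#' Force-directed layout of a similarity network
#'
#' CLANS-style embedding: per round each node is pulled along its edges
#' with force proportional to the edge attraction and pushed away from all
#' nodes by an inverse-square-distance repulsion; the per-round step is
#' capped. Deterministic for a fixed seed.
#'
#' @param net a [build_network()] result.
#' @param dims 2 or 3.
#' @param rounds number of update rounds (>= 1).
#' @param seed integer RNG seed for the initial coordinates.
#' @param gain step size multiplier (default 0.1).
#' @param max_step per-node per-round displacement cap (default 1).
#' @param repulsion repulsion strength (default 0.05).
#' @return object of class `layout_state`: list with `coords` (matrix,
#'   rownames = ids), `rounds_done`, `rng_seed`.
#' @export
layout_network <- function(net, dims = 2, rounds = 1000, seed = 1,
                           gain = 0.1, max_step = 1, repulsion = 0.05) {
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  stopifnot(rounds >= 1)
  n <- length(net$ids)
  coords <- with_seed(seed, matrix(stats::runif(n * dims, -1, 1), nrow = n))
  rownames(coords) <- net$ids
  ia <- match(net$edges$a, net$ids)
  ib <- match(net$edges$b, net$ids)
  att <- net$edges$attraction
  for (r in seq_len(rounds)) {
    force <- matrix(0, n, dims)
    # spring pull along edges
    if (length(ia)) {
      delta <- coords[ib, , drop = FALSE] - coords[ia, , drop = FALSE]
      pull <- delta * att
      force <- force + rowsum_pad(pull, ia, n) - rowsum_pad(pull, ib, n)
    }
    # pairwise inverse-square repulsion
    d2 <- as.matrix(stats::dist(coords))^2
    inv <- 1 / (d2 + 1e-6)
    diag(inv) <- 0
    for (k in seq_len(dims)) {
      dk <- outer(coords[, k], coords[, k], "-")
      force[, k] <- force[, k] + repulsion * rowSums(dk * inv)
    }
    step <- gain * force
    norm <- sqrt(rowSums(step^2))
    over <- norm > max_step
    if (any(over)) step[over, ] <- step[over, , drop = FALSE] * (max_step / norm[over])
    coords <- coords + step
  }
  structure(list(coords = coords, rounds_done = rounds, rng_seed = seed),
            class = "layout_state")
}

# rowsum over an index vector, padded to n rows (zero rows for absent nodes)
rowsum_pad <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Extract clusters from a similarity network
#'
#' Two methods are provided. `components` (default) takes the connected
#' components of the thresholded graph; it is parameter-free and
#' reproducible. `network_offset` then iteratively reassigns each node to
#' the cluster maximizing its average attraction to members, provided that
#' average exceeds `offset` times the global mean attraction, for at most
#' `max_rounds` or until stable (CLANS' network clustering option). In both
#' cases clusters smaller than `min_size` are routed to the unclustered
#' pool. Cluster labels are assigned by decreasing size (`cl1`, `cl2`, ...).
#'
#' @param net a [build_network()] result.
#' @param method `"components"` or `"network_offset"`.
#' @param min_size minimum cluster size (default 10).
#' @param max_rounds reassignment-round cap for `network_offset`
#'   (default 10000).
#' @param offset multiple of the global mean attraction a node's average
#'   attraction must exceed to join a cluster (default 1).
#' @return object of class `cluster_assignment`: list with `clusters`
#'   (named list of member id vectors), `unclustered` (id vector),
#'   `min_size`, `method`.
#' @export
extract_clusters <- function(net, method = c("components", "network_offset"),
                             min_size = 10, max_rounds = 10000, offset = 1.0) {
  method <- match.arg(method)
  stopifnot(min_size >= 1)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("a", "b"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = net$ids))
  comp <- igraph::components(g)
  membership <- comp$membership[net$ids]
  if (method == "network_offset" && nrow(net$edges)) {
    membership <- reassign_by_attraction(net, membership, offset, max_rounds)
  }
  finalize_clusters(net$ids, membership, min_size, method)
}

# iterative CLANS-style reassignment on the attraction matrix; nodes whose
# best average attraction does not exceed offset * global mean drop out.
# scan order and tie-breaks fixed (lexicographic ids, lowest cluster id).
reassign_by_attraction <- function(net, membership, offset, max_rounds) {
  ids <- net$ids
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  ia <- match(net$edges$a, ids); ib <- match(net$edges$b, ids)
  A[cbind(ia, ib)] <- net$edges$attraction
  A[cbind(ib, ia)] <- net$edges$attraction
  global_mean <- if (n > 1) sum(A) / (n * (n - 1)) else 0
  memb <- membership
  scan <- order(ids)
  for (round in seq_len(max_rounds)) {
    changed <- FALSE
    for (v in scan) {
      labs <- sort(unique(memb[!is.na(memb)]))
      if (!length(labs)) break
      avg <- vapply(labs, function(cl) {
        members <- which(memb == cl & seq_len(n) != v)
        if (!length(members)) return(NA_real_)
        mean(A[v, members])
      }, numeric(1))
      if (all(is.na(avg))) next
      best <- labs[which.max(avg)]          # which.max: first max, lowest id
      if (!is.na(avg[match(best, labs)]) &&
          avg[match(best, labs)] > offset * global_mean) {
        if (is.na(memb[v]) || memb[v] != best) { memb[v] <- best; changed <- TRUE }
      } else if (!is.na(memb[v])) {
        memb[v] <- NA; changed <- TRUE
      }
    }
    if (!changed) break
  }
  memb
}

finalize_clusters <- function(ids, membership, min_size, method) {
  unclustered <- ids[is.na(membership)]
  memb <- membership[!is.na(membership)]
  groups <- split(ids[!is.na(membership)], memb)
  sizes <- lengths(groups)
  small <- sizes < min_size
  unclustered <- c(unclustered, unlist(groups[small], use.names = FALSE))
  groups <- groups[!small]
  groups <- groups[order(-lengths(groups), vapply(groups, min, character(1)))]
  names(groups) <- if (length(groups)) paste0("cl", seq_along(groups)) else character()
  structure(list(clusters = groups, unclustered = sort(unclustered),
                 min_size = min_size, method = method),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment>", length(x$clusters), "clusters (min size",
      x$min_size, "),", length(x$unclustered), "unclustered;",
      "method:", x$method, "\n")
  invisible(x)
}

#' Cluster assignment as a per-id label table
#'
#' @param assignment a [extract_clusters()] result.
#' @return data frame with columns `id`, `cluster` (`"unclustered"` for the
#'   pool), `method`.
#' @export
cluster_table <- function(assignment) {
  labs <- c(rep(names(assignment$clusters), lengths(assignment$clusters)),
            rep("unclustered", length(assignment$unclustered)))
  ids <- c(unlist(assignment$clusters, use.names = FALSE),
           assignment$unclustered)
  out <- data.frame(id = ids, cluster = labs, method = assignment$method,
                    stringsAsFactors = FALSE)
  out[order(out$id), , drop = FALSE]
}
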