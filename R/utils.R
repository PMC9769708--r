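#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a computed partition and a reference
#' labeling, e.g. cluster assignments against planted family truth. 1 means
#' identical partitions, 0 is the expectation under random labeling.
#'
#' @param a,b label vectors of equal length (any atomic type; compared as
#'   factors). Names are ignored; elements are matched by position.
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (sij - expected) / (maxidx - expected)
}

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# canonical unordered pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
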