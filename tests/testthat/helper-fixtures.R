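# shared in-code fixtures

protein_record <- function(id, residues) {
  list(id = id, residues = residues, alphabet = "protein")
}

nt_record <- function(id, residues) {
  list(id = id, residues = residues, alphabet = "nucleotide")
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# hand-rolled OLS slope oracle: cov/var quotient
slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# brute-force least-squares tree fit over all 3 unrooted 4-taxon topologies:
# for topology ((a,b),(c,d)) with branch lengths la, lb, lc, ld and internal
# m, path lengths are linear in the 5 branch lengths; solve by lm.
ls_fit_quartet <- function(dm) {
  taxa <- rownames(dm)
  topos <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  best <- NULL
  for (tp in topos) {
    a <- tp[1]; b <- tp[2]; c <- tp[3]; d <- tp[4]
    # rows: pairs ab, ac, ad, bc, bd, cd; cols: la lb lc ld m
    X <- rbind(c(1, 1, 0, 0, 0),
               c(1, 0, 1, 0, 1),
               c(1, 0, 0, 1, 1),
               c(0, 1, 1, 0, 1),
               c(0, 1, 0, 1, 1),
               c(0, 0, 1, 1, 1))
    y <- c(dm[a, b], dm[a, c], dm[a, d], dm[b, c], dm[b, d], dm[c, d])
    beta <- solve(crossprod(X), crossprod(X, y))
    rss <- sum((y - X %*% beta)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, split = list(sort(taxa[c(a, b)]), sort(taxa[c(c, d)])),
                   lengths = as.numeric(beta))
    }
  }
  best
}

# path-length (patristic) matrix of a phylo tree, via ape
patristic <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}

# build an additive distance matrix from a tree
additive_dm <- function(newick) {
  patristic(ape::read.tree(text = newick))
}
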