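#' Genetic code with synonymous-family structure
#'
#' Wraps an NCBI genetic code table together with the degeneracy bookkeeping
#' the codon-usage statistics need: the synonymous families (codons grouped
#' by encoded amino acid) and the per-codon degeneracy class k (number of
#' synonymous codons for that amino acid).
#'
#' Under the standard code (id 1) there are 61 sense codons and 3 stops; the
#' 18 degenerate amino acids split into 9 two-fold, 1 three-fold (Ile),
#' 5 four-fold and 3 six-fold (Leu, Ser, Arg) families, plus the Met and Trp
#' singletons. Six-fold families are kept whole, not split 2+4.
#'
#' @param id NCBI genetic code identifier (integer, default 1 = standard).
#' @return object of class `genetic_code`: list with `id`, `table` (named
#'   64-codon character vector, `*` = stop), `stops`, `sense_codons`,
#'   `families` (list of codon vectors named by amino acid) and `degeneracy`
#'   (named integer, per amino acid).
#' @examples
#' gc <- genetic_code()
#' length(gc$sense_codons)  # 61
#' gc$degeneracy[["L"]]     # 6
#' @export
genetic_code <- function(id = 1L) {
  tab <- Biostrings::getGeneticCode(as.character(id))
  stops <- names(tab)[tab == "*"]
  sense <- names(tab)[tab != "*"]
  families <- split(sense, tab[sense])
  structure(
    list(
      id = as.integer(id),
      table = tab,
      stops = stops,
      sense_codons = sense,
      families = families,
      degeneracy = lengths(families)
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> id", x$id, "-", length(x$sense_codons), "sense codons,",
      length(x$stops), "stops\n")
  invisible(x)
}

# per-codon degeneracy (named integer over sense codons)
codon_degeneracy <- function(code) {
  aa <- code$table[code$sense_codons]
  stats::setNames(code$degeneracy[aa], code$sense_codons)
}
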