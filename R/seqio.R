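#' Read a protein or nucleotide FASTA file into a record table
#'
#' Records are returned as a data frame, one row per FASTA entry in file
#' order. The id is the first whitespace-delimited token of the header, the
#' remainder becomes the description. Residues are upper-cased; for
#' nucleotide input U is mapped to T.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return data frame with columns `id`, `description`, `residues`,
#'   `alphabet`.
#' @details Protein residues must come from the 20 amino acids plus X;
#'   nucleotide residues from A,C,G,T,N and the IUPAC ambiguity codes.
#'   Duplicate ids, out-of-alphabet residues, empty sequences and empty
#'   files are errors.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), function(x) x[1], character(1))
  if (anyNA(ids) || any(!nzchar(ids))) stop("FASTA entry with empty id in ", path)
  desc <- sub("^\\S+\\s*", "", headers)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence ids: ", paste(dup, collapse = ", "))
  residues <- toupper(as.character(set))
  if (alphabet == "nucleotide") residues <- gsub("U", "T", residues, fixed = TRUE)
  if (any(!nzchar(residues))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(residues)], collapse = ", "))
  }
  allowed <- if (alphabet == "protein") "ACDEFGHIKLMNPQRSTVWYX"
             else "ACGTNRYSWKMBDHV"
  bad <- regmatches(residues, regexpr(sprintf("[^%s]", allowed), residues))
  has_bad <- grepl(sprintf("[^%s]", allowed), residues)
  if (any(has_bad)) {
    i <- which(has_bad)[1]
    stop(sprintf("record '%s' contains character '%s' outside the %s alphabet",
                 ids[i], bad[1], alphabet))
  }
  data.frame(id = ids, description = unname(desc),
             residues = unname(residues), alphabet = alphabet,
             stringsAsFactors = FALSE)
}

#' Write a record table to FASTA
#'
#' Inverse of [read_fasta()]: ids and residues round-trip exactly.
#'
#' @param records data frame with `id`, `residues` and optionally
#'   `description` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Validate a nucleotide record as a coding sequence
#'
#' Splits a CDS into codons and applies the cleaning policy used throughout
#' the codon-usage suite: the length must be divisible by 3; a single
#' terminal stop codon is trimmed (and flagged); codons containing non-ACGT
#' characters are excluded and counted. Internal stop codons are an error
#' under the `strict` policy and are excluded like ambiguous codons under
#' `lenient`.
#'
#' @param record one row of a [read_fasta()] table (or any list with `id`
#'   and `residues`), nucleotide alphabet.
#' @param code a [genetic_code()].
#' @param policy `"strict"` (default) or `"lenient"`.
#' @return object of class `coding_sequence`: list with `id`, `codons`
#'   (character vector of sense codons), `genetic_code_id`,
#'   `n_excluded_ambiguous`, `terminal_stop_trimmed`.
#' @export
validate_cds <- function(record, code = genetic_code(),
                         policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  res <- record$residues
  id <- record$id
  if (is.null(res) || is.null(id)) stop("record must have id and residues")
  n <- nchar(res)
  if (n == 0L) stop("empty sequence for '", id, "'")
  if (n %% 3L != 0L)
    stop(sprintf("CDS length %d of '%s' is not divisible by 3", n, id))
  codons <- substring(res, seq(1L, n, 3L), seq(3L, n, 3L))
  terminal_stop <- length(codons) > 0L && codons[length(codons)] %in% code$stops
  if (terminal_stop) codons <- codons[-length(codons)]
  ambiguous <- grepl("[^ACGT]", codons)
  n_excluded <- sum(ambiguous)
  codons <- codons[!ambiguous]
  internal_stop <- codons %in% code$stops
  if (any(internal_stop)) {
    if (policy == "strict") {
      stop(sprintf("internal stop codon in '%s' at codon %d", id,
                   which(internal_stop)[1]))
    }
    n_excluded <- n_excluded + sum(internal_stop)
    codons <- codons[!internal_stop]
  }
  if (length(codons) == 0L)
    stop("no usable codons remain in '", id, "'")
  structure(
    list(id = id, codons = codons, genetic_code_id = code$id,
         n_excluded_ambiguous = n_excluded,
         terminal_stop_trimmed = terminal_stop),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("<coding_sequence>", x$id, "-", length(x$codons), "codons",
      if (x$terminal_stop_trimmed) "(terminal stop trimmed)" else "", "\n")
  invisible(x)
}

#' Write result tables and trees to an output directory
#'
#' Tables go out as tab-separated files with a header row; trees as Newick.
#' Returns a manifest listing every file written with its row count (NA for
#' trees).
#'
#' @param tables named list of data frames (may be empty).
#' @param trees named list of Newick strings or `ape::phylo` objects
#'   (may be empty).
#' @param outdir output directory, created if needed.
#' @return data frame manifest with columns `file`, `type`, `rows`.
#' @export
write_outputs <- function(tables = list(), trees = list(), outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  manifest <- data.frame(file = character(), type = character(),
                         rows = integer(), stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    f <- file.path(outdir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- rbind(manifest, data.frame(
      file = f, type = "table", rows = nrow(tables[[nm]]),
      stringsAsFactors = FALSE))
  }
  for (nm in names(trees)) {
    f <- file.path(outdir, paste0(nm, ".nwk"))
    tr <- trees[[nm]]
    if (inherits(tr, "phylo")) ape::write.tree(tr, file = f)
    else writeLines(as.character(tr), f)
    manifest <- rbind(manifest, data.frame(
      file = f, type = "tree", rows = NA_integer_, stringsAsFactors = FALSE))
  }
  manifest
}
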