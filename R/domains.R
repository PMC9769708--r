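#' Default Rep-protein motif set
#'
#' Motif-signature stand-ins for the two canonical Rep domains of CRESS-DNA
#' viruses: the HUH endonuclease (Viral_Rep) is represented by rolling-circle
#' replication motifs I-III restricted to the N-terminal half, and the
#' superfamily-3 helicase (P-loop NTPase) by the Walker A and Walker B
#' nucleotide-binding motifs in the C-terminal half. Patterns are
#' position-independent residue-class regular expressions and are plain
#' configuration data: edit or replace them freely via [motif_set()].
#'
#' @return data frame with columns `name`, `pattern`, `region`
#'   (one of `"N-half"`, `"C-half"`, `"any"`).
#' @export
default_motif_set <- function() {
  motif_set(data.frame(
    name = c("huh_I", "huh_II", "huh_III", "walker_A", "walker_B"),
    pattern = c("[FYWLIV]T[LIVF]", "H[ILVMFYWAC]H", "Y..[KR]",
                "[GA]....GK[ST]", "[ILVMFACW]{3}[DE][DE]"),
    region = c("N-half", "N-half", "N-half", "C-half", "C-half"),
    stringsAsFactors = FALSE
  ))
}

#' Validate a motif set
#'
#' @param motifs data frame with `name`, `pattern`, `region` columns.
#' @return the validated data frame, classed `motif_set`.
#' @export
motif_set <- function(motifs) {
  stopifnot(is.data.frame(motifs),
            all(c("name", "pattern", "region") %in% names(motifs)))
  if (anyDuplicated(motifs$name))
    stop("duplicate motif names: ",
         paste(unique(motifs$name[duplicated(motifs$name)]), collapse = ", "))
  if (!all(motifs$region %in% c("N-half", "C-half", "any")))
    stop("motif region must be one of N-half, C-half, any")
  for (i in seq_len(nrow(motifs))) {
    ok <- tryCatch({ grepl(motifs$pattern[i], "A", perl = TRUE); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("motif pattern does not compile: ", motifs$pattern[i])
  }
  class(motifs) <- c("motif_set", "data.frame")
  motifs
}

#' Scan a Rep protein for domain motifs and call domain completeness
#'
#' Reports all non-overlapping leftmost matches of each motif within its
#' region constraint (regions split at the sequence midpoint), then derives
#' per-domain completeness: the Viral_Rep (HUH endonuclease) domain is
#' `complete` when at least `huh_min_motifs` of the three HUH motifs are
#' present, `incomplete` when exactly one is; the P-loop NTPase domain is
#' `complete` when Walker A and Walker B are both present with a Walker B
#' start within `walker_max_gap` residues after a Walker A end, `incomplete`
#' when only one motif (or a too-distant pair) is found. When both domains
#' are present and the gap between them exceeds `insert_gap` residues an
#' inserted additional domain is suspected and flagged.
#'
#' @param protein protein record (row of a [read_fasta()] table).
#' @param motifs a [motif_set()] (default [default_motif_set()]).
#' @param huh_min_motifs HUH motifs required for a complete Viral_Rep call
#'   (default 2 of 3).
#' @param walker_max_gap maximum Walker A end to Walker B start distance for
#'   a complete P-loop call (default 120 residues).
#' @param insert_gap Viral_Rep end to P-loop start distance above which an
#'   insert is suspected (default 150 residues).
#' @return object of class `domain_annotation`: list with `id`, `hits`
#'   (data frame `motif`, `start` 0-based, `end` half-open),
#'   `viral_rep_status`, `ploop_status` (each `complete`/`incomplete`/
#'   `absent`) and `insert_suspected`.
#' @export
scan_motifs <- function(protein, motifs = default_motif_set(),
                        huh_min_motifs = 2, walker_max_gap = 120,
                        insert_gap = 150) {
  seq <- protein$residues
  L <- nchar(seq)
  if (L < 30) stop("sequence '", protein$id, "' shorter than 30 residues")
  mid <- floor(L / 2)
  hits <- lapply(seq_len(nrow(motifs)), function(i) {
    m <- gregexpr(motifs$pattern[i], seq, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    start0 <- as.integer(m) - 1L                       # 0-based
    end0 <- start0 + attr(m, "match.length")           # half-open
    keep <- switch(motifs$region[i],
                   "N-half" = end0 <= mid,
                   "C-half" = start0 >= mid,
                   "any" = rep(TRUE, length(start0)))
    if (!any(keep)) return(NULL)
    data.frame(motif = motifs$name[i], start = start0[keep], end = end0[keep],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, c(list(data.frame(motif = character(),
                                           start = integer(), end = integer(),
                                           stringsAsFactors = FALSE)), hits))
  huh_names <- c("huh_I", "huh_II", "huh_III")
  huh_present <- intersect(huh_names, hits$motif)
  viral_rep_status <-
    if (length(huh_present) >= huh_min_motifs) "complete"
    else if (length(huh_present) >= 1) "incomplete"
    else "absent"
  a_ends <- hits$end[hits$motif == "walker_A"]
  b_starts <- hits$start[hits$motif == "walker_B"]
  paired <- length(a_ends) && length(b_starts) &&
    any(outer(b_starts, a_ends, "-") >= 0 &
        outer(b_starts, a_ends, "-") <= walker_max_gap)
  ploop_status <-
    if (paired) "complete"
    else if (length(a_ends) || length(b_starts)) "incomplete"
    else "absent"
  insert_suspected <- FALSE
  if (viral_rep_status != "absent" && ploop_status != "absent") {
    vr_end <- max(hits$end[hits$motif %in% huh_names])
    pl_start <- min(hits$start[hits$motif %in% c("walker_A", "walker_B")])
    insert_suspected <- (pl_start - vr_end) > insert_gap
  }
  structure(list(id = protein$id, hits = hits,
                 viral_rep_status = viral_rep_status,
                 ploop_status = ploop_status,
                 insert_suspected = insert_suspected),
            class = "domain_annotation")
}

#' Classify the domain organization of an annotated Rep protein
#'
#' Pure function of the two completeness statuses:
#' both complete -> `both`; Viral_Rep present (complete or incomplete) with
#' P-loop absent -> `viral_rep_only`; the converse -> `ploop_only`; one
#' complete and one incomplete -> `both_one_incomplete`; both incomplete ->
#' `both_one_incomplete`; both absent -> `none`.
#'
#' @param annotation a [scan_motifs()] result.
#' @return object of class `organization_class`: list with `category` and
#'   `candidate_groups` (from [map_candidate_groups()]).
#' @export
classify_organization <- function(annotation) {
  vr <- annotation$viral_rep_status
  pl <- annotation$ploop_status
  stopifnot(vr %in% c("complete", "incomplete", "absent"),
            pl %in% c("complete", "incomplete", "absent"))
  category <-
    if (vr == "absent" && pl == "absent") "none"
    else if (pl == "absent") "viral_rep_only"
    else if (vr == "absent") "ploop_only"
    else if (vr == "complete" && pl == "complete") "both"
    else "both_one_incomplete"
  structure(list(category = category,
                 candidate_groups = map_candidate_groups(category)),
            class = "organization_class")
}

#' Map a domain organization category to candidate virus groups
#'
#' Encodes the observed association between Rep domain organization and the
#' CRESS-DNA group scheme: viruses with both Viral_Rep and P-loop NTPase
#' domains fall in CRESSV1-3, Circoviridae(-related) and Nanoviridae;
#' Viral_Rep-only viruses in CRESSV4/CRESSV5; P-loop-only in the
#' pCRESS-related group; viruses lacking both domains in Smacoviridae(-related)
#' and the outgroups; a complete + incomplete combination points at the
#' CRESSV2-related group or Nanoviridae.
#'
#' @param category one of `both`, `viral_rep_only`, `ploop_only`,
#'   `both_one_incomplete`, `none`.
#' @return character vector of candidate group labels.
#' @export
map_candidate_groups <- function(category) {
  switch(category,
    both = c("CRESSV1", "CRESSV2", "CRESSV3", "Circoviridae",
             "Circoviridae-related", "Nanoviridae"),
    viral_rep_only = c("CRESSV4", "CRESSV5"),
    ploop_only = "pCRESS-related",
    none = c("Smacoviridae", "Smacoviridae-related",
             "outgroup1", "outgroup2", "outgroup3", "outgroup4"),
    both_one_incomplete = c("CRESSV2-related", "Nanoviridae"),
    stop("unknown organization category: ", category)
  )
}

#' Domain-annotate a whole protein table
#'
#' Convenience wrapper running [scan_motifs()] and
#' [classify_organization()] over every record.
#'
#' @param records protein record table.
#' @param motifs a [motif_set()].
#' @param ... passed on to [scan_motifs()].
#' @return data frame with one row per record: `id`, `viral_rep_status`,
#'   `ploop_status`, `category`, `candidate_groups`
#'   (comma-separated), `insert_suspected`, `n_hits`.
#' @export
annotate_domains <- function(records, motifs = default_motif_set(), ...) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    ann <- scan_motifs(records[i, ], motifs, ...)
    org <- classify_organization(ann)
    data.frame(id = ann$id,
               viral_rep_status = ann$viral_rep_status,
               ploop_status = ann$ploop_status,
               category = org$category,
               candidate_groups = paste(org$candidate_groups, collapse = ","),
               insert_suspected = ann$insert_suspected,
               n_hits = nrow(ann$hits),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
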