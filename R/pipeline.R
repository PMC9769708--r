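#' Assemble and validate a pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Input paths are
#' checked up front so a missing file fails before any stage runs; all
#' seeds are explicit.
#'
#' @param rep_protein,cap_protein paths to protein FASTA files.
#' @param rep_cds,cap_cds paths to nucleotide CDS FASTA files.
#' @param outdir output directory.
#' @param p_threshold network P-value cutoff (default 1e-2).
#' @param min_size minimum cluster size (default 10).
#' @param cluster_method `"components"` or `"network_offset"`.
#' @param layout_rounds force-directed layout rounds (default 1000;
#'   0 skips the layout stage).
#' @param layout_dims 2 or 3.
#' @param seed integer seed used for the layout.
#' @param genetic_code_id NCBI genetic code id (default 1).
#' @param cds_policy `"strict"` or `"lenient"`.
#' @param pr2_sites `"all"` or `"fourfold"`.
#' @param motifs a [motif_set()] (default [default_motif_set()]).
#' @param params a [scoring_params()].
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(rep_protein, cap_protein, rep_cds, cap_cds,
                            outdir, p_threshold = 1e-2, min_size = 10,
                            cluster_method = "components",
                            layout_rounds = 1000, layout_dims = 2,
                            seed = 1, genetic_code_id = 1,
                            cds_policy = "strict", pr2_sites = "all",
                            motifs = default_motif_set(),
                            params = scoring_params()) {
  paths <- c(rep_protein = rep_protein, cap_protein = cap_protein,
             rep_cds = rep_cds, cap_cds = cap_cds)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input path(s) not found: ", paste(missing, collapse = ", "))
  structure(list(
    rep_protein = rep_protein, cap_protein = cap_protein,
    rep_cds = rep_cds, cap_cds = cap_cds, outdir = outdir,
    p_threshold = p_threshold, min_size = min_size,
    cluster_method = cluster_method, layout_rounds = layout_rounds,
    layout_dims = layout_dims, seed = seed,
    genetic_code_id = genetic_code_id, cds_policy = cds_policy,
    pr2_sites = pr2_sites, motifs = motifs, params = params),
    class = "pipeline_config")
}

#' Run the full Rep/Cap evolution analysis
#'
#' Executes clustering (Rep and Cap similarity networks), Rep domain
#' annotation, the neighbor-joining concordance check, the Rep-Cap cluster
#' cross-tabulation, and the codon usage suite on both genes, writing every
#' stage's tables (and the Rep tree) to the output directory together with
#' a run log. Identical config and seeds give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return manifest data frame from [write_outputs()] (with the log file
#'   appended).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(sprintf("cressevolve run_pipeline  seed=%d  p_threshold=%g  min_size=%d",
                         config$seed, config$p_threshold, config$min_size))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  rep_prot <- stage("read", read_fasta(config$rep_protein, "protein"))
  cap_prot <- stage("read", read_fasta(config$cap_protein, "protein"))
  code <- genetic_code(config$genetic_code_id)
  rep_cds <- stage("read", {
    recs <- read_fasta(config$rep_cds, "nucleotide")
    lapply(seq_len(nrow(recs)), function(i)
      validate_cds(recs[i, ], code, config$cds_policy))
  })
  cap_cds <- stage("read", {
    recs <- read_fasta(config$cap_cds, "nucleotide")
    lapply(seq_len(nrow(recs)), function(i)
      validate_cds(recs[i, ], code, config$cds_policy))
  })

  cluster_one <- function(records) {
    hits <- all_pairwise_hits(records, config$params)
    net <- build_network(hits, records$id, config$p_threshold)
    list(net = net, hits = hits,
         clusters = extract_clusters(net, config$cluster_method,
                                     min_size = config$min_size))
  }
  repc <- stage("cluster", cluster_one(rep_prot))
  capc <- stage("cluster", cluster_one(cap_prot))
  log_lines <- c(log_lines,
                 sprintf("rep: %d sequences, %d edges, %d clusters",
                         nrow(rep_prot), nrow(repc$net$edges),
                         length(repc$clusters$clusters)),
                 sprintf("cap: %d sequences, %d edges, %d clusters",
                         nrow(cap_prot), nrow(capc$net$edges),
                         length(capc$clusters$clusters)))

  tables <- list(
    rep_hits = repc$hits, cap_hits = capc$hits,
    rep_clusters = cluster_table(repc$clusters),
    cap_clusters = cluster_table(capc$clusters))

  if (config$layout_rounds > 0) {
    lay <- stage("layout", layout_network(repc$net, config$layout_dims,
                                          config$layout_rounds, config$seed))
    coords <- as.data.frame(lay$coords)
    names(coords) <- c("x", "y", "z")[seq_len(ncol(coords))]
    tables$rep_layout <- cbind(id = rownames(lay$coords), coords,
                               stringsAsFactors = FALSE)
  }

  tables$rep_domains <- stage("domains",
                              annotate_domains(rep_prot, config$motifs))

  trees <- list()
  if (nrow(rep_prot) >= 3) {
    dm <- stage("tree", distance_matrix_from_hits(rep_prot, config$params))
    tree <- stage("tree", nj_tree(dm))
    conc <- stage("tree", cluster_concordance(tree, repc$clusters))
    trees$rep_nj <- tree
    tables$rep_concordance <- data.frame(
      cluster = names(conc$flags), concordant = unname(conc$flags),
      stringsAsFactors = FALSE)
    log_lines <- c(log_lines, sprintf("rep tree concordance: %.3f",
                                      conc$fraction))
  }

  cap_labels <- with(tables$cap_clusters,
                     stats::setNames(cluster, id))
  rep_labels <- with(tables$rep_clusters,
                     stats::setNames(cluster, id))
  shared <- intersect(names(cap_labels), names(rep_labels))
  if (length(shared)) {
    xt <- stage("crosstab", rep_cap_crosstab(cap_labels, rep_labels))
    tables$rep_cap_crosstab <- crosstab_table(xt)
  }

  codon_one <- function(cds_list, prefix) {
    ds <- profile_dataset(cds_list, code, config$pr2_sites)
    neut <- neutrality_regression(ds$table)
    summ <- summarize_dataset(ds$profiles, code)
    out <- list()
    out[[paste0(prefix, "_codon_profile")]] <- ds$table
    out[[paste0(prefix, "_rscu")]] <- data.frame(
      codon = names(summ$pooled_rscu),
      amino_acid = code$table[names(summ$pooled_rscu)],
      rscu = unname(summ$pooled_rscu), stringsAsFactors = FALSE)
    out[[paste0(prefix, "_summary")]] <- data.frame(
      metric = c("n_genes", "gc_mean", "gc_sd", "enc_mean", "enc_sd",
                 "n_enc_na", "n_rscu_gt1", "n_rscu_lt1",
                 "neutrality_slope", "neutrality_intercept",
                 "neutrality_r", "mutation_pct", "selection_pct"),
      value = c(summ$n_genes, summ$gc_mean, summ$gc_sd, summ$enc_mean,
                summ$enc_sd, summ$n_enc_na, summ$n_rscu_gt1,
                summ$n_rscu_lt1, neut$slope, neut$intercept,
                neut$pearson_r, neut$mutation_pct, neut$selection_pct),
      stringsAsFactors = FALSE)
    out
  }
  tables <- c(tables, stage("codon", codon_one(rep_cds, "rep")),
              stage("codon", codon_one(cap_cds, "cap")))

  manifest <- stage("write", write_outputs(tables, trees, config$outdir))
  log_file <- file.path(config$outdir, "run.log")
  writeLines(c(log_lines, sprintf("files written: %d", nrow(manifest))),
             log_file)
  rbind(manifest, data.frame(file = log_file, type = "log",
                             rows = NA_integer_, stringsAsFactors = FALSE))
}
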