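#' Validate a command-line run configuration
#'
#' The command-line layer restricts choices to the menus the analysis was
#' designed around: 1000/10000/100000 repetitions, FDR cutoff in
#' [0.005, 0.2], association windows of 5/10/20 kb and 1-3 peak files.
#' The underlying library functions accept wider values.
#'
#' @param n_reps,fdr_cutoff,window_kb,n_bed_files Values to check;
#'   `window_kb`/`n_bed_files` are only checked when non-`NULL`.
#' @return Invisibly `TRUE`; aborts with a descriptive error otherwise.
#' @export
validate_run_config <- function(n_reps = 10000L, fdr_cutoff = 0.05,
                                window_kb = NULL, n_bed_files = NULL) {
  if (!n_reps %in% c(1000L, 10000L, 100000L)) {
    rlang::abort("n_reps must be one of 1000, 10000, 100000")
  }
  if (fdr_cutoff < 0.005 || fdr_cutoff > 0.2) {
    rlang::abort("fdr_cutoff must lie between 0.005 and 0.2")
  }
  if (!is.null(window_kb) && !window_kb %in% c(5, 10, 20)) {
    rlang::abort("window_kb must be one of 5, 10, 20")
  }
  if (!is.null(n_bed_files) && (n_bed_files < 1L || n_bed_files > 3L)) {
    rlang::abort("between 1 and 3 peak files are supported")
  }
  invisible(TRUE)
}

read_gene_list_file <- function(path) {
  assert_file_exists(path)
  lines <- trimws(readr::read_lines(path, progress = FALSE))
  lines[lines != "" & !startsWith(lines, "#")]
}

# Shared back half of both run modes: enrichment + outputs.
run_enrichment_outputs <- function(gs, background, out_dir, n_reps, fdr_cutoff,
                                   min_target_pct, seed, master = NULL,
                                   feedback = NULL) {
  fit <- mir_enrich(gs, background, n_reps = n_reps, fdr_cutoff = fdr_cutoff,
                    min_target_pct = min_target_pct, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results_path <- file.path(out_dir, "results.tsv")
  pairs_path <- file.path(out_dir, "pairs.tsv")
  res <- fit$results
  names(res)[names(res) == "m"] <- "m_A"
  readr::write_tsv(res, results_path)
  loop_lines <- character(0)
  if (!is.null(master)) {
    over <- fit$results$family_id[fit$results$over_represented]
    ffl <- find_feedforward(over, master, background)
    loop_lines <- c(loop_lines,
                    sprintf("# feedforward_type2_families: %s",
                            if (length(ffl)) paste(ffl, collapse = ",") else "none"))
  }
  if (!is.null(feedback)) {
    loop_lines <- c(loop_lines,
                    sprintf("# feedback_mirna: %s distance=%d",
                            feedback$mirna_name, as.integer(feedback$distance)))
    if (nrow(feedback) == 0L) {
      loop_lines <- c(loop_lines, "# feedback_mirna: none")
    }
  }
  if (length(loop_lines) > 0L) {
    readr::write_lines(loop_lines, results_path, append = TRUE)
  }
  readr::write_tsv(enriched_pairs(fit, background), pairs_path)
  message(sprintf("N = %d genes in background; %d families tested; seed %s",
                  fit$gene_set$N, fit$n_families, seed %||% "unset"))
  invisible(list(fit = fit, results = results_path, pairs = pairs_path))
}

#' Run the full analysis on a gene list
#'
#' Maps the identifiers, restricts to the prediction background (validating
#' that N lies in [20, 4000]), runs the randomization test with the scaling
#' correction, applies Benjamini-Hochberg and the cutoffs, and writes the
#' two text outputs: `results.tsv` (one row per family, sorted by FDR) and
#' `pairs.tsv` (targets of the over-represented families within the gene
#' set). When a master regulator is given, feedforward-loop families are
#' appended to the results file as `#` comment lines.
#'
#' @param genes_file Plain-text gene list, one identifier per line.
#' @param background_file,idmap_file Prediction and identifier tables
#'   ([read_predictions()], [read_idmap()]).
#' @param out_dir Output directory (created if needed).
#' @param id_type Identifier namespace of the list.
#' @param species `"human"` or `"mouse"`.
#' @param master Optional Entrez id of the master transcription factor.
#' @param n_reps,fdr_cutoff,min_target_pct,seed Enrichment configuration;
#'   menu constraints are enforced here (see [validate_run_config()]).
#' @return Invisibly, a list with the `mir_enrichment` fit and the output
#'   paths.
#' @export
run_genelist <- function(genes_file, background_file, idmap_file, out_dir,
                         id_type = c("entrez", "symbol", "ensembl", "refseq"),
                         species = "human", master = NULL,
                         n_reps = 10000L, fdr_cutoff = 0.05,
                         min_target_pct = 0, seed = NULL) {
  id_type <- match.arg(id_type)
  validate_run_config(n_reps = n_reps, fdr_cutoff = fdr_cutoff)
  preds <- read_predictions(background_file, species = species)
  idmap <- read_idmap(idmap_file)
  background <- build_background(preds, idmap)
  tokens <- read_gene_list_file(genes_file)
  mapping <- map_gene_ids(tokens, idmap, namespace = id_type)
  if (length(mapping$unmapped) > 0L) {
    message(sprintf("%d identifier(s) could not be mapped", length(mapping$unmapped)))
  }
  gs <- restrict_to_background(mapping$mapped, background)
  run_enrichment_outputs(gs, background, out_dir, n_reps, fdr_cutoff,
                         min_target_pct, seed, master = master)
}

#' Run the full analysis on 1-3 ChIP-seq peak files
#'
#' Associates peaks with genes (nearest TSS within a window, or ranked
#' promoter/first-intron membership), intersects multiple datasets
#' (a gene must be supported by at least two files when several are
#' given), then proceeds exactly as [run_genelist()]. An audit table of
#' every peak-gene assignment is written alongside the results; when a
#' master and a miRNA locus table are supplied, feedback-loop miRNAs
#' (master peaks near a miRNA gene) are reported too.
#'
#' @param bed_files Character vector of 1-3 BED paths.
#' @param genemodel_file Gene-model table ([read_gene_models()]).
#' @param background_file,idmap_file,out_dir,species,master See
#'   [run_genelist()].
#' @param method `"nearest"` or `"ranked"`.
#' @param window_kb Association window in kb (5, 10 or 20).
#' @param min_support Distinct-file support required when several BED files
#'   are given.
#' @param mirna_loci_file Optional miRNA gene-locus table for feedback
#'   detection (used only with `master`).
#' @param n_reps,fdr_cutoff,min_target_pct,seed Enrichment configuration.
#' @return Invisibly, a list with the fit, output paths and the derived
#'   gene set.
#' @export
run_peaks <- function(bed_files, genemodel_file, background_file, idmap_file,
                      out_dir, method = c("nearest", "ranked"), window_kb = 10,
                      min_support = 2L, species = "human", master = NULL,
                      mirna_loci_file = NULL, n_reps = 10000L, fdr_cutoff = 0.05,
                      min_target_pct = 0, seed = NULL) {
  method <- match.arg(method)
  validate_run_config(n_reps = n_reps, fdr_cutoff = fdr_cutoff,
                      window_kb = if (method == "nearest") window_kb else NULL,
                      n_bed_files = length(bed_files))
  gene_models <- read_gene_models(genemodel_file)
  peak_sets <- purrr::imap(bed_files, function(f, i) read_bed(f, source_index = i))
  assoc <- purrr::map(peak_sets, function(p) {
    if (method == "nearest") associate_nearest(p, gene_models, window_kb = window_kb)
    else associate_ranked(p, gene_models)
  })
  genes <- combine_datasets(assoc, min_support = min_support)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  audit <- dplyr::bind_rows(purrr::map(assoc, tidy))
  audit_path <- file.path(out_dir, "peak_gene_audit.tsv")
  readr::write_tsv(audit, audit_path)
  preds <- read_predictions(background_file, species = species)
  idmap <- read_idmap(idmap_file)
  background <- build_background(preds, idmap)
  gs <- restrict_to_background(genes, background)
  feedback <- NULL
  if (!is.null(master) && !is.null(mirna_loci_file)) {
    loci <- read_mirna_loci(mirna_loci_file)
    feedback <- find_feedback(dplyr::bind_rows(peak_sets), loci, window_kb = window_kb)
  }
  out <- run_enrichment_outputs(gs, background, out_dir, n_reps, fdr_cutoff,
                                min_target_pct, seed, master = master,
                                feedback = feedback)
  invisible(c(out, list(audit = audit_path, genes = genes)))
}
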