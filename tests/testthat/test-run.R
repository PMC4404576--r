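# End-to-end fixture shared across the pipeline tests: a 100-gene background,
# gene models on one synthetic chromosome, and peak files aimed at known genes.
make_pipeline_fixture <- function(dir, seed = 61) {
  sim <- simulate_background(n_genes = 100, n_families = 10, base_density = 0.35,
                             seed = seed)
  write_predictions(sim$predictions, file.path(dir, "predictions.tsv"))
  write_idmap(sim$idmap, file.path(dir, "idmap.tsv"))
  bg <- build_background(sim$predictions)
  gm <- simulate_gene_models(100, gene_ids = sim$manifest$genes, seed = seed + 1)
  write_gene_models(gm, file.path(dir, "genemodels.tsv"))
  list(sim = sim, bg = bg, gm = gm)
}

test_that("a gene-list run recovers a planted family and writes both outputs", {
  dir <- withr::local_tempdir()
  fx <- make_pipeline_fixture(dir)
  fc <- family_counts(fx$bg)
  planted <- fc$family_id[which.max(fc$n_targets)]  # family with enough targets
  set <- simulate_gene_set(fx$bg, target_family = planted, n_set = 30,
                           enrichment_prob = 1, seed = 62)
  write_gene_list(set$genes, file.path(dir, "genes.txt"))
  out <- suppressMessages(run_genelist(
    genes_file = file.path(dir, "genes.txt"),
    background_file = file.path(dir, "predictions.tsv"),
    idmap_file = file.path(dir, "idmap.tsv"),
    out_dir = file.path(dir, "out"),
    n_reps = 1000L, seed = 63,
    master = set$genes[1]
  ))
  res <- readr::read_tsv(out$results, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(res), 10L)
  expect_equal(res$family_id[1], planted)
  expect_true(res$over_represented[1])
  expect_true(file.exists(out$pairs))
  pairs <- readr::read_tsv(out$pairs, show_col_types = FALSE)
  expect_true(all(pairs$family_id %in% res$family_id[res$over_represented]))
  # the planted family targets the master (a set member), closing the loop
  tail_lines <- readLines(out$results)
  expect_true(any(grepl("^# feedforward_type2_families:", tail_lines)))
})

test_that("a null gene set yields no over-represented family at strict cutoff", {
  dir <- withr::local_tempdir()
  fx <- make_pipeline_fixture(dir, seed = 71)
  null_set <- simulate_gene_set(fx$bg, n_set = 30, enrichment_prob = 0, seed = 72)
  write_gene_list(null_set$genes, file.path(dir, "genes.txt"))
  out <- suppressMessages(run_genelist(
    genes_file = file.path(dir, "genes.txt"),
    background_file = file.path(dir, "predictions.tsv"),
    idmap_file = file.path(dir, "idmap.tsv"),
    out_dir = file.path(dir, "out"),
    n_reps = 1000L, fdr_cutoff = 0.05, seed = 73
  ))
  res <- readr::read_tsv(out$results, comment = "#", show_col_types = FALSE)
  expect_equal(sum(res$over_represented), 0L)
})

test_that("identical configuration and seed give byte-identical outputs", {
  dir <- withr::local_tempdir()
  fx <- make_pipeline_fixture(dir, seed = 81)
  set <- simulate_gene_set(fx$bg, target_family = "miR-01", n_set = 25,
                           enrichment_prob = 0.5, seed = 82)
  write_gene_list(set$genes, file.path(dir, "genes.txt"))
  args <- list(
    genes_file = file.path(dir, "genes.txt"),
    background_file = file.path(dir, "predictions.tsv"),
    idmap_file = file.path(dir, "idmap.tsv"),
    n_reps = 1000L, seed = 83
  )
  o1 <- suppressMessages(do.call(run_genelist, c(args, out_dir = file.path(dir, "o1"))))
  o2 <- suppressMessages(do.call(run_genelist, c(args, out_dir = file.path(dir, "o2"))))
  for (f in c("results", "pairs")) {
    expect_identical(readBin(o1[[f]], "raw", file.size(o1[[f]])),
                     readBin(o2[[f]], "raw", file.size(o2[[f]])))
  }
})

test_that("out-of-bounds N aborts with the offending value in the message", {
  dir <- withr::local_tempdir()
  fx <- make_pipeline_fixture(dir, seed = 91)
  small <- simulate_gene_set(fx$bg, n_set = 10, enrichment_prob = 0, seed = 92)
  write_gene_list(small$genes, file.path(dir, "genes.txt"))
  expect_error(
    suppressMessages(run_genelist(
      genes_file = file.path(dir, "genes.txt"),
      background_file = file.path(dir, "predictions.tsv"),
      idmap_file = file.path(dir, "idmap.tsv"),
      out_dir = file.path(dir, "out"),
      n_reps = 1000L, seed = 93
    )),
    "N = 10"
  )
})

test_that("peak mode derives the two-file supported gene set and writes an audit", {
  dir <- withr::local_tempdir()
  fx <- make_pipeline_fixture(dir, seed = 101)
  shared <- fx$sim$manifest$genes[11:40]       # 30 genes hit in both files
  only1 <- fx$sim$manifest$genes[1:5]
  only2 <- fx$sim$manifest$genes[96:100]
  p1 <- simulate_peaks(fx$gm, hit_genes = c(only1, shared), window_kb = 10, seed = 102)
  p2 <- simulate_peaks(fx$gm, hit_genes = c(shared, only2), window_kb = 10, seed = 103)
  write_bed(p1$peaks, file.path(dir, "a.bed"))
  write_bed(p2$peaks, file.path(dir, "b.bed"))
  loci <- simulate_mirna_loci(6, families = families(fx$bg), chrom = "chrS", seed = 104)
  write_mirna_loci(loci, file.path(dir, "loci.tsv"))
  out <- suppressMessages(run_peaks(
    bed_files = c(file.path(dir, "a.bed"), file.path(dir, "b.bed")),
    genemodel_file = file.path(dir, "genemodels.tsv"),
    background_file = file.path(dir, "predictions.tsv"),
    idmap_file = file.path(dir, "idmap.tsv"),
    out_dir = file.path(dir, "out"),
    window_kb = 10, n_reps = 1000L, seed = 105,
    master = shared[1], mirna_loci_file = file.path(dir, "loci.tsv")
  ))
  expect_setequal(out$genes, shared)
  audit <- readr::read_tsv(out$audit, show_col_types = FALSE)
  expect_equal(nrow(audit), nrow(p1$peaks) + nrow(p2$peaks))
  expect_true(all(c("gene_id", "method_tag", "distance") %in% names(audit)))
  expect_true(file.exists(out$results))

  # a gene hit in only one of three files is excluded from the analysis set
  p3 <- simulate_peaks(fx$gm, hit_genes = shared, window_kb = 10, seed = 106)
  write_bed(p3$peaks, file.path(dir, "c.bed"))
  out3 <- suppressMessages(run_peaks(
    bed_files = file.path(dir, c("a.bed", "b.bed", "c.bed")),
    genemodel_file = file.path(dir, "genemodels.tsv"),
    background_file = file.path(dir, "predictions.tsv"),
    idmap_file = file.path(dir, "idmap.tsv"),
    out_dir = file.path(dir, "out3"),
    window_kb = 10, n_reps = 1000L, seed = 107
  ))
  expect_false(any(c(only1, only2) %in% out3$genes))
  expect_true(all(shared %in% out3$genes))
})

test_that("menu validation guards the command-line surface", {
  expect_error(validate_run_config(n_reps = 500L), "1000")
  expect_silent(validate_run_config(n_reps = 100000L))
  expect_error(validate_run_config(fdr_cutoff = 0.3), "0.005")
  expect_error(validate_run_config(fdr_cutoff = 0.001), "0.005")
  expect_silent(validate_run_config(fdr_cutoff = 0.2))
  expect_silent(validate_run_config(fdr_cutoff = 0.005))
  expect_error(validate_run_config(window_kb = 7), "5, 10, 20")
  expect_error(validate_run_config(n_bed_files = 4L), "1 and 3")
  expect_silent(validate_run_config(window_kb = 20, n_bed_files = 3L))
})
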