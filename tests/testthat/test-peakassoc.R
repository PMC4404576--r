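test_that("read_bed parses BED3+, skips headers and reports bad lines", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=test", "# a comment",
               "chr1\t100\t200", "chr2\t5\t50\tpeakname\t940"), path)
  peaks <- read_bed(path)
  expect_equal(nrow(peaks), 2L)
  expect_equal(peaks$start, c(100L, 5L))
  expect_equal(peaks$end, c(200L, 50L))

  writeLines(c("chr1\t100\t200", "chr1\t300\t250"), path)
  expect_error(read_bed(path), "line 2")
  writeLines("chr1\tabc\t200", path)
  expect_error(read_bed(path), "line 1")
  writeLines(c("track name=x", "# nothing"), path)
  expect_error(read_bed(path), "no peaks")
})

test_that("nearest-TSS assignment follows midpoint distance and window", {
  gm <- tibble::tibble(
    gene_id = 1L, chrom = "chr1", strand = "+",
    tx_start = 1000L, tx_end = 3000L,
    exon_starts = list(1000L), exon_ends = list(3000L),
    tss = 1000L, fi_start = NA_integer_, fi_end = NA_integer_
  )
  on_tss <- associate_nearest(tibble::tibble(chrom = "chr1", start = 990L, end = 1010L,
                                             source_index = 1L), gm, window_kb = 5)
  expect_equal(on_tss$peak_to_gene$gene_id, 1L)
  expect_equal(on_tss$peak_to_gene$distance, 0L)

  # midpoint 6 kb off TSS: orphan at 5 kb, assigned at 10 kb
  far <- tibble::tibble(chrom = "chr1", start = 6900L, end = 7100L, source_index = 1L)
  expect_equal(nrow(associate_nearest(far, gm, window_kb = 5)$peak_to_gene), 0L)
  a10 <- associate_nearest(far, gm, window_kb = 10)
  expect_equal(a10$peak_to_gene$gene_id, 1L)
  expect_equal(a10$peak_to_gene$distance, 6000L)

  expect_error(associate_nearest(far, gm[0, ]), "empty gene-model")
})

test_that("nearest assignment matches the all-pairs brute-force oracle", {
  gm <- simulate_gene_models(10, seed = 11)
  withr::with_seed(11, {
    peaks <- tibble::tibble(
      chrom = "chrS",
      start = sample.int(max(gm$tx_end) + 30000L, 100),
      source_index = 1L
    )
    peaks$end <- peaks$start + sample(100:400, 100, replace = TRUE)
  })
  for (w in c(5, 10, 20)) {
    got <- tidy(associate_nearest(peaks, gm, window_kb = w))
    expect_equal(
      got$gene_id[order(got$start)],
      oracle_nearest(peaks[order(peaks$start), ], gm, w)
    )
  }
})

test_that("every peak lands in exactly one bucket and order does not matter", {
  gm <- simulate_gene_models(8, seed = 2)
  sim <- simulate_peaks(gm, hit_genes = gm$gene_id[1:5], window_kb = 10,
                        n_noise_peaks = 6, seed = 3)
  a <- associate_nearest(sim$peaks, gm, window_kb = 10)
  expect_equal(nrow(a$peak_to_gene) + nrow(a$orphan_peaks), nrow(sim$peaks))
  expect_setequal(a$genes, unique(a$peak_to_gene$gene_id))

  perm <- withr::with_seed(4, sample.int(nrow(sim$peaks)))
  a_perm <- associate_nearest(sim$peaks[perm, ], gm[sample.int(nrow(gm)), ], window_kb = 10)
  expect_setequal(a_perm$genes, a$genes)
  expect_equal(
    dplyr::arrange(a_perm$peak_to_gene, start),
    dplyr::arrange(a$peak_to_gene, start)
  )
})

test_that("shrinking the window never adds genes", {
  gm <- simulate_gene_models(12, seed = 6)
  sim <- simulate_peaks(gm, hit_genes = gm$gene_id[c(1, 4, 7)], window_kb = 5,
                        n_noise_peaks = 10, seed = 7)
  g5 <- associate_nearest(sim$peaks, gm, window_kb = 5)$genes
  g10 <- associate_nearest(sim$peaks, gm, window_kb = 10)$genes
  g20 <- associate_nearest(sim$peaks, gm, window_kb = 20)$genes
  expect_true(all(g5 %in% g10))
  expect_true(all(g10 %in% g20))
})

test_that("reflecting coordinates and flipping strands mirrors assignments", {
  gm <- simulate_gene_models(6, seed = 9)
  sim <- simulate_peaks(gm, hit_genes = gm$gene_id, window_kb = 10,
                        n_noise_peaks = 4, peak_width = 201L, seed = 10)
  peaks <- sim$peaks  # odd width keeps the midpoint exact under reflection
  L <- max(gm$tx_end, peaks$end) + 1000L
  gm_ref <- gm
  gm_ref$strand <- ifelse(gm$strand == "+", "-", "+")
  gm_ref$tx_start <- L - gm$tx_end
  gm_ref$tx_end <- L - gm$tx_start
  gm_ref$exon_starts <- lapply(gm$exon_ends, function(e) rev(L - e))
  gm_ref$exon_ends <- lapply(gm$exon_starts, function(s) rev(L - s))
  gm_ref$tss <- ifelse(gm_ref$strand == "+", gm_ref$tx_start, gm_ref$tx_end - 1L)
  peaks_ref <- tibble::tibble(chrom = peaks$chrom, start = L - peaks$end,
                              end = L - peaks$start, source_index = 1L)
  a <- associate_nearest(peaks, gm, window_kb = 10)
  a_ref <- associate_nearest(peaks_ref, gm_ref, window_kb = 10)
  expect_setequal(a_ref$genes, a$genes)
  expect_equal(sort(a_ref$peak_to_gene$distance), sort(a$peak_to_gene$distance))
})

test_that("ranked association prefers promoters over first introns", {
  # + strand gene with promoter [tss-1000, tss+500] and a first intron
  gene_a <- tibble::tibble(
    gene_id = 1L, chrom = "chr1", strand = "+",
    tx_start = 10000L, tx_end = 16000L,
    exon_starts = list(c(10000L, 14000L)), exon_ends = list(c(10500L, 16000L)),
    tss = 10000L, fi_start = 10500L, fi_end = 14000L
  )
  prom_peak <- tibble::tibble(chrom = "chr1", start = 9750L, end = 9850L, source_index = 1L)
  a <- associate_ranked(prom_peak, gene_a)
  expect_equal(a$peak_to_gene$method_tag, "promoter")
  expect_equal(a$peak_to_gene$gene_id, 1L)

  # same midpoint inside gene A's first intron and gene B's promoter -> B wins
  gene_b <- tibble::tibble(
    gene_id = 2L, chrom = "chr1", strand = "-",
    tx_start = 2000L, tx_end = 12001L,
    exon_starts = list(2000L), exon_ends = list(12001L),
    tss = 12000L, fi_start = NA_integer_, fi_end = NA_integer_
  )
  both <- dplyr::bind_rows(gene_a, gene_b)
  mid_peak <- tibble::tibble(chrom = "chr1", start = 11950L, end = 12050L, source_index = 1L)
  m <- floor((11950 + 12050) / 2)
  expect_true(m >= gene_a$fi_start && m < gene_a$fi_end)       # in A's first intron
  expect_true(abs(m - gene_b$tss) <= 500)                      # in B's promoter
  got <- associate_ranked(mid_peak, both)
  expect_equal(got$peak_to_gene$gene_id, 2L)
  expect_equal(got$peak_to_gene$method_tag, "promoter")

  # single-exon gene, peak in the body beyond the promoter window -> orphan
  body_peak <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5100L, source_index = 1L)
  solo <- associate_ranked(body_peak, gene_b)
  expect_equal(nrow(solo$peak_to_gene), 0L)
  expect_equal(nrow(solo$orphan_peaks), 1L)
})

test_that("multi-dataset combination counts distinct-file support", {
  expect_equal(combine_datasets(list(c(1L, 2L))), c(1L, 2L))
  expect_equal(combine_datasets(list(c(1L, 2L), c(2L, 3L))), 2L)
  expect_equal(combine_datasets(list(c(1L, 2L), c(2L, 3L), c(1L, 3L))), c(1L, 2L, 3L))
  expect_equal(combine_datasets(list(c(1L, 2L), c(3L)), min_support = 1L), 1:3)
  # duplicated genes within one file count once
  expect_equal(combine_datasets(list(c(5L, 5L), c(7L))), integer(0))
  expect_error(combine_datasets(list()), "no association results")
})

test_that("peak fixtures round-trip through association and combination", {
  gm <- simulate_gene_models(10, seed = 12)
  hits <- gm$gene_id[1:6]
  clean <- simulate_peaks(gm, hit_genes = hits, window_kb = 10, n_noise_peaks = 0, seed = 13)
  expect_setequal(associate_nearest(clean$peaks, gm, window_kb = 10)$genes, hits)

  pure_noise <- simulate_peaks(gm, hit_genes = integer(0), window_kb = 10,
                               n_noise_peaks = 8, seed = 14)
  noise_assoc <- associate_nearest(pure_noise$peaks, gm, window_kb = 10)
  expect_equal(nrow(noise_assoc$peak_to_gene), 0L)
  expect_equal(nrow(noise_assoc$orphan_peaks), 8L)

  shared <- gm$gene_id[3:6]
  f1 <- simulate_peaks(gm, hit_genes = c(gm$gene_id[1:2], shared), window_kb = 10, seed = 15)
  f2 <- simulate_peaks(gm, hit_genes = c(shared, gm$gene_id[7:8]), window_kb = 10, seed = 16)
  a1 <- associate_nearest(f1$peaks, gm, window_kb = 10)
  a2 <- associate_nearest(f2$peaks, gm, window_kb = 10)
  expect_setequal(combine_datasets(list(a1, a2), min_support = 2L), shared)
})
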