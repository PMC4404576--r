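#' Simulate a target-prediction background with a target-density confounder
#'
#' Generates a toy prediction table, identifier map and manifest. Each
#' (family, gene) pair exists independently with probability
#' `base_density`, multiplied by `bias_factor` (capped at 1) for a
#' "long-3'UTR" subset of genes — the minimal model of the confounder where
#' genes with longer 3'UTRs accumulate more predicted sites for every
#' family. Every gene carries 1-3 transcript rows so that isoform pooling
#' is exercised: each planted pair is emitted once per transcript of the
#' gene. Optionally a fraction of decoy rows flagged `"poorly conserved"`
#' is appended to exercise the conservation filter.
#'
#' @param n_genes,n_families Universe dimensions.
#' @param base_density Probability that a (family, gene) pair exists.
#' @param long_utr_fraction Fraction of genes whose density is multiplied.
#' @param bias_factor Density multiplier for long-3'UTR genes (>= 1).
#' @param frac_nonconserved Fraction of extra decoy rows (relative to the
#'   conserved row count) flagged `"poorly conserved"`.
#' @param species `"human"` or `"mouse"`.
#' @param seed Integer seed; the output is a pure function of the
#'   arguments and the seed.
#' @return List with `predictions` and `idmap` tibbles (the on-disk TSV
#'   dialects of [read_predictions()] / [read_idmap()]) and a `manifest`
#'   recording the planted pairs, long-3'UTR genes and row counts.
#' @export
simulate_background <- function(n_genes = 40L, n_families = 6L,
                                base_density = 0.3, long_utr_fraction = 0.5,
                                bias_factor = 1, frac_nonconserved = 0,
                                species = "human", seed = NULL) {
  stopifnot(n_genes >= 1L, n_families >= 1L, bias_factor >= 1,
            base_density >= 0, base_density <= 1,
            long_utr_fraction >= 0, long_utr_fraction <= 1)
  with_seed(seed, {
    genes <- 1000L + seq_len(n_genes)
    fams <- sprintf("miR-%02d", seq_len(n_families))
    n_long <- round(long_utr_fraction * n_genes)
    long_genes <- sort(sample(genes, n_long))
    dens <- ifelse(genes %in% long_genes, pmin(1, base_density * bias_factor), base_density)
    grid <- tidyr::expand_grid(family_id = fams, gene_id = genes)
    grid$p <- dens[match(grid$gene_id, genes)]
    pairs <- grid[stats::runif(nrow(grid)) < grid$p, c("family_id", "gene_id")]
    if (nrow(pairs) == 0L) {
      rlang::abort("simulated background is empty; raise base_density or sizes")
    }
    n_tx <- sample(1:3, n_genes, replace = TRUE)
    tx <- tibble::tibble(
      gene_id = rep(genes, n_tx),
      refseq_transcript = sprintf("NM_%06d", seq_len(sum(n_tx)))
    )
    idmap <- tibble::tibble(
      entrez_id = tx$gene_id,
      symbol = sprintf("GENE%d", tx$gene_id),
      ensembl_gene = sprintf("ENSG%011d", tx$gene_id),
      refseq_transcript = tx$refseq_transcript
    )
    predictions <- dplyr::inner_join(pairs, tx, by = "gene_id",
                                     relationship = "many-to-many")
    predictions <- tibble::tibble(
      family_id = predictions$family_id,
      transcript_id = predictions$refseq_transcript,
      gene_id = predictions$gene_id,
      species = species,
      conservation = "conserved"
    )
    n_decoy <- round(frac_nonconserved * nrow(predictions))
    if (n_decoy > 0L) {
      decoy <- predictions[sample.int(nrow(predictions), n_decoy, replace = TRUE), ]
      decoy$conservation <- "poorly conserved"
      predictions <- dplyr::bind_rows(predictions, decoy)
    }
    list(
      predictions = predictions,
      idmap = idmap,
      manifest = list(
        n_genes = n_genes, n_families = n_families,
        genes = genes, families = fams,
        long_utr_genes = long_genes,
        pairs = tibble::as_tibble(pairs),
        n_rows_total = nrow(predictions),
        n_rows_conserved = nrow(predictions) - n_decoy,
        seed = seed
      )
    )
  })
}

#' Simulate a gene set with a planted (spiked) enriched family
#'
#' Draws `n_set` distinct genes from the background universe (optionally a
#' restricted pool). The number of members forced to be targets of
#' `target_family` is Binomial(`n_set`, `enrichment_prob`), so
#' `enrichment_prob = 0` is a uniform null draw and `enrichment_prob = 1` a
#' pure spike where every member is a target (shortfall, when the family
#' has too few targets, is reported in the manifest).
#'
#' @param background A `mir_background`.
#' @param target_family Family to spike; may be `NULL` when
#'   `enrichment_prob = 0`.
#' @param n_set Size of the gene set.
#' @param enrichment_prob Mixing weight of the spike in `[0, 1]`.
#' @param pool Optional integer vector restricting the candidate genes
#'   (intersected with the universe); used e.g. to draw sets of only
#'   long-3'UTR genes.
#' @param seed Integer seed.
#' @return List with `genes` (sorted ids) and a `manifest` recording the
#'   planted spike size and the realised target count of `target_family`.
#' @export
simulate_gene_set <- function(background, target_family = NULL, n_set,
                              enrichment_prob = 0, pool = NULL, seed = NULL) {
  stopifnot(enrichment_prob >= 0, enrichment_prob <= 1)
  universe <- gene_universe(background)
  if (!is.null(pool)) universe <- intersect(universe, as.integer(pool))
  if (n_set > length(universe)) {
    rlang::abort(sprintf("gene set size %d exceeds available universe of %d",
                         n_set, length(universe)))
  }
  with_seed(seed, {
    targets <- if (is.null(target_family)) integer(0) else {
      intersect(universe, background$gene_id[background$family_id == target_family])
    }
    k_want <- if (enrichment_prob == 0) 0L else if (enrichment_prob == 1) n_set else {
      stats::rbinom(1L, n_set, enrichment_prob)
    }
    k <- min(k_want, length(targets))
    if (k < k_want) {
      rlang::warn(sprintf("only %d targets of %s available for a spike of %d",
                          length(targets), target_family %||% "<none>", k_want))
    }
    spiked <- if (k > 0L) sample(targets, k) else integer(0)
    rest_pool <- setdiff(universe, spiked)
    rest <- if (n_set - k > 0L) sample(rest_pool, n_set - k) else integer(0)
    genes <- sort(c(spiked, rest))
    list(
      genes = genes,
      manifest = list(
        target_family = target_family,
        n_set = n_set,
        n_spiked = k,
        m_target = if (is.null(target_family)) NA_integer_ else
          length(intersect(genes, targets)),
        enrichment_prob = enrichment_prob,
        seed = seed
      )
    )
  })
}

#' Simulate gene models on one synthetic chromosome
#'
#' Genes are spaced at least `spacing` bp apart (100 kb by default) so that
#' TSS-window assignment is unambiguous at windows up to 20 kb. Each gene
#' gets a random strand and 1-3 exons; multi-exon genes therefore carry a
#' well-defined first intron.
#'
#' @param n_genes Number of genes.
#' @param gene_ids Optional explicit ids (defaults to `1000 + 1:n_genes`,
#'   matching [simulate_background()]).
#' @param chrom Chromosome name.
#' @param spacing Minimum TSS-to-TSS spacing in bp.
#' @param prob_single_exon Probability that a gene has a single exon (and
#'   hence no first intron).
#' @param seed Integer seed.
#' @return Gene-model tibble in the shape returned by [read_gene_models()].
#' @export
simulate_gene_models <- function(n_genes = 10L, gene_ids = NULL, chrom = "chrS",
                                 spacing = 100000L, prob_single_exon = 0.2,
                                 seed = NULL) {
  if (is.null(gene_ids)) gene_ids <- 1000L + seq_len(n_genes)
  stopifnot(length(gene_ids) == n_genes)
  with_seed(seed, {
    anchor <- spacing * seq_len(n_genes)
    rows <- purrr::map(seq_len(n_genes), function(i) {
      strand <- sample(c("+", "-"), 1L)
      single <- stats::runif(1) < prob_single_exon
      if (single) {
        len <- sample(1000:3000, 1L)
        es <- anchor[i]
        ee <- anchor[i] + len
      } else {
        n_ex <- sample(2:3, 1L)
        ex_len <- sample(200:600, n_ex, replace = TRUE)
        intron_len <- sample(500:3000, n_ex - 1L, replace = TRUE)
        es <- anchor[i] + c(0L, cumsum(ex_len[-n_ex] + intron_len))
        ee <- es + ex_len
      }
      tibble::tibble(
        gene_id = gene_ids[i], chrom = chrom, strand = strand,
        tx_start = es[1], tx_end = ee[length(ee)],
        exon_starts = list(as.integer(es)), exon_ends = list(as.integer(ee))
      )
    })
    finish_gene_models(dplyr::bind_rows(rows))
  })
}

#' Simulate a ChIP-seq peak file aimed at chosen genes
#'
#' Places one peak with its midpoint within `window_kb` of each hit gene's
#' TSS, plus noise peaks whose midpoints are at least twice the window from
#' every TSS, so the intended associations are unambiguous.
#'
#' @param gene_models Gene-model tibble (e.g. [simulate_gene_models()]).
#' @param hit_genes Gene ids to place a peak near (subset of the models).
#' @param window_kb Association window the fixture is built for.
#' @param n_noise_peaks Number of unassignable noise peaks.
#' @param peak_width Peak width in bp.
#' @param seed Integer seed.
#' @return List with `peaks` (BED-shaped tibble) and a `manifest` of the
#'   intended peak-gene associations.
#' @export
simulate_peaks <- function(gene_models, hit_genes = integer(0), window_kb = 10,
                           n_noise_peaks = 0L, peak_width = 200L, seed = NULL) {
  stopifnot(all(hit_genes %in% gene_models$gene_id))
  window_bp <- as.integer(window_kb * 1000)
  with_seed(seed, {
    gm <- gene_models[match(hit_genes, gene_models$gene_id), , drop = FALSE]
    offset <- if (length(hit_genes) > 0L) {
      sample(seq(-window_bp + 1L, window_bp - 1L), length(hit_genes), replace = TRUE)
    } else integer(0)
    mids <- gm$tss + offset
    hit_peaks <- tibble::tibble(
      chrom = gm$chrom,
      start = as.integer(mids - peak_width %/% 2),
      end = as.integer(mids - peak_width %/% 2 + peak_width)
    )
    noise <- NULL
    if (n_noise_peaks > 0L) {
      lo <- 1L
      hi <- max(gene_models$tx_end) + 10L * window_bp
      tss <- gene_models$tss
      placed <- integer(0)
      tries <- 0L
      while (length(placed) < n_noise_peaks && tries < 200L * n_noise_peaks) {
        cand <- sample.int(hi - lo, 1L) + lo
        if (min(abs(cand - tss)) >= 2L * window_bp) placed <- c(placed, cand)
        tries <- tries + 1L
      }
      if (length(placed) < n_noise_peaks) {
        rlang::abort("could not place noise peaks away from every TSS; genome too crowded")
      }
      noise <- tibble::tibble(
        chrom = gene_models$chrom[1],
        start = as.integer(placed - peak_width %/% 2),
        end = as.integer(placed - peak_width %/% 2 + peak_width)
      )
    }
    peaks <- dplyr::bind_rows(hit_peaks, noise)
    peaks$source_index <- 1L
    list(
      peaks = peaks,
      manifest = list(
        hit_genes = as.integer(hit_genes),
        intended = tibble::tibble(gene_id = as.integer(hit_genes),
                                  midpoint = as.integer(mids),
                                  distance = abs(offset)),
        n_noise = n_noise_peaks,
        window_kb = window_kb,
        seed = seed
      )
    )
  })
}

#' Simulate a miRNA gene-locus table
#'
#' Loci of 80-150 bp spaced well apart on one synthetic chromosome,
#' optionally carrying family labels recycled from `families`.
#'
#' @param n_loci Number of miRNA genes.
#' @param families Optional family labels to attach (recycled); `NULL`
#'   leaves the column `NA`.
#' @param chrom Chromosome name.
#' @param spacing Locus-to-locus spacing in bp.
#' @param seed Integer seed.
#' @return Tibble in the shape of [read_mirna_loci()].
#' @export
simulate_mirna_loci <- function(n_loci = 8L, families = NULL, chrom = "chrM1",
                                spacing = 100000L, seed = NULL) {
  with_seed(seed, {
    starts <- spacing * seq_len(n_loci) + sample.int(1000L, n_loci)
    len <- sample(80:150, n_loci, replace = TRUE)
    tibble::tibble(
      mirna_name = sprintf("mir-s%02d", seq_len(n_loci)),
      family_id = if (is.null(families)) NA_character_ else
        rep_len(families, n_loci),
      chrom = chrom,
      strand = sample(c("+", "-"), n_loci, replace = TRUE),
      start = as.integer(starts),
      end = as.integer(starts + len)
    )
  })
}

#' Write fixture tables in the dialects the readers consume
#'
#' Plain-text writers for the prediction, idmap, gene-model, miRNA-locus,
#' BED and gene-list formats, inverse to the corresponding `read_*`
#' functions.
#'
#' @param x The tibble (or, for `write_gene_list()`, integer vector) to
#'   write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name fixture-writers
NULL

#' @rdname fixture-writers
#' @export
write_predictions <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname fixture-writers
#' @export
write_idmap <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname fixture-writers
#' @export
write_gene_models <- function(x, path) {
  out <- tibble::tibble(
    gene_id = x$gene_id, chrom = x$chrom, strand = x$strand,
    tx_start = x$tx_start, tx_end = x$tx_end,
    exon_starts = vapply(x$exon_starts, paste, character(1), collapse = ","),
    exon_ends = vapply(x$exon_ends, paste, character(1), collapse = ",")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname fixture-writers
#' @export
write_mirna_loci <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname fixture-writers
#' @export
write_bed <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end")], path, col_names = FALSE)
  invisible(path)
}

#' @rdname fixture-writers
#' @export
write_gene_list <- function(x, path) {
  readr::write_lines(as.character(x), path)
  invisible(path)
}
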