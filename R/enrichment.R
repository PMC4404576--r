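#' Observed per-family target counts in a gene set
#'
#' For every miRNA family in the background, counts how many genes of the set
#' are predicted targets (the observed statistic m_A). Families with no
#' target in the set are kept with a count of zero; the total over families
#' (T_set) is recorded as an attribute and drives the scaling correction.
#'
#' @param gene_set A `mir_geneset` from [restrict_to_background()], or an
#'   integer vector of gene ids (silently intersected with the universe).
#' @param background A `mir_background`.
#' @return Tibble `family_id`, `m`, `target_pct` with attributes `T_set`
#'   and `N`.
#' @export
count_targets <- function(gene_set, background) {
  genes <- if (inherits(gene_set, "mir_geneset")) {
    gene_set$background_genes
  } else {
    intersect(unique(as.integer(gene_set)), gene_universe(background))
  }
  fam <- families(background)
  hit <- background[background$gene_id %in% genes, , drop = FALSE]
  counts <- table(factor(hit$family_id, levels = fam))
  n <- length(genes)
  out <- tibble::tibble(
    family_id = fam,
    m = as.integer(counts),
    target_pct = if (n > 0L) 100 * as.integer(counts) / n else 0
  )
  attr(out, "T_set") <- sum(out$m)
  attr(out, "N") <- n
  out
}

#' Draw a uniform random gene set from the background universe
#'
#' Samples `n` distinct genes without replacement from the genes with at
#' least one predicted site. Uses the current RNG stream, so wrap in a seed
#' for reproducibility.
#'
#' @param background A `mir_background`.
#' @param n Number of genes to draw.
#' @return Integer vector of `n` gene ids.
#' @export
sample_random_set <- function(background, n) {
  universe <- gene_universe(background)
  if (n > length(universe)) {
    rlang::abort(sprintf("cannot draw %d genes from a universe of %d", n, length(universe)))
  }
  if (n == 0L) return(integer(0))
  universe[sample.int(length(universe), n)]
}

# 0/1 incidence matrix of the background: genes (rows) x families (columns)
incidence_matrix <- function(background) {
  universe <- gene_universe(background)
  fam <- families(background)
  M <- matrix(0L, nrow = length(universe), ncol = length(fam),
              dimnames = list(as.character(universe), fam))
  M[cbind(match(background$gene_id, universe), match(background$family_id, fam))] <- 1L
  M
}

#' Monte-Carlo over-representation p-values with scaling correction
#'
#' For each of `n_reps` repetitions a random gene set of size `n` is drawn
#' from the background universe and its per-family target count z_A is
#' scaled by the ratio of the observed total target count to the random
#' set's total (T_set / T_rand). A repetition counts against family A when
#' the scaled z_A reaches or exceeds the observed m_A; the p-value is the
#' add-one estimator (1 + successes) / (n_reps + 1), so p is never zero.
#' Repetitions whose random set has no targets at all define a ratio of 0.
#'
#' The scaling neutralises gene-set-level confounders: a set of genes with,
#' say, longer-than-average 3'UTRs carries more predicted targets for every
#' family, which would otherwise inflate all m_A relative to the null.
#'
#' @param observed Tibble from [count_targets()].
#' @param background A `mir_background`.
#' @param n Size of each random set (the gene set's N).
#' @param n_reps Number of repetitions (any positive integer here; the
#'   command line restricts to 1000, 10000 or 100000).
#' @param correct Apply the T_set/T_rand scaling (default). `FALSE` forces
#'   the ratio to 1 — the uncorrected variant, exposed for comparison.
#' @param seed Optional integer; when given, results are reproducible and
#'   the caller's RNG state is untouched.
#' @return Tibble `family_id`, `m`, `p_raw`.
#' @export
randomization_pvalues <- function(observed, background, n, n_reps = 10000L,
                                  correct = TRUE, seed = NULL) {
  assert_scalar_number(n_reps, "n_reps", min = 1)
  n_reps <- as.integer(n_reps)
  M <- incidence_matrix(background)
  G <- nrow(M)
  if (n > G) {
    rlang::abort(sprintf("random set size %d exceeds universe size %d", n, G))
  }
  m <- observed$m[match(colnames(M), observed$family_id)]
  T_set <- sum(m)
  successes <- with_seed(seed, {
    succ <- numeric(ncol(M))
    chunk <- 5000L
    done <- 0L
    while (done < n_reps) {
      k <- min(chunk, n_reps - done)
      # draws are sequential so chunking never changes the stream
      idx <- vapply(seq_len(k), function(i) sample.int(G, n), integer(n))
      Z <- rowsum(M[as.vector(idx), , drop = FALSE], group = rep(seq_len(k), each = n))
      T_rand <- rowSums(Z)
      ratio <- if (correct) ifelse(T_rand > 0, T_set / T_rand, 0) else rep(1, k)
      succ <- succ + colSums(Z * ratio >= rep(m, each = k))
      done <- done + k
    }
    succ
  })
  tibble::tibble(
    family_id = colnames(M),
    m = as.integer(m),
    p_raw = unname(1 + successes) / (n_reps + 1)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across all families tested,
#' delegated to [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Filter and order enrichment results by the two cutoffs
#'
#' Keeps families with FDR at or below `fdr_cutoff` whose observed target
#' count reaches `ceiling(min_target_pct/100 * N)`; both cutoffs are
#' inclusive. Results are ordered by ascending FDR, ties broken by
#' descending m then family label.
#'
#' @param results Tibble with columns `family_id`, `m`, `fdr` (as produced
#'   inside [mir_enrich()]).
#' @param fdr_cutoff Inclusive FDR threshold.
#' @param min_target_pct Minimum required targets as a percentage of N.
#' @param N Gene-set size in the background.
#' @return The over-represented sublist, sorted.
#' @export
apply_cutoffs <- function(results, fdr_cutoff = 0.05, min_target_pct = 0, N) {
  min_m <- ceiling(min_target_pct / 100 * N)
  out <- dplyr::filter(results, .data$fdr <= fdr_cutoff, .data$m >= min_m)
  dplyr::arrange(out, .data$fdr, dplyr::desc(.data$m), .data$family_id)
}

#' Test a gene set for miRNA-family target over-representation
#'
#' The full pipeline on an already-mapped gene set: restrict to the
#' background, count observed targets per family, compute randomization
#' p-values with the scaling correction, adjust with Benjamini-Hochberg,
#' and flag over-represented families by the two inclusive cutoffs.
#'
#' @param genes Integer vector of Entrez ids, a [map_gene_ids()] result, or
#'   a `mir_geneset` already restricted to the background.
#' @param background A `mir_background` from [build_background()].
#' @param n_reps Number of random sets (1000, 10000 or 100000 at the
#'   command line; any positive integer here).
#' @param fdr_cutoff Inclusive FDR threshold for calling over-representation.
#' @param min_target_pct Minimum targets per family as a percentage of N.
#' @param seed Integer seed; identical inputs, configuration and seed give
#'   an identical result table.
#' @param correct Apply the total-target scaling correction (default TRUE).
#' @param min_n,max_n Inclusive bounds on the background-restricted size N.
#' @return A `mir_enrichment` object. `tidy()` returns the per-family
#'   table (`family_id`, `m`, `target_pct`, `p_raw`, `fdr`,
#'   `over_represented`), `glance()` a one-row run summary, and
#'   `autoplot()` an enrichment plot.
#' @examples
#' sim <- simulate_background(n_genes = 40, n_families = 6, base_density = 0.4, seed = 1)
#' bg <- build_background(sim$predictions)
#' set <- simulate_gene_set(bg, target_family = "miR-01", n_set = 25,
#'                          enrichment_prob = 1, seed = 2)
#' fit <- mir_enrich(set$genes, bg, n_reps = 1000, seed = 3)
#' tidy(fit)
#' @export
mir_enrich <- function(genes, background, n_reps = 10000L, fdr_cutoff = 0.05,
                       min_target_pct = 0, seed = NULL, correct = TRUE,
                       min_n = 20L, max_n = 4000L) {
  gs <- if (inherits(genes, "mir_geneset")) {
    genes
  } else {
    restrict_to_background(genes, background, min_n = min_n, max_n = max_n)
  }
  observed <- count_targets(gs, background)
  pvals <- randomization_pvalues(observed, background, n = gs$N, n_reps = n_reps,
                                 correct = correct, seed = seed)
  results <- dplyr::left_join(observed, pvals[, c("family_id", "p_raw")], by = "family_id")
  results$fdr <- bh_adjust(results$p_raw)
  min_m <- ceiling(min_target_pct / 100 * gs$N)
  results$over_represented <- results$fdr <= fdr_cutoff & results$m >= min_m
  results <- dplyr::arrange(results, .data$fdr, dplyr::desc(.data$m), .data$family_id)
  structure(
    list(
      results = tibble::as_tibble(results),
      gene_set = gs,
      config = list(n_reps = as.integer(n_reps), fdr_cutoff = fdr_cutoff,
                    min_target_pct = min_target_pct, seed = seed, correct = correct),
      T_set = attr(observed, "T_set"),
      n_families = length(families(background))
    ),
    class = "mir_enrichment"
  )
}

#' Target pairs for the over-represented families
#'
#' The (family, gene) pairs between the input gene set and the families
#' called over-represented — the companion table for downstream analyses of
#' the targets of an enriched family.
#'
#' @param object A `mir_enrichment`.
#' @param background The `mir_background` the fit was run against.
#' @return Tibble `family_id`, `gene_id`.
#' @export
enriched_pairs <- function(object, background) {
  over <- object$results$family_id[object$results$over_represented]
  out <- background[background$family_id %in% over &
                      background$gene_id %in% object$gene_set$background_genes, ,
                    drop = FALSE]
  dplyr::arrange(tibble::as_tibble(out), .data$family_id, .data$gene_id)
}

#' @export
print.mir_enrichment <- function(x, ...) {
  cat(sprintf("<mir_enrichment> N = %d genes, %d families, %d reps (seed %s)\n",
              x$gene_set$N, x$n_families, x$config$n_reps,
              x$config$seed %||% "unset"))
  n_over <- sum(x$results$over_represented)
  cat(sprintf("%d over-represented at FDR <= %g", n_over, x$config$fdr_cutoff))
  if (x$config$min_target_pct > 0) {
    cat(sprintf(" and m >= %g%% of N", x$config$min_target_pct))
  }
  cat("\n")
  if (n_over > 0) print(utils::head(x$results[x$results$over_represented, ], 10))
  invisible(x)
}
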