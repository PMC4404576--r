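# Shared fixture builders and independent oracles.
# Oracles deliberately use brute-force formulations (all-pairs scans, subset
# enumeration, hand-rolled step-up) so they stay independent of the package's
# vectorised implementations.

# Prediction tibble straight from a pairs table (one transcript per gene
# unless tx_per_gene says otherwise).
toy_predictions <- function(pairs, species = "human", tx_per_gene = 1L) {
  rows <- pairs[rep(seq_len(nrow(pairs)), each = tx_per_gene), , drop = FALSE]
  rows$tx <- rep(seq_len(tx_per_gene), times = nrow(pairs))
  tibble::tibble(
    family_id = rows$family_id,
    transcript_id = sprintf("NM_%d_%d", rows$gene_id, rows$tx),
    gene_id = as.integer(rows$gene_id),
    species = species,
    conservation = "conserved"
  )
}

toy_background <- function(pairs, ...) {
  build_background(toy_predictions(pairs, ...))
}

# A small random background: each (family, gene) pair present with prob p.
random_pairs <- function(n_genes, n_families, p, seed) {
  withr::with_seed(seed, {
    grid <- expand.grid(
      family_id = sprintf("miR-%02d", seq_len(n_families)),
      gene_id = 1000L + seq_len(n_genes),
      stringsAsFactors = FALSE
    )
    tibble::as_tibble(grid[stats::runif(nrow(grid)) < p, ])
  })
}

# Exact over-representation p-values by enumerating every n-subset of the
# universe, with the same scaled >= comparison rule as the implementation.
exact_pvalues <- function(background, gene_set) {
  universe <- gene_universe(background)
  fams <- families(background)
  genes <- intersect(gene_set, universe)
  n <- length(genes)
  count_by_family <- function(set) {
    hit <- background$gene_id %in% set
    as.integer(table(factor(background$family_id[hit], levels = fams)))
  }
  m <- count_by_family(genes)
  T_set <- sum(m)
  subsets <- utils::combn(universe, n)
  succ <- numeric(length(fams))
  for (j in seq_len(ncol(subsets))) {
    z <- count_by_family(subsets[, j])
    T_rand <- sum(z)
    ratio <- if (T_rand > 0) T_set / T_rand else 0
    succ <- succ + (z * ratio >= m)
  }
  stats::setNames(succ / ncol(subsets), fams)
}

# All-pairs nearest-TSS oracle (O(P*G)): returns the assigned gene id per
# peak (NA for orphans), smallest gene id on distance ties.
oracle_nearest <- function(peaks, gene_models, window_kb) {
  mid <- floor((peaks$start + peaks$end) / 2)
  vapply(seq_len(nrow(peaks)), function(i) {
    g <- gene_models[gene_models$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) return(NA_integer_)
    d <- abs(mid[i] - g$tss)
    if (min(d) > window_kb * 1000) return(NA_integer_)
    min(g$gene_id[d == min(d)])
  }, integer(1))
}

# All-pairs peak-to-miRNA-locus minimum-gap oracle.
oracle_feedback <- function(peaks, loci, window_kb) {
  mid <- floor((peaks$start + peaks$end) / 2)
  out <- lapply(seq_len(nrow(loci)), function(i) {
    dmin <- Inf
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != loci$chrom[i]) next
      m <- mid[j]
      d <- if (m >= loci$start[i] && m < loci$end[i]) 0 else
        min(abs(m - loci$start[i]), abs(m - (loci$end[i] - 1)))
      dmin <- min(dmin, d)
    }
    c(name = loci$mirna_name[i], d = dmin)
  })
  df <- data.frame(
    mirna_name = vapply(out, `[[`, character(1), "name"),
    distance = as.numeric(vapply(out, `[[`, character(1), "d"))
  )
  df <- stats::aggregate(distance ~ mirna_name, df, min)
  df <- df[df$distance <= window_kb * 1000, , drop = FALSE]
  df[order(df$distance, df$mirna_name), , drop = FALSE]
}

# Hand-rolled Benjamini-Hochberg step-up: fdr_(i) = min_{j >= i} p_(j)*k/j.
oracle_bh <- function(p) {
  k <- length(p)
  o <- order(p)
  adj <- numeric(k)
  running <- Inf
  for (i in rev(seq_len(k))) {
    running <- min(running, p[o[i]] * k / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}
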