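#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-family enrichment table
#'
#' @param x A `mir_enrichment` from [mir_enrich()].
#' @param ... Unused.
#' @return Tibble `family_id`, `m`, `target_pct`, `p_raw`, `fdr`,
#'   `over_represented`, sorted by ascending FDR.
#' @export
tidy.mir_enrichment <- function(x, ...) {
  x$results
}

#' One-row summary of an enrichment run
#'
#' @param x A `mir_enrichment`.
#' @param ... Unused.
#' @return Tibble with `N`, `n_families`, `T_set`, `n_over_represented`,
#'   `n_reps`, `fdr_cutoff`, `min_target_pct`, `seed`.
#' @export
glance.mir_enrichment <- function(x, ...) {
  tibble::tibble(
    N = x$gene_set$N,
    n_families = x$n_families,
    T_set = x$T_set,
    n_over_represented = sum(x$results$over_represented),
    n_reps = x$config$n_reps,
    fdr_cutoff = x$config$fdr_cutoff,
    min_target_pct = x$config$min_target_pct,
    seed = x$config$seed %||% NA_integer_
  )
}

#' Tidy a peak-gene association
#'
#' @param x A `mir_association`.
#' @param ... Unused.
#' @return One row per input peak; `gene_id`, `method_tag` and `distance`
#'   are `NA` for orphan peaks.
#' @export
tidy.mir_association <- function(x, ...) {
  orphans <- x$orphan_peaks
  if (nrow(orphans) > 0L) {
    orphans$gene_id <- NA_integer_
    orphans$method_tag <- NA_character_
    orphans$distance <- NA_integer_
  }
  dplyr::bind_rows(x$peak_to_gene, orphans)
}

#' Enrichment plot: per-family target percentage against FDR
#'
#' Each point is one miRNA family; over-represented families are
#' highlighted and the FDR cutoff drawn as a dashed line.
#'
#' @param object A `mir_enrichment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mir_enrichment <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_pct, y = -log10(.data$fdr),
                                   colour = .data$over_represented)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(object$config$fdr_cutoff),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
                                 name = "over-represented") +
    ggplot2::labs(x = "targets in gene set (% of N)",
                  y = expression(-log[10] ~ FDR),
                  title = "miRNA-family target over-representation") +
    ggplot2::theme_minimal()
}

#' Peak-association plot: assignment distances by method tag
#'
#' @param object A `mir_association`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mir_association <- function(object, ...) {
  df <- object$peak_to_gene
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, fill = .data$method_tag)) +
    ggplot2::geom_histogram(bins = 30, colour = "white") +
    ggplot2::labs(x = "peak midpoint to TSS distance (bp)", y = "peaks",
                  fill = "assignment") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
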