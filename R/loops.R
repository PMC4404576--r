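#' Read a miRNA gene-locus table
#'
#' Tab-separated with header
#' `mirna_name  family_id  chrom  strand  start  end` (0-based half-open
#' gene coordinates; a projection of a miRBase-style GFF3). `family_id` may
#' be empty when the miRNA belongs to no tested family.
#'
#' @param path Path to the TSV file.
#' @return Tibble with the six columns; empty family labels become `NA`.
#' @export
read_mirna_loci <- function(path) {
  assert_file_exists(path)
  loci <- readr::read_tsv(path, col_types = readr::cols(
    mirna_name = readr::col_character(),
    family_id = readr::col_character(),
    chrom = readr::col_character(),
    strand = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer()
  ), progress = FALSE, na = c("", "NA"))
  if (any(loci$start >= loci$end)) {
    rlang::abort("miRNA locus with start >= end")
  }
  loci
}

#' Feedforward loops: over-represented families that target the master
#'
#' A miRNA family that is over-represented in the master regulator's gene
#' set and is itself predicted to target the master closes a feedforward
#' loop of type 2 (whether coherent or incoherent depends on regulatory
#' signs this tool does not compute). Returns exactly the over-represented
#' families with a predicted site on the master gene.
#'
#' @param over_represented Character vector of over-represented family ids.
#' @param master_gene Entrez id of the master transcription factor.
#' @param background A `mir_background`.
#' @return Character vector (subset of `over_represented`, original order).
#'   Empty, with a warning, when the master has no predicted sites at all.
#' @export
find_feedforward <- function(over_represented, master_gene, background) {
  master_gene <- as.integer(master_gene)
  if (!master_gene %in% gene_universe(background)) {
    rlang::warn(sprintf("master gene %d has no predicted miRNA binding sites", master_gene))
    return(character(0))
  }
  master_families <- background$family_id[background$gene_id == master_gene]
  over_represented[over_represented %in% master_families]
}

#' Negative feedback: miRNA genes with a master peak close by
#'
#' A miRNA transcriptionally controlled by the master while its family
#' targets the master (or its regulon) closes a negative feedback loop.
#' This reports every miRNA gene that has a peak midpoint within
#' `window_kb` kilobases: distance 0 when the midpoint falls inside the
#' locus, otherwise the gap to the nearest locus edge. Each miRNA appears
#' once with its minimum distance.
#'
#' @param peaks Tibble from [read_bed()] (peaks of the master factor).
#' @param loci Tibble from [read_mirna_loci()].
#' @param window_kb Window in kb (5, 10 or 20 at the command line).
#' @return Tibble `mirna_name`, `distance`, sorted by distance then name.
#' @export
find_feedback <- function(peaks, loci, window_kb = 10) {
  if (is.null(loci) || nrow(loci) == 0L) {
    rlang::abort("empty miRNA locus table")
  }
  window_bp <- window_kb * 1000
  mid <- peak_midpoint(peaks)
  per_locus <- purrr::pmap_dbl(
    list(loci$chrom, loci$start, loci$end),
    function(ch, s, e) {
      m <- mid[peaks$chrom == ch]
      if (length(m) == 0L) return(Inf)
      inside <- m >= s & m < e
      if (any(inside)) return(0)
      min(pmin(abs(m - s), abs(m - (e - 1L))))
    }
  )
  hits <- tibble::tibble(mirna_name = loci$mirna_name, distance = per_locus)
  hits <- dplyr::summarise(dplyr::group_by(hits, .data$mirna_name),
                           distance = min(.data$distance), .groups = "drop")
  hits <- dplyr::filter(hits, .data$distance <= window_bp)
  dplyr::arrange(hits, .data$distance, .data$mirna_name)
}
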