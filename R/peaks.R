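#' Read a BED file of ChIP-seq peaks
#'
#' Parses BED3+ records; `track`, `browser` and `#` lines are skipped and
#' columns beyond the third are ignored. Coordinates stay 0-based half-open.
#'
#' @param path Path to the BED file.
#' @param source_index Which of the 1-3 uploaded files this is; recorded per
#'   peak so multi-dataset support can be counted per file.
#' @return Tibble `chrom`, `start`, `end`, `source_index`.
#' @export
read_bed <- function(path, source_index = 1L) {
  assert_file_exists(path)
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & trimws(lines) != ""
  body <- lines[keep]
  if (length(body) == 0L) {
    rlang::abort(sprintf("no peaks parsed from %s", path))
  }
  line_no <- which(keep)
  fields <- strsplit(body, "[ \t]+")
  n_col <- lengths(fields)
  if (any(n_col < 3L)) {
    rlang::abort(sprintf("line %d of %s has fewer than 3 columns",
                         line_no[which(n_col < 3L)[1]], path))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    rlang::abort(sprintf("non-integer coordinate at line %d of %s", line_no[bad[1]], path))
  }
  rev <- which(start >= end)
  if (length(rev) > 0L) {
    rlang::abort(sprintf("start >= end at line %d of %s", line_no[rev[1]], path))
  }
  tibble::tibble(chrom = chrom, start = start, end = end,
                 source_index = as.integer(source_index))
}

#' Read a gene-model table
#'
#' Tab-separated with header
#' `gene_id  chrom  strand  tx_start  tx_end  exon_starts  exon_ends`
#' (coordinate lists comma-separated, BED12-like, 0-based half-open).
#' When a gene has several transcript rows the representative (longest
#' span, then smallest start) is kept, so each gene contributes one TSS.
#' The strand-aware TSS and first intron (between exon 1 and exon 2 in
#' transcription order; absent for single-exon genes) are derived.
#'
#' @param path Path to the TSV file.
#' @return Tibble `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`,
#'   `tss`, `exon_starts`/`exon_ends` (list columns), `fi_start`/`fi_end`
#'   (`NA` when no first intron exists).
#' @export
read_gene_models <- function(path) {
  assert_file_exists(path)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_integer(),
    chrom = readr::col_character(),
    strand = readr::col_character(),
    tx_start = readr::col_integer(),
    tx_end = readr::col_integer(),
    exon_starts = readr::col_character(),
    exon_ends = readr::col_character()
  ), progress = FALSE)
  parse_list <- function(x) lapply(strsplit(x, ","), function(v) as.integer(v[v != ""]))
  raw$exon_starts <- parse_list(raw$exon_starts)
  raw$exon_ends <- parse_list(raw$exon_ends)
  finish_gene_models(raw)
}

# Derive TSS / first intron and keep one representative transcript per gene.
finish_gene_models <- function(gm) {
  if (!all(gm$strand %in% c("+", "-"))) {
    rlang::abort("gene-model strand must be '+' or '-'")
  }
  bad <- which(lengths(gm$exon_starts) != lengths(gm$exon_ends))
  if (length(bad) > 0L) {
    rlang::abort(sprintf("gene %d has mismatched exon coordinate lists", gm$gene_id[bad[1]]))
  }
  gm <- dplyr::mutate(gm, .span = .data$tx_end - .data$tx_start)
  gm <- dplyr::arrange(gm, .data$gene_id, dplyr::desc(.data$.span), .data$tx_start)
  gm <- dplyr::distinct(gm, .data$gene_id, .keep_all = TRUE)
  gm$.span <- NULL
  gm$tss <- ifelse(gm$strand == "+", gm$tx_start, gm$tx_end - 1L)
  fi <- purrr::pmap(list(gm$exon_starts, gm$exon_ends, gm$strand), function(es, ee, st) {
    k <- length(es)
    if (k < 2L) return(c(NA_integer_, NA_integer_))
    if (st == "+") c(ee[1], es[2]) else c(ee[k - 1L], es[k])
  })
  gm$fi_start <- vapply(fi, `[[`, integer(1), 1L)
  gm$fi_end <- vapply(fi, `[[`, integer(1), 2L)
  tibble::as_tibble(gm)
}

peak_midpoint <- function(peaks) {
  as.integer(floor((peaks$start + peaks$end) / 2))
}

new_association <- function(peaks, assigned_gene, method_tag, distance,
                            method, params = list()) {
  stopifnot(nrow(peaks) == length(assigned_gene))
  tab <- dplyr::bind_cols(
    tibble::as_tibble(peaks),
    tibble::tibble(gene_id = assigned_gene, method_tag = method_tag, distance = distance)
  )
  structure(
    list(
      peak_to_gene = tab[!is.na(tab$gene_id), , drop = FALSE],
      orphan_peaks = tab[is.na(tab$gene_id), names(peaks), drop = FALSE],
      genes = sort(unique(assigned_gene[!is.na(assigned_gene)])),
      method = method,
      params = params
    ),
    class = "mir_association"
  )
}

#' @export
print.mir_association <- function(x, ...) {
  cat(sprintf("<mir_association> method '%s': %d/%d peaks assigned to %d genes (%d orphans)\n",
              x$method, nrow(x$peak_to_gene),
              nrow(x$peak_to_gene) + nrow(x$orphan_peaks),
              length(x$genes), nrow(x$orphan_peaks)))
  invisible(x)
}

#' Assign peaks to the nearest gene TSS within a window
#'
#' Each peak is represented by its interval midpoint and assigned to the
#' single gene, on the same chromosome, whose TSS is closest — provided the
#' unsigned distance is at most `window_kb` kilobases. Ties go to the
#' smaller gene id; peaks with no gene in range are orphans.
#'
#' @param peaks Tibble from [read_bed()].
#' @param gene_models Tibble from [read_gene_models()].
#' @param window_kb Window half-width in kb (5, 10 or 20 at the command
#'   line; any positive value here).
#' @return A `mir_association` object; `tidy()` gives one row per peak with
#'   `gene_id` `NA` for orphans.
#' @export
associate_nearest <- function(peaks, gene_models, window_kb = 10) {
  if (is.null(gene_models) || nrow(gene_models) == 0L) {
    rlang::abort("empty gene-model list")
  }
  assert_scalar_number(window_kb, "window_kb", min = 1e-9)
  window_bp <- window_kb * 1000
  mid <- peak_midpoint(peaks)
  gene <- rep(NA_integer_, nrow(peaks))
  dist <- rep(NA_integer_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    g <- gene_models[gene_models$chrom == ch, , drop = FALSE]
    p_idx <- which(peaks$chrom == ch)
    if (nrow(g) == 0L) next
    # sorted-TSS neighbour search; ties at equal distance -> smaller gene_id,
    # guaranteed because ties within one TSS value resolve to its first
    # (smallest-id) occurrence in this ordering
    o <- order(g$tss, g$gene_id)
    ts <- g$tss[o]
    gid <- g$gene_id[o]
    first_at <- function(v) findInterval(v - 1L, ts) + 1L  # first index with ts == v
    j <- findInterval(mid[p_idx], ts)
    n_g <- length(ts)
    for (k in seq_along(p_idx)) {
      i <- p_idx[k]
      jl <- j[k]
      d_left <- if (jl >= 1L) mid[i] - ts[jl] else Inf
      d_right <- if (jl < n_g) ts[jl + 1L] - mid[i] else Inf
      d_min <- min(d_left, d_right)
      if (d_min > window_bp) next
      cand <- integer(0)
      if (d_left == d_min) cand <- c(cand, gid[first_at(mid[i] - d_min)])
      if (d_right == d_min) cand <- c(cand, gid[first_at(mid[i] + d_min)])
      gene[i] <- min(cand)
      dist[i] <- as.integer(d_min)
    }
  }
  new_association(peaks, gene,
                  method_tag = ifelse(is.na(gene), NA_character_, "nearest"),
                  distance = dist, method = "nearest",
                  params = list(window_kb = window_kb))
}

#' Assign peaks to genes by ranked promoter / first-intron membership
#'
#' Transcription-factor binding concentrates in the core promoter and the
#' first intron, so a peak midpoint inside a gene's strand-aware core
#' promoter window (`tss - upstream` to `tss + downstream`, orientation
#' flipped on the minus strand) is assigned with tag `"promoter"`; failing
#' that, a midpoint inside the first intron gets tag `"first_intron"`.
#' Promoter membership outranks first-intron membership; among equal-rank
#' candidates the nearest TSS wins, ties by smaller gene id.
#'
#' @param peaks Tibble from [read_bed()].
#' @param gene_models Tibble from [read_gene_models()]; exon structure is
#'   required for the intron test.
#' @param promoter_upstream,promoter_downstream Core-promoter window in bp
#'   around the TSS (defaults 1000 up, 500 down).
#' @return A `mir_association` object.
#' @export
associate_ranked <- function(peaks, gene_models,
                             promoter_upstream = 1000L, promoter_downstream = 500L) {
  if (is.null(gene_models) || nrow(gene_models) == 0L) {
    rlang::abort("empty gene-model list")
  }
  gm <- gene_models
  plus <- gm$strand == "+"
  gm$p_lo <- ifelse(plus, gm$tss - promoter_upstream, gm$tss - promoter_downstream)
  gm$p_hi <- ifelse(plus, gm$tss + promoter_downstream, gm$tss + promoter_upstream)
  pk <- tibble::as_tibble(peaks)
  pk$.peak <- seq_len(nrow(pk))
  pk$.mid <- peak_midpoint(pk)
  cand <- dplyr::inner_join(
    pk,
    gm[, c("gene_id", "chrom", "tss", "p_lo", "p_hi", "fi_start", "fi_end")],
    by = "chrom", relationship = "many-to-many"
  )
  in_prom <- cand$.mid >= cand$p_lo & cand$.mid <= cand$p_hi
  in_intron <- !is.na(cand$fi_start) & cand$.mid >= cand$fi_start & cand$.mid < cand$fi_end
  cand$rank <- ifelse(in_prom, 1L, ifelse(in_intron, 2L, NA_integer_))
  cand <- cand[!is.na(cand$rank), , drop = FALSE]
  cand$distance <- abs(cand$.mid - cand$tss)
  cand <- dplyr::arrange(cand, .data$.peak, .data$rank, .data$distance, .data$gene_id)
  best <- cand[!duplicated(cand$.peak), , drop = FALSE]
  gene <- rep(NA_integer_, nrow(pk))
  dist <- rep(NA_integer_, nrow(pk))
  tag <- rep(NA_character_, nrow(pk))
  gene[best$.peak] <- best$gene_id
  dist[best$.peak] <- as.integer(best$distance)
  tag[best$.peak] <- ifelse(best$rank == 1L, "promoter", "first_intron")
  new_association(peaks, gene, method_tag = tag, distance = dist,
                  method = "ranked",
                  params = list(promoter_upstream = promoter_upstream,
                                promoter_downstream = promoter_downstream))
}

#' Combine gene sets from several peak files
#'
#' With a single dataset the associated gene set passes through unchanged;
#' with two or three, only genes supported by at least `min_support`
#' distinct files are kept (several peaks from one file near one gene count
#' once).
#'
#' @param results List of 1-3 `mir_association` objects (or plain gene-id
#'   vectors).
#' @param min_support Minimum number of distinct files; applies only when
#'   more than one result is supplied.
#' @return Sorted integer vector of gene ids.
#' @export
combine_datasets <- function(results, min_support = 2L) {
  if (length(results) == 0L) {
    rlang::abort("no association results supplied")
  }
  gene_sets <- lapply(results, function(r) {
    if (inherits(r, "mir_association")) r$genes else sort(unique(as.integer(r)))
  })
  if (length(gene_sets) == 1L) {
    return(gene_sets[[1]])
  }
  support <- table(unlist(lapply(gene_sets, unique)))
  sort(as.integer(names(support)[support >= min_support]))
}
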