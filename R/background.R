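#' Read a conserved miRNA target-prediction table
#'
#' Reads a tab-separated table of per-transcript miRNA-family target
#' predictions (the column-reduced projection of a TargetScan-style
#' "conserved family info" file) and keeps rows whose conservation flag is in
#' an accepted set. Expected header:
#' `family_id  transcript_id  gene_id  species  conservation`.
#'
#' @param path Path to the TSV file.
#' @param species Species the table must describe, `"human"` or `"mouse"`.
#' @param conservation_keep Character vector of accepted conservation flags;
#'   rows with any other flag are dropped.
#' @return A tibble with columns `family_id`, `transcript_id`, `gene_id`
#'   (integer), `species`, `conservation`, one row per retained prediction.
#'   Duplicate (family, transcript) rows are preserved; gene-level pooling
#'   happens in [build_background()].
#' @seealso [build_background()]
#' @export
read_predictions <- function(path,
                             species = c("human", "mouse"),
                             conservation_keep = c("conserved", "broadly conserved")) {
  species <- match.arg(species)
  assert_file_exists(path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("family_id", "transcript_id", "gene_id", "species", "conservation")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("prediction table is missing columns: %s",
                         paste(missing, collapse = ", ")))
  }
  gene_id <- suppressWarnings(as.integer(raw$gene_id))
  bad <- which(is.na(gene_id) | gene_id <= 0L | is.na(raw$family_id) | raw$family_id == "")
  if (length(bad) > 0L) {
    # +1 for the header line so the message points at the file line
    rlang::abort(sprintf("malformed prediction row at line %d of %s",
                         bad[1] + 1L, path))
  }
  other <- setdiff(unique(raw$species), species)
  if (length(other) > 0L) {
    rlang::abort(sprintf("prediction table contains species %s but `%s` was requested",
                         paste(shQuote(other), collapse = ", "), species))
  }
  out <- dplyr::mutate(raw, gene_id = gene_id)
  dplyr::filter(out, .data$conservation %in% conservation_keep)
}

#' Read a gene-identifier mapping table
#'
#' One row per transcript with header
#' `entrez_id  symbol  ensembl_gene  refseq_transcript`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the four columns above, `entrez_id` integer.
#' @export
read_idmap <- function(path) {
  assert_file_exists(path)
  idmap <- readr::read_tsv(path, col_types = readr::cols(
    entrez_id = readr::col_integer(),
    symbol = readr::col_character(),
    ensembl_gene = readr::col_character(),
    refseq_transcript = readr::col_character()
  ), progress = FALSE)
  if (anyNA(idmap$entrez_id)) {
    rlang::abort("idmap rows must all carry an entrez_id")
  }
  idmap
}

#' Build the unique-pair prediction background
#'
#' Pools predictions across all isoforms of a gene and collects the universe
#' of unique (miRNA family, gene) pairs. This background defines both the
#' set of families tested and the gene universe from which random sets are
#' drawn: genes without any predicted site are outside it.
#'
#' @param predictions Tibble from [read_predictions()]; rows carrying an
#'   `NA` gene id are resolved through `idmap` (by `refseq_transcript`) when
#'   one is supplied, otherwise dropped with a warning.
#' @param idmap Optional tibble from [read_idmap()] used to resolve
#'   transcript accessions that lack a gene id.
#' @return A `mir_background` object: a tibble of unique
#'   (`family_id`, `gene_id`) pairs with the species recorded as an
#'   attribute.
#' @examples
#' preds <- tibble::tibble(
#'   family_id = c("miR-1", "miR-1", "miR-2"),
#'   transcript_id = c("tx1", "tx2", "tx1"),
#'   gene_id = c(10L, 10L, 10L),
#'   species = "human", conservation = "conserved"
#' )
#' bg <- build_background(preds)
#' family_counts(bg)
#' @export
build_background <- function(predictions, idmap = NULL) {
  if (is.null(predictions) || nrow(predictions) == 0L) {
    rlang::abort("empty background: no predictions supplied")
  }
  preds <- predictions
  if (anyNA(preds$gene_id)) {
    if (!is.null(idmap)) {
      lut <- stats::setNames(idmap$entrez_id, idmap$refseq_transcript)
      miss <- is.na(preds$gene_id)
      preds$gene_id[miss] <- unname(lut[preds$transcript_id[miss]])
    }
    unresolved <- is.na(preds$gene_id)
    if (any(unresolved)) {
      rlang::warn(sprintf("%d prediction rows could not be resolved to a gene and were dropped",
                          sum(unresolved)))
      preds <- preds[!unresolved, , drop = FALSE]
    }
  }
  if (nrow(preds) == 0L) {
    rlang::abort("empty background: no resolvable predictions")
  }
  pairs <- dplyr::distinct(preds, .data$family_id, .data$gene_id)
  pairs <- dplyr::arrange(pairs, .data$family_id, .data$gene_id)
  new_background(pairs, species = if ("species" %in% names(preds)) preds$species[1] else NA_character_)
}

new_background <- function(pairs, species = NA_character_) {
  out <- tibble::as_tibble(pairs[, c("family_id", "gene_id")])
  attr(out, "species") <- species
  class(out) <- c("mir_background", class(out))
  out
}

#' @export
print.mir_background <- function(x, ...) {
  cat(sprintf("<mir_background> %d unique pairs, %d families, %d genes (%s)\n",
              nrow(x), length(families(x)), length(gene_universe(x)),
              attr(x, "species") %||% "species unknown"))
  NextMethod()
}

#' Families, gene universe and per-family target counts of a background
#'
#' @param background A `mir_background` from [build_background()].
#' @return `families()` gives the sorted family labels; `gene_universe()` the
#'   sorted integer gene ids with at least one predicted site;
#'   `family_counts()` a tibble `family_id`, `n_targets`.
#' @export
families <- function(background) {
  sort(unique(background$family_id))
}

#' @rdname families
#' @export
gene_universe <- function(background) {
  sort(unique(background$gene_id))
}

#' @rdname families
#' @export
family_counts <- function(background) {
  dplyr::count(tibble::as_tibble(background), .data$family_id, name = "n_targets")
}

#' Map user gene identifiers to Entrez ids
#'
#' Entrez tokens are parsed directly; symbol lookup is case-insensitive;
#' Ensembl gene ids and RefSeq transcript accessions are matched exactly.
#' A token mapping to several Entrez ids contributes all of them. Mapped ids
#' are deduplicated; failures are reported, never fatal.
#'
#' @param tokens Character vector of raw user identifiers.
#' @param idmap Tibble from [read_idmap()]; unused for `namespace = "entrez"`.
#' @param namespace One of `"entrez"`, `"symbol"`, `"ensembl"`, `"refseq"`.
#' @return A list with `mapped` (sorted unique integer Entrez ids) and
#'   `unmapped` (unique tokens that resolved to nothing).
#' @export
map_gene_ids <- function(tokens, idmap = NULL,
                         namespace = c("entrez", "symbol", "ensembl", "refseq")) {
  namespace <- match.arg(namespace)
  tokens <- trimws(as.character(tokens))
  tokens <- tokens[tokens != ""]
  if (namespace == "entrez") {
    ids <- suppressWarnings(as.integer(tokens))
    ok <- !is.na(ids) & ids > 0L
    return(list(mapped = sort(unique(ids[ok])), unmapped = unique(tokens[!ok])))
  }
  if (is.null(idmap)) {
    rlang::abort(sprintf("an idmap is required for namespace '%s'", namespace))
  }
  key <- switch(namespace,
    symbol = tolower(idmap$symbol),
    ensembl = idmap$ensembl_gene,
    refseq = idmap$refseq_transcript
  )
  probe <- if (namespace == "symbol") tolower(tokens) else tokens
  hits <- purrr::map(probe, function(tok) unique(idmap$entrez_id[!is.na(key) & key == tok]))
  n_hit <- lengths(hits)
  expanded <- which(n_hit > 1L)
  if (length(expanded) > 0L) {
    rlang::inform(sprintf("%d token(s) map to multiple Entrez ids; all targets kept: %s",
                          length(expanded),
                          paste(unique(tokens[expanded]), collapse = ", ")))
  }
  list(
    mapped = sort(unique(unlist(hits))),
    unmapped = unique(tokens[n_hit == 0L])
  )
}

#' Restrict a mapped gene set to the prediction background
#'
#' Genes without predicted binding sites are excluded; the retained count `N`
#' must lie between `min_n` and `max_n` (both inclusive) for the analysis to
#' run.
#'
#' @param genes Integer vector of mapped Entrez ids (or a list as returned by
#'   [map_gene_ids()], in which case its `mapped` element is used).
#' @param background A `mir_background`.
#' @param min_n,max_n Inclusive bounds on `N`; defaults 20 and 4000.
#' @param validate Apply the bounds? Set `FALSE` to inspect an out-of-bounds
#'   set without erroring.
#' @return A `mir_geneset`: list with `mapped_genes`, `background_genes`,
#'   `N`, and `excluded` (tibble of dropped ids with a reason).
#' @export
restrict_to_background <- function(genes, background, min_n = 20L, max_n = 4000L,
                                   validate = TRUE) {
  if (is.list(genes) && !is.null(genes$mapped)) genes <- genes$mapped
  mapped <- sort(unique(as.integer(genes)))
  universe <- gene_universe(background)
  inside <- mapped[mapped %in% universe]
  dropped <- setdiff(mapped, inside)
  gs <- structure(
    list(
      mapped_genes = mapped,
      background_genes = inside,
      N = length(inside),
      excluded = tibble::tibble(
        gene_id = dropped,
        reason = rep("no predicted binding sites", length(dropped))
      )
    ),
    class = "mir_geneset"
  )
  if (validate) {
    if (gs$N < min_n) {
      rlang::abort(sprintf("gene set too small: N = %d (minimum %d)", gs$N, min_n),
                   class = "mirenrich_set_too_small", N = gs$N)
    }
    if (gs$N > max_n) {
      rlang::abort(sprintf("gene set too large: N = %d (maximum %d)", gs$N, max_n),
                   class = "mirenrich_set_too_large", N = gs$N)
    }
  }
  gs
}

#' @export
print.mir_geneset <- function(x, ...) {
  cat(sprintf("<mir_geneset> N = %d genes in background (%d mapped, %d excluded)\n",
              x$N, length(x$mapped_genes), nrow(x$excluded)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
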