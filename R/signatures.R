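#' Tissue-specific signature by intersection of up-lists
#'
#' The genes up-regulated in one stromal class against *every* other
#' stromal class: the intersection of the supplied up-lists (one per
#' competing class; three lists in a four-class design).
#'
#' @param up_lists List (>= 2) of character vectors of up-regulated
#'   genes, one per contrast of the focal class versus another class.
#' @return Sorted character vector: the intersection.
#' @export
tissue_specific_signature <- function(up_lists) {
  if (!is.list(up_lists) || length(up_lists) < 2L)
    stop("need >= 2 up-lists to intersect")
  sort(Reduce(intersect, lapply(up_lists, as.character)))
}

#' Lineage-core signature with staged provenance
#'
#' Intersects the per-tissue up-lists (each tissue class versus the
#' out-of-lineage population), then the resulting shared set with an
#' optional meta-analysis up-list and an optional externally derived
#' expression footprint. Empty optional stages are skipped and noted.
#' The sizes after every stage are recorded so the derivation flow can
#' be reported.
#'
#' @param tissue_up_lists Named list (>= 2) of up-lists, one per tissue
#'   class contrasted against the out-of-lineage population.
#' @param meta_up Optional up-list from an independent meta-analysis
#'   contrast (`NULL` to skip).
#' @param footprint Optional expression footprint gene set (`NULL` to
#'   skip).
#' @return List of class `core_signature`: `genes` (sorted), `stages`
#'   (data.frame stage/size), `skipped` (character).
#' @export
lineage_core_signature <- function(tissue_up_lists, meta_up = NULL,
                                   footprint = NULL) {
  if (!is.list(tissue_up_lists) || length(tissue_up_lists) < 2L)
    stop("need >= 2 tissue up-lists")
  core <- Reduce(intersect, lapply(tissue_up_lists, as.character))
  stages <- data.frame(stage = "tissue_intersection",
                       size = length(core), stringsAsFactors = FALSE)
  skipped <- character()
  if (is.null(meta_up) || !length(meta_up)) {
    skipped <- c(skipped, "meta_up")
    message("lineage_core_signature: meta-analysis list empty, skipped")
  } else {
    core <- intersect(core, as.character(meta_up))
    stages <- rbind(stages, data.frame(stage = "meta_intersection",
                                       size = length(core)))
  }
  if (is.null(footprint) || !length(footprint)) {
    skipped <- c(skipped, "footprint")
    message("lineage_core_signature: footprint empty, skipped")
  } else {
    core <- intersect(core, as.character(footprint))
    stages <- rbind(stages, data.frame(stage = "footprint_intersection",
                                       size = length(core)))
  }
  structure(list(genes = sort(core), stages = stages, skipped = skipped),
            class = "core_signature")
}

#' Hypergeometric marker-panel enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a gene list and
#' a marker panel: with universe size N, panel size K, list size n and
#' overlap k, `p = P(X >= k)` for X ~ Hypergeometric(N, K, n). Panel or
#' list members outside the universe are dropped with a warning, so the
#' universe must be stated explicitly.
#'
#' @param genes Gene list to test (e.g. an up-regulated set).
#' @param panel Marker panel gene set.
#' @param universe All genes considered (e.g. every gene on the array).
#' @param panel_name Label carried into the result.
#' @return Object of class `enrichment_result` with `panel`, `N`, `K`,
#'   `n`, `k`, `p`, `overlap` (gene ids).
#' @export
panel_enrichment <- function(genes, panel, universe,
                             panel_name = "panel") {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  genes <- unique(as.character(genes)); panel <- unique(as.character(panel))
  out_p <- setdiff(panel, universe)
  if (length(out_p)) {
    warning(length(out_p), " panel gene(s) outside the universe dropped")
    panel <- intersect(panel, universe)
  }
  out_g <- setdiff(genes, universe)
  if (length(out_g)) {
    warning(length(out_g), " list gene(s) outside the universe dropped")
    genes <- intersect(genes, universe)
  }
  N <- length(universe); K <- length(panel); n <- length(genes)
  overlap <- intersect(genes, panel)
  k <- length(overlap)
  p <- if (k == 0L) 1 else
    phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  structure(list(panel = panel_name, N = N, K = K, n = n, k = k,
                 p = min(p, 1), overlap = sort(overlap)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Enrichment '%s': overlap %d of list %d vs panel %d in universe %d, p = %.4g\n",
    x$panel, x$k, x$n, x$K, x$N, x$p))
  invisible(x)
}

#' Overlap report against published signatures
#'
#' For each published set: the overlapping members and their count.
#' Genes appearing in two or more published sets are flagged
#' (`multi_hit`), the usual convention for highlighting recurrently
#' reported genes.
#'
#' @param signature Non-empty character vector of gene ids.
#' @param collection A [gene_set_collection()] of published signatures.
#' @return Object of class `signature_report`: `summary` (data.frame
#'   set/set_size/overlap_size), `overlaps` (named list of gene
#'   vectors), `multi_hit` (genes overlapping >= 2 sets).
#' @export
overlap_report <- function(signature, collection) {
  signature <- unique(as.character(signature))
  if (!length(signature)) stop("signature is empty")
  stopifnot(is.list(collection), !is.null(names(collection)))
  overlaps <- lapply(collection, function(s)
    sort(intersect(signature, as.character(s))))
  hits <- table(unlist(overlaps))
  structure(list(
    summary = data.frame(set = names(collection),
                         set_size = lengths(collection),
                         overlap_size = lengths(overlaps),
                         row.names = NULL, stringsAsFactors = FALSE),
    overlaps = overlaps,
    multi_hit = sort(names(hits)[hits >= 2L])),
    class = "signature_report")
}
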