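# Secretome annotation summaries: flag fractions, ES-stratified annotation
# rates, multi-list overlaps, and hypergeometric tissue-panel enrichment.

#' Read an annotation flag table
#'
#' @param path TSV with columns `protein_id`, `secreted`, `signalp`,
#'   `tmh` (0/1 or TRUE/FALSE).
#' @return Data frame with logical flag columns.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "secreted", "signalp", "tmh")
  if (!all(need %in% names(df)))
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
  for (cn in c("secreted", "signalp", "tmh")) df[[cn]] <- as.logical(df[[cn]])
  df
}

flag_values <- function(ids, annotation, flag_expr) {
  idx <- match(ids, annotation$protein_id)
  switch(flag_expr,
         secreted = annotation$secreted[idx],
         signalp_or_tmh = annotation$signalp[idx] | annotation$tmh[idx],
         stop("unknown flag_expr: ", flag_expr))
}

#' Fraction of proteins carrying an annotation flag
#'
#' Computes the count and fraction of IDs flagged under `flag_expr`
#' (`"secreted"`, or `"signalp_or_tmh"` — the inclusive OR of the signal
#' peptide and transmembrane-helix predictions). Unannotated IDs count in
#' the denominator — an unannotated protein is not a secreted one — and
#' their number is reported separately. Duplicate IDs are collapsed with
#' a warning.
#'
#' @param ids Character vector of protein IDs.
#' @param annotation An annotation data frame ([read_annotation()]).
#' @param flag_expr `"secreted"` or `"signalp_or_tmh"`.
#' @return List `count`, `total`, `fraction`, `n_unannotated`.
#' @export
fraction_flagged <- function(ids, annotation, flag_expr = "signalp_or_tmh") {
  if (!length(ids)) stop("empty id list")
  if (anyDuplicated(ids)) {
    warning("duplicate IDs collapsed")
    ids <- unique(ids)
  }
  fl <- flag_values(ids, annotation, flag_expr)
  n_unann <- sum(is.na(fl))
  count <- sum(fl, na.rm = TRUE)
  list(count = count, total = length(ids),
       fraction = count / length(ids), n_unannotated = n_unann)
}

#' Annotation rate stratified by enrichment score
#'
#' For each ES level the fraction of proteins at that level carrying a
#' SignalP-or-TMH flag. Rising fractions with rising ES indicate that
#' high-ES strata are dominated by genuine secretory-pathway proteins.
#' Empty strata are reported with `NA` fraction (undefined, not zero).
#'
#' @param es_results An [enrichment_score()] data frame.
#' @param annotation An annotation data frame.
#' @return Data frame `es`, `n`, `n_flagged`, `fraction`.
#' @export
es_annotation_profile <- function(es_results, annotation) {
  n_pairs <- attr(es_results, "n_pairs")
  if (is.null(n_pairs)) n_pairs <- max(es_results$es)
  fl <- flag_values(es_results$protein_id, annotation, "signalp_or_tmh")
  fl[is.na(fl)] <- FALSE
  levels <- 0:n_pairs
  n <- vapply(levels, function(l) sum(es_results$es == l), 0L)
  nf <- vapply(levels, function(l) sum(fl[es_results$es == l]), 0L)
  data.frame(es = levels, n = n, n_flagged = nf,
             fraction = ifelse(n > 0, nf / n, NA_real_))
}

#' Exact overlap-region counts for named lists
#'
#' Tallies, for every membership pattern over the input lists (every
#' Venn/upset region), the number of elements showing exactly that
#' pattern. Region counts over all patterns sum to the size of the union.
#'
#' @param named_lists Named list (>= 2 entries) of character vectors.
#' @return Data frame with one logical membership column per list,
#'   `pattern` (e.g. `"A&C"`), and `count`; rows cover all observed and
#'   unobserved non-empty patterns.
#' @export
set_overlaps <- function(named_lists) {
  if (length(named_lists) < 2) stop("need at least two lists")
  if (is.null(names(named_lists)) || any(!nzchar(names(named_lists))))
    stop("every list must be named")
  nms <- names(named_lists)
  sets <- lapply(named_lists, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, nms))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(nms)))[-1, ,
                                                                  drop = FALSE]
  names(patterns) <- nms
  key_obs <- apply(member, 1, paste, collapse = ".")
  key_pat <- apply(as.matrix(patterns), 1, paste, collapse = ".")
  counts <- as.integer(table(factor(key_obs, levels = key_pat)))
  out <- patterns
  out$pattern <- apply(as.matrix(patterns), 1, function(r)
    paste(nms[r], collapse = "&"))
  out$count <- counts
  rownames(out) <- NULL
  out
}

#' Composite overlap query: elements of one list found in any of several
#'
#' Counts `|focus intersect union(others)|` — e.g. proteins shared between
#' serum and at least one of several tissues.
#'
#' @param named_lists Named list of character vectors.
#' @param focus Name of the focal list.
#' @param others Names of the lists whose union is intersected.
#' @return List `count` and `ids`.
#' @export
overlap_with_any <- function(named_lists, focus, others) {
  stopifnot(focus %in% names(named_lists),
            all(others %in% names(named_lists)))
  ids <- intersect(unique(named_lists[[focus]]),
                   unique(unlist(named_lists[others], use.names = FALSE)))
  list(count = length(ids), ids = sort(ids))
}

#' Tissue-panel enrichment by upper-tail hypergeometric test
#'
#' For each tissue panel, tests whether the hit list overlaps the panel
#' more than expected by chance when drawing `|hits|` proteins from the
#' universe: `p = P(X >= k)`, `X ~ Hypergeometric(N = |universe|,
#' K = |panel|, n = |hits|)`. P-values are BH-adjusted across tissues.
#' Hits outside the universe are dropped with a warning; panels are
#' intersected with the universe.
#'
#' @param hits Character vector of hit IDs.
#' @param panels Named list of tissue-specific ID sets.
#' @param universe Character vector: the background ID universe.
#' @return Data frame `tissue`, `panel_size`, `n_hits`, `overlap`, `p`,
#'   `adj_p`, sorted by `p`.
#' @export
tissue_enrichment <- function(hits, panels, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hits <- unique(hits)
  outside <- setdiff(hits, universe)
  if (length(outside)) {
    warning(length(outside), " hit(s) outside the universe dropped")
    hits <- intersect(hits, universe)
  }
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(panels), function(tn) {
    panel <- intersect(unique(panels[[tn]]), universe)
    K <- length(panel)
    k <- length(intersect(hits, panel))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(tissue = tn, panel_size = K, n_hits = n, overlap = k, p = p)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
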