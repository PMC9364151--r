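# FPR-calibrated TMT-ratio cutoffs and the enrichment score (ES).
#
# Calibration uses two control lists: PC (positive controls, proteins known
# to traffic through the ER / be secreted) and NC (negative controls,
# nuclear / cytoskeletal proteins never expected in the secretory pathway).
# For a candidate ratio cutoff r the "FPR" is the likelihood ratio
#     fpr(r) = [n_NC(>= r) / N_NC] / [n_PC(>= r) / N_PC],
# i.e. the upper-tail probability of the NC ratio distribution over that of
# the PC distribution. The cutoff is chosen as the smallest observed ratio
# at which fpr drops to the target (default 0.1: a protein passing is ten
# times more likely to be a true secreted protein than a false positive).
# The enrichment score of a protein is the number of its pairwise
# case/control ratios that pass their column cutoffs (0..9 in a 3 vs 3
# design); hits are called at ES >= 5.

#' Assemble positive/negative control lists for calibration
#'
#' The raw negative-control list (typically nuclear/transcription-factor
#' plus cytoskeletal proteins) is purged of any ID that is also on the
#' positive (secreted) list or on any exclusion list (receptors, ER
#' proteins, ...). Only IDs detected in the experiment are retained for
#' calibration.
#'
#' @param protein_ids Character vector of IDs detected in the experiment.
#' @param pc_list Character vector, positive-control (secreted) IDs.
#' @param nc_raw_list Character vector, raw negative-control IDs.
#' @param exclusion_lists Optional list of character vectors of IDs removed
#'   from the NC list (e.g. receptors, ER residents).
#' @return An object of class `control_lists` with elements `pc`, `nc`
#'   (detected IDs used for calibration), `pc_all`, `nc_all` (after
#'   exclusion, before intersection) and `counts`.
#' @export
label_controls <- function(protein_ids, pc_list, nc_raw_list,
                           exclusion_lists = list()) {
  pc_all <- unique(as.character(pc_list))
  excl <- unique(c(pc_all, unlist(exclusion_lists, use.names = FALSE)))
  nc_all <- setdiff(unique(as.character(nc_raw_list)), excl)
  pc <- intersect(pc_all, protein_ids)
  nc <- intersect(nc_all, protein_ids)
  if (!length(pc))
    stop("no positive-control protein detected in the experiment; ",
         "calibration impossible")
  if (!length(nc))
    stop("no negative-control protein detected in the experiment; ",
         "calibration impossible")
  structure(
    list(pc = pc, nc = nc, pc_all = pc_all, nc_all = nc_all,
         counts = c(pc_listed = length(pc_all), nc_listed = length(nc_all),
                    pc_detected = length(pc), nc_detected = length(nc))),
    class = "control_lists"
  )
}

#' @export
print.control_lists <- function(x, ...) {
  cat("control_lists: ", x$counts[["pc_detected"]], "/",
      x$counts[["pc_listed"]], " PC and ", x$counts[["nc_detected"]], "/",
      x$counts[["nc_listed"]], " NC proteins detected\n", sep = "")
  invisible(x)
}

#' False-positive-rate curve over candidate ratio cutoffs
#'
#' Candidate cutoffs are the sorted distinct ratios observed on the PC and
#' NC lists. At each candidate `r` the FPR is the NC upper-tail fraction
#' over the PC upper-tail fraction (tails inclusive of `r`). A candidate
#' with an empty PC tail but non-empty NC tail has infinite FPR; one with
#' both tails empty is undefined and dropped.
#'
#' @param ratios Named numeric vector: one ratio column, names = protein
#'   IDs. May contain `NA`.
#' @param controls A [label_controls()] result, or a list with character
#'   elements `pc` and `nc`.
#' @return An `fpr_curve` data frame with columns `cutoff`, `n_pc`, `n_nc`,
#'   `fpr`, plus attributes `N_pc`, `N_nc` (list sizes with a present ratio
#'   in this column).
#' @export
fpr_curve <- function(ratios, controls) {
  if (is.null(names(ratios))) stop("'ratios' must be named by protein ID")
  pc_r <- ratios[names(ratios) %in% controls$pc]
  nc_r <- ratios[names(ratios) %in% controls$nc]
  pc_r <- pc_r[!is.na(pc_r)]
  nc_r <- nc_r[!is.na(nc_r)]
  if (!length(pc_r)) stop("no present PC ratio in this column")
  if (!length(nc_r)) stop("no present NC ratio in this column")
  cand <- sort(unique(c(pc_r, nc_r)))
  # tail counts n(>= r) via sorted position
  n_pc <- length(pc_r) - findInterval(cand, sort(pc_r), left.open = TRUE)
  n_nc <- length(nc_r) - findInterval(cand, sort(nc_r), left.open = TRUE)
  fpr <- ifelse(n_pc == 0,
                ifelse(n_nc == 0, NA_real_, Inf),
                (n_nc / length(nc_r)) / (n_pc / length(pc_r)))
  keep <- !is.na(fpr)
  out <- data.frame(cutoff = cand, n_pc = n_pc, n_nc = n_nc,
                    fpr = fpr)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "N_pc") <- length(pc_r)
  attr(out, "N_nc") <- length(nc_r)
  class(out) <- c("fpr_curve", "data.frame")
  out
}

#' Select the ratio cutoff at a target FPR
#'
#' Returns the smallest candidate cutoff whose FPR, and that of every
#' larger candidate, is at or below the target. The suffix condition
#' guards against non-monotone empirical curves: a spurious dip below the
#' target that rises again is never selected.
#'
#' @param curve An [fpr_curve()] result.
#' @param target_fpr Target FPR (default 0.1).
#' @return A list with `cutoff`, `achieved_fpr` and `target_fpr`.
#' @export
select_cutoff <- function(curve, target_fpr = 0.1) {
  stopifnot(inherits(curve, "fpr_curve"), target_fpr > 0)
  ok <- curve$fpr <= target_fpr
  # positions where every candidate from here to the end satisfies ok
  suffix_ok <- rev(cumprod(rev(ok))) > 0
  if (!any(suffix_ok))
    stop(sprintf(
      "no cutoff attains target FPR %g (minimum achieved FPR: %g)",
      target_fpr, min(curve$fpr)))
  i <- which(suffix_ok)[1L]
  list(cutoff = curve$cutoff[i], achieved_fpr = curve$fpr[i],
       target_fpr = target_fpr)
}

#' Calibrate all ratio columns
#'
#' Runs [fpr_curve()] and [select_cutoff()] on every column of a ratio
#' matrix. By default each of the (typically nine) ratio columns is
#' calibrated independently; `global = TRUE` pools all columns' control
#' ratios into one curve and applies the single resulting cutoff to every
#' column.
#'
#' @param rm A `ratio_matrix` from [compute_ratio_matrix()].
#' @param controls A [label_controls()] result.
#' @param target_fpr Target FPR (default 0.1).
#' @param global Pool columns into one calibration? Default `FALSE`.
#' @return A `calibration` data frame with columns `column`, `cutoff`,
#'   `achieved_fpr`; attribute `target_fpr`.
#' @export
calibrate_cutoffs <- function(rm, controls, target_fpr = 0.1, global = FALSE) {
  stopifnot(inherits(rm, "ratio_matrix"))
  cols <- colnames(rm$ratios)
  if (global) {
    pooled <- as.vector(rm$ratios)
    names(pooled) <- rep(rownames(rm$ratios), times = ncol(rm$ratios))
    sel <- select_cutoff(fpr_curve(pooled, controls), target_fpr)
    out <- data.frame(column = cols, cutoff = sel$cutoff,
                      achieved_fpr = sel$achieved_fpr)
  } else {
    sels <- lapply(cols, function(cn) {
      col <- rm$ratios[, cn]
      names(col) <- rownames(rm$ratios)
      select_cutoff(fpr_curve(col, controls), target_fpr)
    })
    out <- data.frame(column = cols,
                      cutoff = vapply(sels, `[[`, 0, "cutoff"),
                      achieved_fpr = vapply(sels, `[[`, 0, "achieved_fpr"))
  }
  attr(out, "target_fpr") <- target_fpr
  class(out) <- c("calibration", "data.frame")
  out
}

#' Enrichment score: count of ratios passing their column cutoffs
#'
#' For each protein, ES is the number of present pairwise ratios at or
#' above the calibrated cutoff of their column (ties at the cutoff pass).
#' Missing ratios never count towards ES; they reduce `n_evaluable`
#' instead, so the attainable ES of a sparsely quantified protein is
#' bounded by its evaluable ratio count.
#'
#' @param rm A `ratio_matrix`.
#' @param calibration A [calibrate_cutoffs()] result (one row per ratio
#'   column of `rm`).
#' @return Data frame `protein_id`, `es`, `n_evaluable`.
#' @export
enrichment_score <- function(rm, calibration) {
  stopifnot(inherits(rm, "ratio_matrix"))
  cols <- colnames(rm$ratios)
  if (!setequal(cols, calibration$column) ||
      length(cols) != nrow(calibration))
    stop("calibration columns do not match the ratio matrix")
  cuts <- calibration$cutoff[match(cols, calibration$column)]
  pass <- sweep(rm$ratios, 2, cuts, `>=`)
  out <- data.frame(protein_id = rownames(rm$ratios),
                    es = as.integer(rowSums(pass, na.rm = TRUE)),
                    n_evaluable = as.integer(rowSums(!is.na(rm$ratios))),
                    row.names = NULL)
  attr(out, "n_pairs") <- ncol(rm$ratios)
  out
}

#' Call hits at a minimum enrichment score
#'
#' A protein is a hit when its ES reaches `min_es` (boundary inclusive;
#' the conventional threshold in a 3 vs 3 design is 5 of 9). Proteins with
#' fewer than `min_es` evaluable ratios can never be hits; they are
#' flagged in `es_attainable` so under-quantified proteins are
#' distinguishable from genuinely unenriched ones.
#'
#' @param result An [enrichment_score()] data frame.
#' @param min_es Minimum ES to call a hit (default 5).
#' @return The input with columns `hit` and `es_attainable` added, sorted
#'   by decreasing ES, ties broken by protein ID.
#' @export
call_hits <- function(result, min_es = 5L) {
  max_pairs <- attr(result, "n_pairs")
  if (is.null(max_pairs)) max_pairs <- max(result$n_evaluable)
  if (min_es < 0 || min_es > max_pairs)
    stop("min_es must be in [0, ", max_pairs, "]")
  out <- result
  out$hit <- out$es >= min_es
  out$es_attainable <- out$n_evaluable >= min_es
  out[order(-out$es, out$protein_id), , drop = FALSE]
}
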