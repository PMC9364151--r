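# Protein quant table I/O, median normalization, and pairwise TMT ratios.
# Intensities are stored on the linear scale; normalization works on log2.

#' Construct a protein quant table
#'
#' A `protein_quant` object holds a protein x channel reporter-intensity
#' matrix (linear scale, `NA` = missing) together with the case/control
#' design label of each channel.
#'
#' @param intensity Numeric matrix, rows = proteins (rownames = protein IDs),
#'   columns = channels (colnames = channel names). Non-negative or `NA`.
#' @param design Named character vector mapping every channel name to
#'   `"case"` or `"control"`.
#' @param gene_symbol Optional character vector of gene symbols, parallel to
#'   the rows.
#' @return An object of class `protein_quant`.
#' @export
protein_quant <- function(intensity, design, gene_symbol = NULL) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("'intensity' must be a numeric matrix")
  if (is.null(rownames(intensity)) || anyDuplicated(rownames(intensity)))
    stop("intensity rows must carry unique protein IDs")
  if (is.null(colnames(intensity)))
    stop("intensity columns must be named channels")
  design <- validate_design(design, colnames(intensity))
  if (any(intensity < 0, na.rm = TRUE))
    stop("intensities must be non-negative where present")
  structure(
    list(intensity = intensity,
         design = design,
         gene_symbol = gene_symbol),
    class = "protein_quant"
  )
}

validate_design <- function(design, channels) {
  if (is.null(names(design)) || !all(channels %in% names(design)))
    stop("'design' must name every channel in the table")
  design <- design[channels]
  bad <- setdiff(unique(design), c("case", "control"))
  if (length(bad))
    stop("design labels must be 'case' or 'control', got: ",
         paste(bad, collapse = ", "))
  if (!any(design == "case") || !any(design == "control"))
    stop("design needs at least one case and one control channel")
  design
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("protein_quant: ", nrow(x$intensity), " proteins x ",
      ncol(x$intensity), " channels (",
      sum(x$design == "case"), " case, ",
      sum(x$design == "control"), " control)\n", sep = "")
  norm <- attr(x, "normalization")
  if (!is.null(norm)) cat("  median-normalized\n")
  invisible(x)
}

#' Read a protein quant table from TSV/CSV
#'
#' The first column must be `protein_id`; remaining columns named in
#' `design` are parsed as reporter intensities. Empty cells and
#' non-positive values are recorded as missing (`NA`), never as zero.
#'
#' @param path Path to a delimited text file with a header row.
#' @param design Named character vector mapping intensity column names to
#'   `"case"` / `"control"`.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return A [protein_quant] object.
#' @export
read_protein_table <- function(path, design, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  if (!"protein_id" %in% names(df))
    stop("input must have a 'protein_id' column")
  dup <- df$protein_id[duplicated(df$protein_id)]
  if (length(dup))
    stop("duplicated protein_id: ", paste(unique(dup), collapse = ", "))
  missing_cols <- setdiff(names(design), names(df))
  if (length(missing_cols))
    stop("design column(s) absent from table: ",
         paste(missing_cols, collapse = ", "))
  mat <- as.matrix(df[, names(design), drop = FALSE])
  storage.mode(mat) <- "double"
  mat[!is.na(mat) & mat <= 0] <- NA_real_   # non-positive -> missing
  rownames(mat) <- df$protein_id
  all_missing <- rowSums(!is.na(mat)) == 0
  if (any(all_missing))
    warning(sum(all_missing), " protein(s) with no quantified channel retained")
  gene <- if ("gene_symbol" %in% names(df)) df$gene_symbol else NULL
  protein_quant(mat, design, gene_symbol = gene)
}

#' Write a protein quant table as TSV
#'
#' Missing values are written as empty cells so that
#' [read_protein_table()] round-trips the table exactly.
#'
#' @param x A [protein_quant] object.
#' @param path Output path.
#' @export
write_protein_table <- function(x, path) {
  stopifnot(inherits(x, "protein_quant"))
  df <- data.frame(protein_id = rownames(x$intensity),
                   x$intensity, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Median-normalize reporter intensities
#'
#' Each channel is shifted on the log2 scale by a single constant so that
#' its median over present values equals the grand median of the
#' pre-normalization channel medians. The absolute intensity scale is
#' therefore preserved; only between-channel loading offsets are removed.
#' Missing values stay missing.
#'
#' @param x A [protein_quant] object.
#' @return The normalized `protein_quant`; the per-channel shift report is
#'   attached as `attr(, "normalization")` (a data frame with the channel,
#'   its pre-normalization log2 median and the log2 shift applied).
#' @export
median_normalize <- function(x) {
  stopifnot(inherits(x, "protein_quant"))
  lg <- log2(x$intensity)
  n_present <- colSums(!is.na(lg))
  if (any(n_present == 0))
    stop("channel(s) with no present values: ",
         paste(colnames(lg)[n_present == 0], collapse = ", "))
  ch_med <- apply(lg, 2, stats::median, na.rm = TRUE)
  grand <- stats::median(ch_med)
  shift <- ch_med - grand
  lg <- sweep(lg, 2, shift)
  out <- x
  out$intensity <- 2^lg
  attr(out, "normalization") <- data.frame(
    channel = colnames(lg),
    median_log2 = unname(ch_med),
    shift_log2 = unname(shift),
    row.names = NULL
  )
  out
}

#' Compute all pairwise case/control TMT ratios
#'
#' Forms one ratio column per (case, control) channel pair on the linear
#' scale (case intensity / control intensity); a 3 vs 3 design yields the
#' nine ratio datasets used for enrichment scoring. Columns are ordered
#' lexicographically by (case index, control index). Any ratio involving a
#' missing intensity is missing; a zero control intensity also yields a
#' missing ratio (division undefined).
#'
#' @param x A (normalized) [protein_quant] object.
#' @return A `ratio_matrix`: list with `ratios` (protein x pair matrix) and
#'   `pairs` (data frame with case and control channel of each column).
#' @export
compute_ratio_matrix <- function(x) {
  stopifnot(inherits(x, "protein_quant"))
  case_ch <- names(x$design)[x$design == "case"]
  ctrl_ch <- names(x$design)[x$design == "control"]
  pairs <- expand.grid(control = ctrl_ch, case = case_ch,
                       stringsAsFactors = FALSE)[, c("case", "control")]
  ratios <- matrix(NA_real_, nrow(x$intensity), nrow(pairs),
                   dimnames = list(rownames(x$intensity),
                                   paste0("ratio_", pairs$case, "_", pairs$control)))
  for (j in seq_len(nrow(pairs))) {
    den <- x$intensity[, pairs$control[j]]
    den[!is.na(den) & den == 0] <- NA_real_
    ratios[, j] <- x$intensity[, pairs$case[j]] / den
  }
  structure(list(ratios = ratios, pairs = pairs), class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat("ratio_matrix: ", nrow(x$ratios), " proteins x ",
      ncol(x$ratios), " case/control pairs\n", sep = "")
  invisible(x)
}

#' Write a ratio matrix as TSV
#' @param x A `ratio_matrix`.
#' @param path Output path.
#' @export
write_ratio_matrix <- function(x, path) {
  stopifnot(inherits(x, "ratio_matrix"))
  df <- data.frame(protein_id = rownames(x$ratios), x$ratios,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a ratio matrix written by [write_ratio_matrix()]
#' @param path Input TSV path; columns `ratio_<case>_<control>`.
#' @return A `ratio_matrix`.
#' @export
read_ratio_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  if (!"protein_id" %in% names(df))
    stop("input must have a 'protein_id' column")
  rcols <- grep("^ratio_", names(df), value = TRUE)
  if (!length(rcols)) stop("no ratio_* columns found")
  mat <- as.matrix(df[, rcols, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df$protein_id
  halves <- strsplit(sub("^ratio_", "", rcols), "_(?=[^_]+_[^_]+$)", perl = TRUE)
  # pair labels are best-effort here: channel names themselves may contain '_'
  pairs <- data.frame(case = vapply(halves, `[`, "", 1L),
                      control = vapply(halves, function(h)
                        paste(h[-1L], collapse = "_"), ""))
  structure(list(ratios = mat, pairs = pairs), class = "ratio_matrix")
}
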