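# Peptide-to-topology mapping for ectodomain-shedding inference.
# All residue coordinates are 1-based inclusive (UniProt convention).

#' Topology model of a membrane protein
#'
#' @param protein_id Protein identifier.
#' @param sequence Uppercase amino-acid string.
#' @param segments Data frame with columns `segment_type` (one of
#'   `"extracellular"`, `"TM"`, `"cytoplasmic"`, `"signal_peptide"`),
#'   `start`, `end` (1-based inclusive). Segments must be sorted,
#'   non-overlapping and within the sequence; gaps (unannotated stretches)
#'   are allowed.
#' @return An object of class `topology_model`.
#' @export
topology_model <- function(protein_id, sequence, segments) {
  need <- c("segment_type", "start", "end")
  if (!all(need %in% names(segments)))
    stop("segments need columns: ", paste(need, collapse = ", "))
  seg <- segments[order(segments$start), need, drop = FALSE]
  if (nrow(seg)) {
    if (any(seg$start > seg$end))
      stop("segment start must not exceed end")
    if (any(seg$start < 1) || any(seg$end > nchar(sequence)))
      stop("segments must lie within [1, sequence length]")
    if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)]))
      stop("segments must not overlap")
  }
  rownames(seg) <- NULL
  structure(list(protein_id = protein_id, sequence = sequence,
                 segments = seg),
            class = "topology_model")
}

#' @export
print.topology_model <- function(x, ...) {
  cat("topology_model ", x$protein_id, ": ", nchar(x$sequence),
      " aa, segments ", paste(sprintf("%s[%d,%d]", x$segments$segment_type,
                                      x$segments$start, x$segments$end),
                              collapse = " "), "\n", sep = "")
  invisible(x)
}

# All occurrences (including overlapping) of peptide in sequence; exact,
# I/L distinct unless collapsed by the caller.
find_occurrences <- function(peptide, sequence) {
  m <- nchar(peptide)
  n <- nchar(sequence)
  if (m == 0 || m > n)
    return(data.frame(start = integer(0), end = integer(0)))
  starts <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(peptide, substr(sequence, from, n), fixed = TRUE)
    if (hit == -1L) break
    s <- from + as.integer(hit) - 1L
    starts <- c(starts, s)
    from <- s + 1L   # advance one residue: overlapping hits are real
    if (from > n - m + 1L) break
  }
  data.frame(start = starts, end = starts + m - 1L)
}

#' Map identified peptides onto a protein sequence
#'
#' Exact substring search of each peptide against the full-length
#' sequence. A peptide found once gets coordinates; one found at several
#' positions (overlaps included) is flagged ambiguous with all coordinate
#' pairs retained; one not found is reported unmapped.
#'
#' @param peptides Character vector of uppercase peptide sequences.
#' @param sequence Uppercase amino-acid string.
#' @param il_equivalent Treat isoleucine and leucine as indistinguishable
#'   (both matched as either)? Default `FALSE` (exact matching).
#' @return A `peptide_map` data frame: `peptide`, `start`, `end`,
#'   `n_occurrences`, `ambiguous`, `mapped` — one row per occurrence, and
#'   one `NA`-coordinate row for each unmapped peptide.
#' @export
map_peptides <- function(peptides, sequence, il_equivalent = FALSE) {
  if (any(!nzchar(peptides))) stop("empty peptide")
  seq_use <- if (il_equivalent) chartr("I", "L", sequence) else sequence
  rows <- lapply(peptides, function(p) {
    p_use <- if (il_equivalent) chartr("I", "L", p) else p
    occ <- find_occurrences(p_use, seq_use)
    if (nrow(occ) == 0)
      return(data.frame(peptide = p, start = NA_integer_, end = NA_integer_,
                        n_occurrences = 0L, ambiguous = FALSE,
                        mapped = FALSE))
    data.frame(peptide = p, start = occ$start, end = occ$end,
               n_occurrences = nrow(occ), ambiguous = nrow(occ) > 1L,
               mapped = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("peptide_map", "data.frame")
  out
}

#' Classify mapped peptides by membrane topology
#'
#' Labels each unambiguously mapped peptide with the set of segment types
#' its interval intersects; residues falling outside every annotated
#' segment contribute the label `"unannotated"`. Ambiguous peptides are
#' excluded with a warning (they cannot place a cleavage bound).
#'
#' @param map A [map_peptides()] result.
#' @param topo A [topology_model].
#' @return Data frame `peptide`, `start`, `end`, `regions`
#'   (comma-separated label set), `extracellular_only`.
#' @export
classify_topology <- function(map, topo) {
  stopifnot(inherits(topo, "topology_model"))
  use <- map[map$mapped & !map$ambiguous, , drop = FALSE]
  n_drop <- sum(map$ambiguous[!duplicated(map$peptide)])
  if (n_drop > 0)
    warning(n_drop, " ambiguous peptide(s) excluded from classification")
  seg <- topo$segments
  lab <- lapply(seq_len(nrow(use)), function(i) {
    s <- use$start[i]; e <- use$end[i]
    hit <- seg$start <= e & seg$end >= s
    labels <- unique(seg$segment_type[hit])
    covered <- sum(pmin(seg$end[hit], e) - pmax(seg$start[hit], s) + 1L)
    if (covered < e - s + 1L) labels <- c(labels, "unannotated")
    if (!length(labels)) labels <- "unannotated"
    labels
  })
  out <- data.frame(peptide = use$peptide, start = use$start, end = use$end,
                    regions = vapply(lab, paste, "", collapse = ","),
                    extracellular_only = vapply(lab, function(l)
                      identical(l, "extracellular"), logical(1)))
  rownames(out) <- NULL
  out
}

#' Infer an ectodomain-shedding call and cleavage-site bound
#'
#' A shedding-consistent protein has every mapped peptide confined to
#' extracellular topology. The approximate cleavage site is then bounded
#' by the most terminal peptide and the transmembrane segment: for an
#' N-terminal-out protein (ectodomain before the TM), the cleavage site
#' lies between the end of the most C-terminal extracellular peptide and
#' the TM start; for a C-terminal-out protein the rule mirrors. Signal
#' peptide segments are ignored when orienting and bounding (mature-chain
#' coordinates).
#'
#' @param classified A [classify_topology()] result.
#' @param topo A [topology_model] (a TM segment is required for a
#'   cleavage bound; without one, only `all_extracellular` is reported).
#' @return A `shedding_call` list: `protein_id`, `all_extracellular`,
#'   `orientation` (`"N-terminal-out"` / `"C-terminal-out"` / `NA`),
#'   `cleavage_bound` (integer `c(start, end)`, 1-based inclusive, or
#'   `NULL`).
#' @export
call_shedding <- function(classified, topo) {
  stopifnot(inherits(topo, "topology_model"))
  if (nrow(classified) == 0) stop("no mapped peptide to assess")
  all_ec <- all(classified$extracellular_only)
  seg <- topo$segments[topo$segments$segment_type != "signal_peptide", ,
                       drop = FALSE]
  tm <- seg[seg$segment_type == "TM", , drop = FALSE]
  out <- list(protein_id = topo$protein_id, all_extracellular = all_ec,
              orientation = NA_character_, cleavage_bound = NULL)
  class(out) <- "shedding_call"
  if (!all_ec || nrow(tm) == 0) return(out)
  ec <- seg[seg$segment_type == "extracellular", , drop = FALSE]
  # orientation: is the peptide-bearing ectodomain N-terminal of a TM?
  pep_lo <- min(classified$start)
  pep_hi <- max(classified$end)
  tm_after <- tm[tm$start > pep_hi, , drop = FALSE]
  tm_before <- tm[tm$end < pep_lo, , drop = FALSE]
  if (nrow(tm_after)) {
    out$orientation <- "N-terminal-out"
    out$cleavage_bound <- c(pep_hi + 1L, min(tm_after$start) - 1L)
  } else if (nrow(tm_before)) {
    out$orientation <- "C-terminal-out"
    out$cleavage_bound <- c(max(tm_before$end) + 1L, pep_lo - 1L)
  }
  if (!is.null(out$cleavage_bound) &&
      out$cleavage_bound[1] > out$cleavage_bound[2]) {
    # most terminal peptide abuts the TM: bound collapses to empty
    out$cleavage_bound <- NULL
  }
  out
}

#' @export
print.shedding_call <- function(x, ...) {
  cat("shedding_call ", x$protein_id, ": all_extracellular = ",
      x$all_extracellular, sep = "")
  if (!is.null(x$cleavage_bound))
    cat("; cleavage within [", x$cleavage_bound[1], ", ",
        x$cleavage_bound[2], "] (", x$orientation, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' In-silico tryptic digestion
#'
#' Cleaves after lysine (K) or arginine (R). By default cleavage is
#' suppressed when the next residue is proline (P); `allow_p = TRUE`
#' ("trypsin allow P" specificity) cleaves regardless. With `m` missed
#' cleavages, every concatenation of up to `m + 1` adjacent fully-cleaved
#' fragments is emitted.
#'
#' @param sequence Uppercase amino-acid string.
#' @param missed_cleavages Maximum missed cleavages (default 0).
#' @param allow_p Cleave K/R-P bonds too? Default `FALSE`.
#' @return Data frame `peptide`, `start`, `end`, `n_missed` (1-based
#'   inclusive coordinates); zero rows for an empty sequence.
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L, allow_p = FALSE) {
  n <- nchar(sequence)
  if (n == 0)
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), n_missed = integer(0)))
  resid <- strsplit(sequence, "")[[1]]
  cut_after <- resid %in% c("K", "R")
  if (!allow_p) {
    next_p <- c(resid[-1] == "P", FALSE)
    cut_after <- cut_after & !next_p
  }
  cut_after[n] <- TRUE
  ends <- which(cut_after)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  frags <- data.frame(start = starts, end = ends)
  out <- do.call(rbind, lapply(0:missed_cleavages, function(m) {
    if (nrow(frags) < m + 1) return(NULL)
    i <- seq_len(nrow(frags) - m)
    data.frame(start = frags$start[i], end = frags$end[i + m],
               n_missed = m)
  }))
  out$peptide <- substring(sequence, out$start, out$end)
  out <- out[order(out$n_missed, out$start),
             c("peptide", "start", "end", "n_missed")]
  rownames(out) <- NULL
  out
}

#' Read topology annotations from TSV
#'
#' Expects columns `protein_id`, `segment_type`, `start`, `end` (1-based
#' inclusive) and returns one [topology_model] per protein, joined to the
#' supplied sequences.
#'
#' @param path TSV path.
#' @param sequences Named character vector (or `Biostrings::AAStringSet`)
#'   of protein sequences, names = protein IDs.
#' @return Named list of [topology_model] objects.
#' @export
read_topology <- function(path, sequences) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "segment_type", "start", "end")
  if (!all(need %in% names(df)))
    stop("topology TSV needs columns: ", paste(need, collapse = ", "))
  seqs <- as.character(sequences)
  if (is.null(names(seqs)) && !is.null(names(sequences)))
    names(seqs) <- names(sequences)
  out <- lapply(split(df, df$protein_id), function(d) {
    id <- d$protein_id[1]
    if (!id %in% names(seqs))
      stop("no sequence for protein ", id)
    topology_model(id, seqs[[id]], d[, c("segment_type", "start", "end")])
  })
  out
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences (first
#'   whitespace-delimited token of each header as the name).
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  out
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta_sequences <- function(sequences, path) {
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Ectodomain-shedding analysis for one protein
#'
#' Convenience wrapper chaining [map_peptides()], [classify_topology()]
#' and [call_shedding()], also returning the coverage-diagram data
#' (peptide intervals plus topology segments) used for plotting.
#'
#' @param peptides Character vector of identified peptides.
#' @param topo A [topology_model].
#' @param il_equivalent Passed to [map_peptides()].
#' @return List with `map`, `classified`, `call` and `coverage` (data
#'   frame of segment and peptide intervals, `kind` column
#'   distinguishing them).
#' @export
shedding_analysis <- function(peptides, topo, il_equivalent = FALSE) {
  map <- map_peptides(peptides, topo$sequence, il_equivalent = il_equivalent)
  classified <- classify_topology(map, topo)
  call <- call_shedding(classified, topo)
  coverage <- rbind(
    data.frame(kind = "segment", label = topo$segments$segment_type,
               start = topo$segments$start, end = topo$segments$end),
    if (nrow(classified))
      data.frame(kind = "peptide", label = classified$peptide,
                 start = classified$start, end = classified$end)
  )
  list(map = map, classified = classified, call = call, coverage = coverage)
}
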