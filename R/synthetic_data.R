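# Seeded generators: TMT proximity-labelling experiments with known ground
# truth, and topology-annotated membrane proteins shedding extracellular
# tryptic peptides.

#' Simulation configuration
#'
#' Defaults describe a typical 6plex proximity-labelling experiment: three
#' case against three control channels, a minority (10%) of truly
#' ER-trafficked proteins enriched ~4-fold (log2 effect ~ N(2, 0.5)) over
#' an abundant non-specific bead background, 10% negative-class
#' (nuclear/cytoskeletal) proteins, and a handful of endogenously
#' biotinylated carboxylase-like proteins that are high-abundance in both
#' genotypes and must never be called hits. Reporter noise is log-normal
#' (cell sd 0.3 log2 units), channels carry additive log2 loading offsets
#' (sd 0.2) to exercise median normalization, and 5% of cells are missing
#' completely at random.
#'
#' @param n_proteins Number of proteins.
#' @param n_case,n_control Channels per group (default 3 and 3).
#' @param frac_true_enriched Fraction of truly enriched proteins (floor
#'   rounding).
#' @param frac_negative_class Fraction of negative-class proteins (floor
#'   rounding); remainder after both classes and the biotin proteins is
#'   background.
#' @param n_endogenous_biotin Count of endogenously biotinylated
#'   high-abundance proteins (default 5).
#' @param enrichment_log2fc_mean,enrichment_log2fc_sd Normal parameters of
#'   the true per-protein log2 effect added to case channels.
#' @param noise_sd Per-cell log2 noise sd.
#' @param channel_shift_sd Sd of per-channel additive log2 offsets.
#' @param missing_rate Fraction of cells missing completely at random.
#' @param base_log2_mean,base_log2_sd Log2 base-abundance distribution
#'   (reporter-intensity scale).
#' @param biotin_log2_bonus Log2 abundance bonus of endogenous-biotin
#'   proteins.
#' @param annotation_tp_rate Probability a true-enriched protein is
#'   flagged SignalP/TMH-positive (and secreted) in the annotation table.
#' @param annotation_bg_rate Probability any other protein carries a flag.
#' @param seed Integer seed; mandatory (reproducibility is not optional).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_proteins = 1000L,
                       n_case = 3L,
                       n_control = 3L,
                       frac_true_enriched = 0.1,
                       frac_negative_class = 0.1,
                       n_endogenous_biotin = 5L,
                       enrichment_log2fc_mean = 2,
                       enrichment_log2fc_sd = 0.5,
                       noise_sd = 0.3,
                       channel_shift_sd = 0.2,
                       missing_rate = 0.05,
                       base_log2_mean = 20,
                       base_log2_sd = 2,
                       biotin_log2_bonus = 4,
                       annotation_tp_rate = 0.9,
                       annotation_bg_rate = 0.05,
                       seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("'seed' is mandatory: simulations must be reproducible")
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_case = as.integer(n_case),
              n_control = as.integer(n_control),
              frac_true_enriched = frac_true_enriched,
              frac_negative_class = frac_negative_class,
              n_endogenous_biotin = as.integer(n_endogenous_biotin),
              enrichment_log2fc_mean = enrichment_log2fc_mean,
              enrichment_log2fc_sd = enrichment_log2fc_sd,
              noise_sd = noise_sd,
              channel_shift_sd = channel_shift_sd,
              missing_rate = missing_rate,
              base_log2_mean = base_log2_mean,
              base_log2_sd = base_log2_sd,
              biotin_log2_bonus = biotin_log2_bonus,
              annotation_tp_rate = annotation_tp_rate,
              annotation_bg_rate = annotation_bg_rate,
              seed = as.integer(seed))
  with(cfg, {
    if (n_proteins < 1 || n_case < 1 || n_control < 1)
      stop("counts must be positive")
    fracs <- c(frac_true_enriched, frac_negative_class, missing_rate,
               annotation_tp_rate, annotation_bg_rate)
    if (any(fracs < 0 | fracs > 1))
      stop("fractions must lie in [0, 1]")
    if (frac_true_enriched + frac_negative_class > 1)
      stop("frac_true_enriched + frac_negative_class must be <= 1")
    if (enrichment_log2fc_sd < 0 || noise_sd < 0 || channel_shift_sd < 0)
      stop("standard deviations must be non-negative")
  })
  class(cfg) <- "sim_config"
  cfg
}

# Evaluate expr under a derived seed without disturbing the caller's RNG
# stream; fixed offsets per draw block keep earlier draws stable when
# n_proteins grows.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a TMT proximity-labelling experiment
#'
#' Draws a protein quant table under the generative model described in
#' [sim_config()], with classes assigned by the floor rule
#' (`floor(n_proteins * fraction)`; remainder to background). Returns the
#' table, the ground truth, positive/negative control lists (the
#' true-enriched and negative-class proteins, respectively) and an
#' annotation flag table.
#'
#' @param config A [sim_config()].
#' @return List with `table` ([protein_quant]), `truth` (data frame
#'   `protein_id`, `class`, `true_log2fc`), `control_lists` (list `pc`,
#'   `nc`) and `annotation` (data frame `protein_id`, `secreted`,
#'   `signalp`, `tmh` as 0/1).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_proteins
  k <- cfg$n_case + cfg$n_control
  n_true <- floor(n * cfg$frac_true_enriched)
  n_neg <- floor(n * cfg$frac_negative_class)
  n_bio <- min(cfg$n_endogenous_biotin, n - n_true - n_neg)
  cls <- rep("background", n)
  cls[seq_len(n_true)] <- "true_enriched"
  if (n_neg > 0) cls[n_true + seq_len(n_neg)] <- "negative_control"
  if (n_bio > 0) cls[n_true + n_neg + seq_len(n_bio)] <- "endogenous_biotin"
  ids <- sprintf("P%05d", seq_len(n))
  channels <- c(sprintf("case_%d", seq_len(cfg$n_case)),
                sprintf("control_%d", seq_len(cfg$n_control)))
  design <- stats::setNames(rep(c("case", "control"),
                                c(cfg$n_case, cfg$n_control)), channels)

  base <- with_seed(cfg$seed + 1L,
                    stats::rnorm(n, cfg$base_log2_mean, cfg$base_log2_sd))
  base[cls == "endogenous_biotin"] <- base[cls == "endogenous_biotin"] +
    cfg$biotin_log2_bonus
  effect <- numeric(n)
  if (n_true > 0)
    effect[seq_len(n_true)] <- with_seed(
      cfg$seed + 2L,
      stats::rnorm(n_true, cfg$enrichment_log2fc_mean,
                   cfg$enrichment_log2fc_sd))
  shifts <- with_seed(cfg$seed + 3L,
                      stats::rnorm(k, 0, cfg$channel_shift_sd))
  noise <- with_seed(cfg$seed + 4L,
                     matrix(stats::rnorm(n * k, 0, cfg$noise_sd),
                            nrow = n, byrow = TRUE))
  lg <- matrix(base, n, k) + noise
  lg[, seq_len(cfg$n_case)] <- lg[, seq_len(cfg$n_case)] + effect
  lg <- sweep(lg, 2, shifts, `+`)
  intensity <- 2^lg
  if (cfg$missing_rate > 0) {
    u <- with_seed(cfg$seed + 5L,
                   matrix(stats::runif(n * k), nrow = n, byrow = TRUE))
    intensity[u < cfg$missing_rate] <- NA_real_
  }
  dimnames(intensity) <- list(ids, channels)

  ann_draw <- with_seed(cfg$seed + 6L, stats::runif(n))
  flagged <- ifelse(cls == "true_enriched",
                    ann_draw < cfg$annotation_tp_rate,
                    ann_draw < cfg$annotation_bg_rate)
  annotation <- data.frame(protein_id = ids,
                           secreted = as.integer(flagged),
                           signalp = as.integer(flagged),
                           tmh = 0L)

  list(table = protein_quant(intensity, design),
       truth = data.frame(protein_id = ids, class = cls,
                          true_log2fc = effect),
       control_lists = list(pc = ids[cls == "true_enriched"],
                            nc = ids[cls == "negative_control"]),
       annotation = annotation)
}

#' Write a simulated experiment to a directory
#'
#' Emits the quant table, ground truth and annotation as TSV and the
#' control lists as one-ID-per-line text files.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_experiment <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_protein_table(sim$table, file.path(dir, "protein_quant.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$control_lists$pc, file.path(dir, "pc.txt"))
  writeLines(sim$control_lists$nc, file.path(dir, "nc.txt"))
  invisible(dir)
}

#' Simulate an ectodomain-shedding case
#'
#' Generates a random protein sequence tiled by the given topology layout
#' and draws identified peptides exclusively from the extracellular
#' segment(s) by in-silico tryptic digestion. Each emitted peptide occurs
#' exactly once in the full sequence (the sequence is re-drawn until the
#' peptides are unique), so downstream mapping is unambiguous.
#'
#' @param seq_length Protein length in residues.
#' @param topology_layout Data frame with columns `segment_type`
#'   (`"extracellular"`, `"TM"` or `"cytoplasmic"`), `start`, `end`
#'   (1-based inclusive) tiling `[1, seq_length]` without gaps or overlap.
#' @param n_peptides Number of peptides to emit.
#' @param seed Integer seed (mandatory).
#' @param min_peptide_length Shortest emitted peptide (default 5; shorter
#'   tryptic fragments are rarely unique or identified).
#' @param max_tries Sequence re-draw attempts before giving up.
#' @return List with `protein_id`, `sequence`, `topology` (a
#'   [topology_model]) and `peptides` (data frame `peptide`, `start`,
#'   `end`).
#' @export
simulate_shedding_case <- function(seq_length, topology_layout, n_peptides,
                                   seed, min_peptide_length = 5L,
                                   max_tries = 100L) {
  if (missing(seed)) stop("'seed' is mandatory")
  lay <- topology_layout[order(topology_layout$start), , drop = FALSE]
  if (lay$start[1] != 1 || lay$end[nrow(lay)] != seq_length ||
      (nrow(lay) > 1 && any(lay$start[-1] != lay$end[-nrow(lay)] + 1)))
    stop("topology_layout must tile [1, seq_length] without gaps or overlap")
  ec <- lay[lay$segment_type == "extracellular", , drop = FALSE]
  if (n_peptides > 0 && nrow(ec) == 0)
    stop("no extracellular segment to draw peptides from")
  # amino-acid alphabet weighted towards average composition, K/R ~ 11%
  # so tryptic fragments have realistic lengths
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  w <- c(8.3,1.4,5.5,6.7,3.9,7.1,2.3,5.9,5.8,9.7,
         2.4,4.1,4.7,3.9,5.5,6.6,5.3,6.9,1.1,2.9)
  res <- with_seed(seed, {
    found <- NULL
    for (try in seq_len(max_tries)) {
      seqc <- sample(aa, seq_length, replace = TRUE, prob = w)
      sq <- paste(seqc, collapse = "")
      dig <- tryptic_digest(sq)
      cand <- dig[nchar(dig$peptide) >= min_peptide_length, , drop = FALSE]
      inside <- vapply(seq_len(nrow(cand)), function(i) {
        any(cand$start[i] >= ec$start & cand$end[i] <= ec$end)
      }, logical(1))
      cand <- cand[inside, , drop = FALSE]
      unique_once <- vapply(cand$peptide, function(p)
        nrow(find_occurrences(p, sq)) == 1L, logical(1))
      cand <- cand[unique_once, , drop = FALSE]
      if (nrow(cand) >= n_peptides) {
        pick <- if (n_peptides > 0)
          sort(sample(nrow(cand), n_peptides)) else integer(0)
        found <- list(sq = sq, pep = cand[pick, , drop = FALSE])
        break
      }
    }
    if (is.null(found))
      stop("could not draw ", n_peptides,
           " unique extracellular tryptic peptides in ", max_tries, " tries")
    found
  })
  pep <- res$pep
  rownames(pep) <- NULL
  list(protein_id = sprintf("SYN_SHED_%d", as.integer(seed)),
       sequence = res$sq,
       topology = topology_model(sprintf("SYN_SHED_%d", as.integer(seed)),
                                 res$sq, lay),
       peptides = pep)
}
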