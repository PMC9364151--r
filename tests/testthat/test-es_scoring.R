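# FPR calibration and enrichment scoring against hand-derived values and
# the brute-force enumeration oracle.

named <- function(x, prefix = "P") setNames(x, paste0(prefix, seq_along(x)))

# build a one-column "experiment" from explicit PC and NC ratio values
controls_from <- function(pc_vals, nc_vals) {
  ids_pc <- paste0("PC", seq_along(pc_vals))
  ids_nc <- paste0("NC", seq_along(nc_vals))
  list(ratios = setNames(c(pc_vals, nc_vals), c(ids_pc, ids_nc)),
       controls = list(pc = ids_pc, nc = ids_nc))
}

test_that("negative-control list is purged of positives and exclusions", {
  ids <- c("A", "B", "C", "X")
  ctl <- label_controls(ids, pc_list = c("B", "X"), nc_raw_list = c("A", "B", "C"),
                        exclusion_lists = list(c("C")))
  expect_equal(ctl$nc, "A")
  expect_setequal(ctl$pc, c("B", "X"))
  # only detected IDs are retained for calibration
  ctl2 <- label_controls(c("X", "A"), pc_list = c("X", "Y"),
                         nc_raw_list = "A")
  expect_equal(ctl2$pc, "X")
  # disjoint lists with no exclusions pass through unchanged
  ctl3 <- label_controls(c("A", "B"), "A", "B")
  expect_equal(ctl3$nc, "B")
  expect_error(label_controls(c("A"), "Z", "A"), "positive-control")
  expect_error(label_controls(c("Z"), "Z", "A"), "negative-control")
})

test_that("FPR curve reproduces hand tail counts and symmetry cases", {
  cc <- controls_from(c(1.5, 2.0, 3.0, 1.2), c(0.8, 1.0, 1.1, 1.6))
  curve <- fpr_curve(cc$ratios, cc$controls)
  # at cutoff 1.5: NC tail {1.6} of 4, PC tail {1.5,2,3} of 4 -> 1/3
  expect_equal(curve$fpr[curve$cutoff == 1.5], (1 / 4) / (3 / 4))
  expect_equal(curve$n_pc[curve$cutoff == 1.5], 3L)
  expect_equal(curve$n_nc[curve$cutoff == 1.5], 1L)

  # identical PC and NC multisets: fpr is 1 everywhere
  same <- controls_from(c(1, 2, 3), c(1, 2, 3))
  expect_equal(fpr_curve(same$ratios, same$controls)$fpr, rep(1, 3))

  # all NC strictly below min PC: fpr = 0 at the min PC value
  sep <- controls_from(c(2, 3), c(0.5, 0.9))
  cs <- fpr_curve(sep$ratios, sep$controls)
  expect_equal(cs$fpr[cs$cutoff == 2], 0)

  # missing ratios and absent control columns are rejected
  expect_error(fpr_curve(setNames(c(NA, 1), c("PC1", "NC1")),
                         list(pc = "PC1", nc = "NC1")), "PC")
})

test_that("cutoff selection finds the smallest dominating candidate", {
  cc <- controls_from(c(1.2, 1.5, 2.0, 3.0), c(0.8, 1.0, 1.1, 1.6))
  sel <- select_cutoff(fpr_curve(cc$ratios, cc$controls), 0.1)
  expect_equal(sel$cutoff, 2.0)
  expect_equal(sel$achieved_fpr, 0)

  sep <- controls_from(c(2, 3), c(0.5, 0.9))
  expect_equal(select_cutoff(fpr_curve(sep$ratios, sep$controls))$cutoff, 2)

  same <- controls_from(c(1, 2, 3), c(1, 2, 3))
  expect_error(select_cutoff(fpr_curve(same$ratios, same$controls), 0.1),
               "minimum achieved FPR: 1")

  # a dip below the target inside a non-monotone curve is never selected
  dip <- controls_from(c(1, 3, 5), c(2, 4))
  curve <- fpr_curve(dip$ratios, dip$controls)
  expect_equal(curve$fpr, c(1, 1.5, 0.75, 1.5, 0))
  expect_equal(select_cutoff(curve, 0.8)$cutoff, 5)
})

test_that("curve and selection agree exactly with brute-force enumeration", {
  set.seed(301)
  for (rep in 1:25) {
    n_pc <- sample(3:25, 1)
    n_nc <- sample(3:25, 1)
    pc <- round(rlnorm(n_pc, log(2), 0.6), 2)
    nc <- round(rlnorm(n_nc, 0, 0.6), 2)   # rounding forces ties
    cc <- controls_from(pc, nc)
    curve <- fpr_curve(cc$ratios, cc$controls)
    orc <- oracle_fpr_curve(pc, nc)
    expect_identical(curve$cutoff, orc$cutoff)
    expect_identical(curve$n_pc, as.integer(orc$n_pc))
    expect_identical(curve$n_nc, as.integer(orc$n_nc))
    expect_equal(curve$fpr, orc$fpr)
    target <- sample(c(0.05, 0.1, 0.3), 1)
    want <- oracle_select_cutoff(orc, target)
    if (is.null(want)) {
      expect_error(select_cutoff(curve, target))
    } else {
      got <- select_cutoff(curve, target)
      expect_identical(got$cutoff, want$cutoff)
      expect_identical(got$achieved_fpr, want$achieved_fpr)
    }
  }
})

test_that("enrichment score counts passing ratios with inclusive boundary", {
  ratios <- matrix(c(2.5, 2.1, 3.0, 1.9, 2.2, 2.8, 2.0, 2.4, 2.6,
                     rep(3, 9),
                     rep(1, 9)),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("Pmid", "Pall", "Pnone"),
                                   paste0("ratio_c", 1:9)))
  rm <- structure(list(ratios = ratios,
                       pairs = data.frame(case = paste0("c", 1:9),
                                          control = "k")),
                  class = "ratio_matrix")
  calib <- data.frame(column = paste0("ratio_c", 1:9), cutoff = 2.0,
                      achieved_fpr = 0.05)
  class(calib) <- c("calibration", "data.frame")
  es <- enrichment_score(rm, calib)
  expect_equal(es$es[es$protein_id == "Pmid"], 8L)  # 1.9 fails, 2.0 passes
  expect_equal(es$es[es$protein_id == "Pall"], 9L)
  expect_equal(es$es[es$protein_id == "Pnone"], 0L)
  expect_equal(es$n_evaluable, rep(9L, 3))

  # missing ratios are excluded from the count and the evaluable tally
  rm$ratios["Pall", 1:5] <- NA
  es2 <- enrichment_score(rm, calib)
  expect_equal(es2$es[es2$protein_id == "Pall"], 4L)
  expect_equal(es2$n_evaluable[es2$protein_id == "Pall"], 4L)

  calib_bad <- calib[-1, ]
  class(calib_bad) <- c("calibration", "data.frame")
  expect_error(enrichment_score(rm, calib_bad), "match")

  hits <- call_hits(es, min_es = 5)
  expect_equal(hits$hit[hits$protein_id == "Pmid"], TRUE)   # es 8
  expect_equal(hits$hit[hits$protein_id == "Pnone"], FALSE)
  expect_equal(hits$protein_id, c("Pall", "Pmid", "Pnone"))  # es desc
  expect_true(all(call_hits(es, min_es = 0)$hit))
  expect_error(call_hits(es, min_es = 10), "min_es")

  # boundary: es exactly at min_es is a hit, one below is not
  es_edge <- data.frame(protein_id = c("A", "B"), es = c(5L, 4L),
                        n_evaluable = c(9L, 9L))
  attr(es_edge, "n_pairs") <- 9L
  h <- call_hits(es_edge, min_es = 5)
  expect_equal(h$hit[h$protein_id == "A"], TRUE)
  expect_equal(h$hit[h$protein_id == "B"], FALSE)
})

test_that("ES is monotone: raising any single ratio never lowers it", {
  set.seed(77)
  sim <- simulate_experiment(sim_config(n_proteins = 80, seed = 21))
  rm <- compute_ratio_matrix(median_normalize(sim$table))
  ctl <- label_controls(rownames(rm$ratios), sim$control_lists$pc,
                        sim$control_lists$nc)
  calib <- calibrate_cutoffs(rm, ctl)
  base_es <- enrichment_score(rm, calib)
  for (rep in 1:20) {
    i <- sample(nrow(rm$ratios), 1)
    j <- sample(ncol(rm$ratios), 1)
    if (is.na(rm$ratios[i, j])) next
    bumped <- rm
    bumped$ratios[i, j] <- bumped$ratios[i, j] * (1 + runif(1, 0, 3))
    es2 <- enrichment_score(bumped, calib)
    expect_gte(es2$es[i], base_es$es[i])
  }
})

test_that("global calibration pools columns into one cutoff", {
  sim <- simulate_experiment(sim_config(n_proteins = 200, seed = 31))
  rm <- compute_ratio_matrix(median_normalize(sim$table))
  ctl <- label_controls(rownames(rm$ratios), sim$control_lists$pc,
                        sim$control_lists$nc)
  calib <- calibrate_cutoffs(rm, ctl, global = TRUE)
  expect_equal(length(unique(calib$cutoff)), 1L)
  expect_lte(calib$achieved_fpr[1], 0.1)
})
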