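# Peptide mapping, topology classification, cleavage bounding and
# tryptic digestion. Coordinates are 1-based inclusive throughout.

test_that("peptides map to exact 1-based inclusive coordinates", {
  m <- map_peptides("AGTK", "MKAGTKLL")
  expect_equal(m$start, 3L)
  expect_equal(m$end, 6L)
  expect_false(m$ambiguous)

  whole <- map_peptides("MKAGTKLL", "MKAGTKLL")
  expect_equal(c(whole$start, whole$end), c(1L, 8L))

  amb <- map_peptides("AA", "AAA")
  expect_equal(amb$start, c(1L, 2L))
  expect_equal(amb$end, c(2L, 3L))
  expect_true(all(amb$ambiguous))
  expect_equal(amb$n_occurrences, c(2L, 2L))

  un <- map_peptides("WWW", "MKAGTKLL")
  expect_false(un$mapped)
  expect_true(is.na(un$start))

  expect_error(map_peptides("", "MKAGT"), "empty")

  # I/L equivalence toggle, off by default
  expect_false(map_peptides("AILK", "MALLKG")$mapped)
  expect_true(map_peptides("ALIK", "MALLKG", il_equivalent = TRUE)$mapped)
})

test_that("mapping agrees with a brute-force substring scan", {
  set.seed(501)
  for (rep in 1:30) {
    sq <- random_aa(sample(20:200, 1))
    s <- sample(nchar(sq) - 4, 1)
    pep <- substr(sq, s, s + sample(2:4, 1))
    m <- map_peptides(pep, sq)
    occ <- oracle_occurrences(pep, sq)
    expect_equal(m$start, occ)
    expect_equal(m$n_occurrences[1], length(occ))
  }
})

test_that("topology classification labels every intersected segment", {
  topo <- topology_model("T1", strrep("A", 160),
                         data.frame(segment_type = c("extracellular", "TM",
                                                     "cytoplasmic"),
                                    start = c(1, 101, 122),
                                    end = c(100, 121, 160)))
  mk <- function(start, end)
    data.frame(peptide = "X", start = start, end = end, n_occurrences = 1L,
               ambiguous = FALSE, mapped = TRUE)
  cl <- classify_topology(mk(3, 6), topo)
  expect_equal(cl$regions, "extracellular")
  expect_true(cl$extracellular_only)

  straddle <- classify_topology(mk(95, 105), topo)
  expect_equal(straddle$regions, "extracellular,TM")
  expect_false(straddle$extracellular_only)

  # segment gap: residues outside every annotation
  topo_gap <- topology_model("T2", strrep("A", 160),
                             data.frame(segment_type = c("extracellular",
                                                         "TM"),
                                        start = c(1, 120),
                                        end = c(100, 140)))
  gap <- classify_topology(mk(105, 110), topo_gap)
  expect_equal(gap$regions, "unannotated")

  # ambiguous peptides are dropped with a warning
  amb <- map_peptides("AA", strrep("A", 160))
  expect_warning(out <- classify_topology(amb, topo), "ambiguous")
  expect_equal(nrow(out), 0L)
})

test_that("cleavage bound lies between terminal peptide and TM segment", {
  topo <- topology_model("Nout1", strrep("A", 600),
                         data.frame(segment_type = c("extracellular", "TM",
                                                     "cytoplasmic"),
                                    start = c(1, 540, 561),
                                    end = c(539, 560, 600)))
  classified <- data.frame(peptide = c("p1", "p2"),
                           start = c(10, 500), end = c(20, 530),
                           regions = "extracellular",
                           extracellular_only = TRUE)
  call <- call_shedding(classified, topo)
  expect_true(call$all_extracellular)
  expect_equal(call$orientation, "N-terminal-out")
  expect_equal(call$cleavage_bound, c(531L, 539L))

  # a peptide overlapping the TM blocks the call
  tm_pep <- rbind(classified,
                  data.frame(peptide = "p3", start = 535, end = 545,
                             regions = "extracellular,TM",
                             extracellular_only = FALSE))
  call2 <- call_shedding(tm_pep, topo)
  expect_false(call2$all_extracellular)
  expect_null(call2$cleavage_bound)

  # C-terminal-out layout: cytoplasmic first, ectodomain after the TM
  topo_c <- topology_model("Cout", strrep("A", 400),
                           data.frame(segment_type = c("cytoplasmic", "TM",
                                                       "extracellular"),
                                      start = c(1, 131, 151),
                                      end = c(130, 150, 400)))
  cl_c <- data.frame(peptide = "p1", start = 200, end = 250,
                     regions = "extracellular", extracellular_only = TRUE)
  call3 <- call_shedding(cl_c, topo_c)
  expect_equal(call3$orientation, "C-terminal-out")
  expect_equal(call3$cleavage_bound, c(151L, 199L))

  # no TM segment: shedding consistency still reported, no bound
  topo_sol <- topology_model("Sol", strrep("A", 100),
                             data.frame(segment_type = "extracellular",
                                        start = 1, end = 100))
  call4 <- call_shedding(
    data.frame(peptide = "p1", start = 5, end = 20,
               regions = "extracellular", extracellular_only = TRUE),
    topo_sol)
  expect_true(call4$all_extracellular)
  expect_null(call4$cleavage_bound)
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  d <- tryptic_digest("MKRAGTPKLR")
  expect_equal(d$peptide, c("MK", "R", "AGTPK", "LR"))
  expect_equal(d$start, c(1L, 3L, 4L, 9L))
  expect_equal(d$end, c(2L, 3L, 8L, 10L))

  expect_equal(tryptic_digest("MAGTC")$peptide, "MAGTC")  # no K/R
  expect_equal(nrow(tryptic_digest("")), 0L)

  # proline suppression and the allow-P toggle
  expect_equal(tryptic_digest("AKPR")$peptide, "AKPR")
  expect_equal(tryptic_digest("AKPR", allow_p = TRUE)$peptide,
               c("AK", "PR"))

  # missed cleavages: all concatenations of <= m+1 adjacent fragments
  d1 <- tryptic_digest("MKR", missed_cleavages = 1)
  expect_setequal(d1$peptide, c("MK", "R", "MKR"))
  d2 <- tryptic_digest("MKRAGTPKLR", missed_cleavages = 2)
  expect_setequal(d2$peptide[d2$n_missed == 2],
                  c("MKRAGTPK", "RAGTPKLR"))
})

test_that("zero-missed-cleavage peptides concatenate to the sequence", {
  set.seed(502)
  for (rep in 1:20) {
    sq <- random_aa(sample(10:120, 1))
    for (allow_p in c(FALSE, TRUE)) {
      d <- tryptic_digest(sq, allow_p = allow_p)
      expect_equal(paste(d$peptide, collapse = ""), sq)
      expect_equal(d$start[1], 1L)
      expect_equal(d$end[nrow(d)], nchar(sq))
    }
  }
})

test_that("simulated shedding cases round-trip through the full analysis", {
  set.seed(503)
  for (rep in 1:10) {
    n_out <- sample(c(TRUE, FALSE), 1)
    ec_len <- sample(80:150, 1)
    tail_len <- sample(30:60, 1)
    len <- ec_len + 21 + tail_len
    lay <- if (n_out) {
      data.frame(segment_type = c("extracellular", "TM", "cytoplasmic"),
                 start = c(1, ec_len + 1, ec_len + 22),
                 end = c(ec_len, ec_len + 21, len))
    } else {
      data.frame(segment_type = c("cytoplasmic", "TM", "extracellular"),
                 start = c(1, tail_len + 1, tail_len + 22),
                 end = c(tail_len, tail_len + 21, len))
    }
    sc <- simulate_shedding_case(len, lay, n_peptides = 3, seed = 600 + rep)
    an <- shedding_analysis(sc$peptides$peptide, sc$topology)
    expect_true(all(an$map$mapped))
    expect_true(all(!an$map$ambiguous))
    expect_true(an$call$all_extracellular)
    ec <- lay[lay$segment_type == "extracellular", ]
    tm <- lay[lay$segment_type == "TM", ]
    if (n_out) {
      gap_start <- max(sc$peptides$end) + 1L
      want <- if (gap_start <= tm$start - 1L) c(gap_start, tm$start - 1L)
    } else {
      gap_end <- min(sc$peptides$start) - 1L
      want <- if (tm$end + 1L <= gap_end) c(tm$end + 1L, gap_end)
    }
    expect_equal(call_shedding(an$classified, sc$topology)$cleavage_bound,
                 want)
  }
})
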