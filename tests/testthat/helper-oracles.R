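# Independent brute-force oracles, deliberately naive: each re-derives its
# quantity by direct enumeration so it cannot share a defect with the
# implementation it checks.

# FPR over all observed candidate cutoffs by direct tail counting.
oracle_fpr_curve <- function(pc, nc) {
  cand <- sort(unique(c(pc, nc)))
  rows <- lapply(cand, function(r) {
    npc <- sum(pc >= r)
    nnc <- sum(nc >= r)
    fpr <- if (npc == 0 && nnc == 0) NA_real_
    else if (npc == 0) Inf
    else (nnc / length(nc)) / (npc / length(pc))
    data.frame(cutoff = r, n_pc = npc, n_nc = nnc, fpr = fpr)
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$fpr), , drop = FALSE]
}

# Smallest candidate whose whole suffix sits at or below the target.
oracle_select_cutoff <- function(curve, target) {
  for (i in seq_len(nrow(curve))) {
    if (all(curve$fpr[i:nrow(curve)] <= target))
      return(list(cutoff = curve$cutoff[i], achieved_fpr = curve$fpr[i]))
  }
  NULL
}

# BH step-up by the O(m^2) double loop.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[ord[j]] * m / j, 0)
    adj[ord[i]] <- min(1, min(vals))
  }
  adj
}

# Every occurrence of a peptide by scanning all start positions.
oracle_occurrences <- function(peptide, sequence) {
  m <- nchar(peptide)
  hits <- integer(0)
  for (s in seq_len(max(nchar(sequence) - m + 1, 0))) {
    if (substr(sequence, s, s + m - 1) == peptide) hits <- c(hits, s)
  }
  hits
}

# Upper-tail hypergeometric p by summing the exact pmf over j >= k.
oracle_hyper_p <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Random amino-acid sequence for mapping/digestion property tests.
random_aa <- function(n, alphabet = c("A", "C", "G", "K", "R", "S", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
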