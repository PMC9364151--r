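# Empirical-Bayes moderated two-sample t-test on log2 reporter intensities.
#
# Per-protein sample variances are shrunk towards a scaled
# inverse-chi-square prior fitted across all proteins by moment matching
# on log variances (digamma/trigamma), adding df_prior degrees of freedom
# to each protein's test. Enrichment is called at adjusted p < alpha and
# log2 fold change > fc_threshold (both strict).

#' Per-protein group statistics on the log2 scale
#'
#' Computes, over present values, the case-minus-control difference of
#' log2 means, the pooled within-group sample variance and its residual
#' degrees of freedom. Proteins without at least one present value in each
#' group are excluded (no imputation); exclusions are reported in
#' `attr(, "excluded")`.
#'
#' @param x A [protein_quant] object (linear intensities).
#' @return Data frame `protein_id`, `log2fc`, `s2`, `df_residual`,
#'   `n_case_present`, `n_ctrl_present`. Proteins with `df_residual = 0`
#'   (one present value per group) carry `s2 = NA` and rely entirely on
#'   the prior downstream.
#' @export
group_stats <- function(x) {
  stopifnot(inherits(x, "protein_quant"))
  lg <- log2(x$intensity)
  case <- lg[, x$design == "case", drop = FALSE]
  ctrl <- lg[, x$design == "control", drop = FALSE]
  n1 <- rowSums(!is.na(case))
  n2 <- rowSums(!is.na(ctrl))
  keep <- n1 >= 1 & n2 >= 1
  excluded <- rownames(lg)[!keep]
  case <- case[keep, , drop = FALSE]
  ctrl <- ctrl[keep, , drop = FALSE]
  n1 <- n1[keep]; n2 <- n2[keep]
  m1 <- rowMeans(case, na.rm = TRUE)
  m2 <- rowMeans(ctrl, na.rm = TRUE)
  ss <- rowSums((case - m1)^2, na.rm = TRUE) +
        rowSums((ctrl - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2L
  s2 <- ifelse(df > 0, ss / pmax(df, 1L), NA_real_)
  out <- data.frame(protein_id = rownames(case),
                    log2fc = unname(m1 - m2),
                    s2 = unname(s2),
                    df_residual = unname(as.integer(df)),
                    n_case_present = unname(as.integer(n1)),
                    n_ctrl_present = unname(as.integer(n2)),
                    row.names = NULL)
  attr(out, "excluded") <- excluded
  out
}

#' Fit the variance prior by moment matching on log variances
#'
#' Fits a scaled inverse-chi-square prior (`df_prior`, `s2_prior`) to the
#' observed sample variances, assuming s2 | sigma2 ~ sigma2 * chi2_df / df.
#' On the log scale, E log(s2) and Var log(s2) have closed forms in
#' digamma/trigamma, so the prior parameters follow from matching the
#' empirical mean and the excess variance of log(s2) beyond what equal
#' true variances would produce. When there is no excess dispersion the
#' prior is degenerate: `df_prior = Inf` and `s2_prior` the common value.
#'
#' @param s2 Numeric vector of sample variances (`NA` entries ignored).
#' @param df_residual Integer vector of their residual df.
#' @return List with `df_prior` (may be `Inf`) and `s2_prior`. Zero
#'   variances are floored at `min positive s2 * 1e-3` for the fit only.
#' @export
fit_variance_prior <- function(s2, df_residual) {
  keep <- !is.na(s2) & df_residual >= 1
  s2 <- s2[keep]
  df <- df_residual[keep]
  if (length(s2) < 2)
    stop("need at least two proteins with df_residual >= 1 to fit the prior")
  if (any(s2 == 0)) {
    pos <- s2[s2 > 0]
    if (!length(pos)) stop("all sample variances are zero")
    s2[s2 == 0] <- min(pos) * 1e-3
  }
  z <- log(s2)
  if (stats::var(z) == 0)   # no dispersion at all: prior is the common value
    return(list(df_prior = Inf, s2_prior = s2[1]))
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  excess <- stats::var(e) - mean(trigamma(df / 2))
  if (is.na(excess) || excess <= 0) {
    return(list(df_prior = Inf, s2_prior = exp(e_mean)))
  }
  df_prior <- 2 * trigamma_inverse(excess)
  s2_prior <- exp(e_mean + digamma(df_prior / 2) - log(df_prior / 2))
  list(df_prior = df_prior, s2_prior = s2_prior)
}

# Solve trigamma(y) = x by Newton iteration on the monotone decreasing
# trigamma; convergence is fast from the large-y asymptote y ~ 1/x.
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated t-statistics with shrunken variances
#'
#' The posterior variance of each protein blends its pooled sample
#' variance with the prior: `s2_post = (df_prior * s2_prior +
#' df_residual * s2) / (df_prior + df_residual)` (limit `s2_prior` when
#' `df_prior` is infinite). The moderated t is the log2 fold change over
#' its standard error based on `s2_post`, referred to a t distribution
#' with `df_residual + df_prior` degrees of freedom (total df capped at
#' 1e6 for the p-value when the prior df is infinite).
#'
#' @param stats A [group_stats()] data frame.
#' @param prior A [fit_variance_prior()] list.
#' @return The input with `s2_post`, `df_total`, `t_mod`, `p` and a
#'   `degenerate` flag (`s2_post == 0`, where p collapses to 0 or 1).
#' @export
moderated_t <- function(stats, prior) {
  d0 <- prior$df_prior
  s02 <- prior$s2_prior
  df <- stats$df_residual
  s2 <- ifelse(is.na(stats$s2), 0, stats$s2)
  if (is.infinite(d0)) {
    s2_post <- rep(s02, nrow(stats))
    df_total <- rep(1e6, nrow(stats))
  } else {
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
    df_total <- pmin(df + d0, 1e6)
  }
  se2 <- s2_post * (1 / stats$n_case_present + 1 / stats$n_ctrl_present)
  degenerate <- se2 == 0
  t_mod <- ifelse(degenerate,
                  ifelse(stats$log2fc == 0, 0, Inf * sign(stats$log2fc)),
                  stats$log2fc / sqrt(se2))
  p <- ifelse(degenerate,
              ifelse(stats$log2fc == 0, 1, 0),
              2 * stats::pt(-abs(t_mod), df = df_total))
  out <- stats
  out$s2_post <- s2_post
  out$df_total <- df_total
  out$t_mod <- t_mod
  out$p <- p
  out$degenerate <- degenerate
  attr(out, "prior") <- prior
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard step-up FDR adjustment: in ascending order,
#' `adj_p(i) = min over j >= i of p(j) * m / j`, capped at 1 and mapped
#' back to the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed,
#'   propagated).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call enrichment from the moderated test
#'
#' A protein is enriched when its adjusted p-value is below `alpha` and
#' its log2 fold change is above `fc_threshold` — both strictly, so a
#' protein sitting exactly on either boundary is not called.
#'
#' @param result A [moderated_t()] data frame (an `adj_p` column is added
#'   from [bh_adjust()] if absent).
#' @param fc_threshold Log2 fold-change threshold (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return The input with `adj_p` and logical `enriched` columns.
#' @export
call_enriched <- function(result, fc_threshold = 1.0, alpha = 0.05) {
  if (is.null(result$adj_p)) result$adj_p <- bh_adjust(result$p)
  result$enriched <- result$adj_p < alpha & result$log2fc > fc_threshold
  result
}

#' Moderated-test enrichment path, end to end
#'
#' Convenience wrapper: [group_stats()] on a (median-normalized) quant
#' table, [fit_variance_prior()], [moderated_t()], [bh_adjust()] and
#' [call_enriched()].
#'
#' @param x A [protein_quant] object, normally after [median_normalize()].
#' @param fc_threshold Log2 fold-change threshold (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Per-protein data frame with `log2fc`, `t_mod`, `p`, `adj_p`,
#'   `enriched`; the fitted prior in `attr(, "prior")`, excluded proteins
#'   in `attr(, "excluded")`.
#' @export
moderated_test <- function(x, fc_threshold = 1.0, alpha = 0.05) {
  st <- group_stats(x)
  prior <- fit_variance_prior(st$s2, st$df_residual)
  res <- moderated_t(st, prior)
  res$adj_p <- bh_adjust(res$p)
  res <- call_enriched(res, fc_threshold = fc_threshold, alpha = alpha)
  attr(res, "excluded") <- attr(st, "excluded")
  attr(res, "prior") <- prior
  res
}
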