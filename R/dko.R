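# Knockout-vs-control comparison: per-CpG methylation differences, per-CpG
# Fisher exact tests with Benjamini-Hochberg correction, and a two-factor
# ANOVA apportioning variance between cell line and knockout condition.

.check_design <- function(samples) {
  d <- samples[samples$condition %in% c("control", "knockout"), , drop = FALSE]
  tab <- table(d$lineage, d$condition)
  if (ncol(tab) < 2 || any(tab != 1))
    stopf("design must be balanced: one control and one knockout sample per lineage")
  d
}

#' Per-CpG methylation difference between knockout and control
#'
#' Unweighted mean of per-sample methylation percentages within each
#' condition; the difference is knockout minus control, in percentage
#' points.
#'
#' @param mat A `cpg_matrix` whose samples carry `condition` labels
#'   (`control`/`knockout`) and a paired lineage per condition.
#' @return Numeric vector of deltas in [-100, 100].
#' @export
per_site_delta <- function(mat) {
  .check_design(mat$samples)
  ko <- mat$samples$condition == "knockout"
  ct <- mat$samples$condition == "control"
  rowMeans(mat$meth[, ko, drop = FALSE]) -
    rowMeans(mat$meth[, ct, drop = FALSE])
}

#' Per-CpG Fisher's exact tests between conditions
#'
#' Methylated/unmethylated call counts are pooled across the samples of
#' each condition into a per-site 2x2 table; the two-sided exact p-value
#' (point-probability method) is computed and adjusted across all tested
#' sites by Benjamini-Hochberg. Sites with zero pooled calls in a condition
#' are skipped and flagged.
#'
#' @param counts_meth,counts_unmeth Site x sample matrices of call counts
#'   (e.g. derived from a `cpg_matrix`'s `cov` and `meth`).
#' @param samples A [sample_info()] `data.frame` matching the columns.
#' @param q_threshold Significance cutoff on the adjusted p (default 0.01).
#' @return `data.frame` per site: `delta` (percentage points), `p`, `q`,
#'   `significant`, `skipped`.
#' @export
fisher_per_site <- function(counts_meth, counts_unmeth, samples,
                            q_threshold = 0.01) {
  .check_design(samples)
  ko <- samples$condition == "knockout"
  ct <- samples$condition == "control"
  m_ko <- rowSums(counts_meth[, ko, drop = FALSE])
  u_ko <- rowSums(counts_unmeth[, ko, drop = FALSE])
  m_ct <- rowSums(counts_meth[, ct, drop = FALSE])
  u_ct <- rowSums(counts_unmeth[, ct, drop = FALSE])
  n <- length(m_ko)
  skipped <- (m_ko + u_ko) == 0 | (m_ct + u_ct) == 0
  p <- rep(NA_real_, n)
  for (i in which(!skipped)) {
    p[i] <- fisher.test(matrix(c(m_ko[i], u_ko[i], m_ct[i], u_ct[i]),
                               nrow = 2))$p.value
  }
  q <- rep(NA_real_, n)
  q[!skipped] <- p.adjust(p[!skipped], method = "BH")
  pct_ko <- 100 * m_ko / (m_ko + u_ko)
  pct_ct <- 100 * m_ct / (m_ct + u_ct)
  data.frame(delta = pct_ko - pct_ct, p = p, q = q,
             significant = !is.na(q) & q < q_threshold, skipped = skipped)
}

#' Two-factor ANOVA of methylation variance: cell line vs condition
#'
#' Fits `methylation ~ lineage + condition` (no interaction) on
#' per-(site, sample) methylation percentages over a seeded random
#' subsample of sites, and reports the F statistic and p-value of both
#' factors. A fit with (near) zero residual variance is flagged degenerate.
#'
#' @param mat A `cpg_matrix` with a balanced control/knockout design.
#' @param subsample_size Maximum number of sites used (default 50000).
#' @param seed RNG seed for the site subsample.
#' @return List: `F_line`, `p_line`, `F_condition`, `p_condition`,
#'   `n_sites`, `degenerate`.
#' @export
variance_anova <- function(mat, subsample_size = 50000, seed = 1) {
  .check_design(mat$samples)
  set.seed(seed)
  n <- nrow(mat$sites)
  rows <- if (n > subsample_size) sort(sample.int(n, subsample_size))
  else seq_len(n)
  keep <- mat$samples$condition %in% c("control", "knockout")
  m <- mat$meth[rows, keep, drop = FALSE]
  long <- data.frame(
    meth = as.numeric(m),
    lineage = factor(rep(mat$samples$lineage[keep], each = length(rows))),
    condition = factor(rep(mat$samples$condition[keep],
                           each = length(rows))))
  fit <- aov(meth ~ lineage + condition, data = long)
  s <- summary(fit)[[1]]
  rn <- trimws(rownames(s))
  resid_ms <- s[which(rn == "Residuals"), "Mean Sq"]
  degenerate <- !is.finite(resid_ms) || resid_ms < 1e-12
  li <- which(rn == "lineage"); co <- which(rn == "condition")
  list(F_line = s[li, "F value"],
       p_line = s[li, "Pr(>F)"],
       F_condition = s[co, "F value"],
       p_condition = s[co, "Pr(>F)"],
       n_sites = length(rows), degenerate = degenerate)
}
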