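# Fixtures are built in code; no data files.

# A cpg_matrix assembled directly from a methylation-percentage matrix.
# Default design mirrors the study: 2 lineages x (1 parental + 7 clonal).
toy_matrix <- function(meth, chrom = NULL, pos = NULL, cov = 30,
                       n_clones = 7, n_lineages = 2) {
  meth <- as.matrix(meth)
  n <- nrow(meth)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq(100L, by = 50L, length.out = n)
  ids <- character(0); roles <- character(0); lins <- character(0)
  for (L in seq_len(n_lineages)) {
    ids <- c(ids, sprintf("L%d-P", L), sprintf("L%d-C%d", L,
                                               seq_len(n_clones)))
    roles <- c(roles, "parental", rep("clonal", n_clones))
    lins <- c(lins, rep(sprintf("L%d", L), n_clones + 1))
  }
  stopifnot(ncol(meth) == length(ids))
  colnames(meth) <- ids
  covm <- matrix(cov, n, ncol(meth), dimnames = list(NULL, ids))
  structure(list(
    sites = data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE),
    meth = meth, cov = covm,
    samples = sample_info(ids, roles, lins)), class = "cpg_matrix")
}

# matrix whose 16 columns are (P, C1..C7) x 2 lineages with constant rows
constant_row_matrix <- function(values_by_site, ...) {
  toy_matrix(matrix(rep(values_by_site, each = 16), ncol = 16,
                    byrow = TRUE), ...)
}

# independent interval-membership oracles, written as explicit loops so the
# vectorized implementations are checked against a second route
oracle_fidelity <- function(v) {
  hits <- 0
  for (x in v) {
    if ((x >= 0 && x <= 10) || (x >= 40 && x <= 60) || (x >= 90 && x <= 100))
      hits <- hits + 1
  }
  hits / length(v)
}

oracle_bin <- function(x) {
  if (x < 10) "low"
  else if (x < 40) "low_intermediate"
  else if (x < 60) "intermediate"
  else if (x < 90) "high_intermediate"
  else "high"
}

oracle_density <- function(pos, i, window = 100, cap = 30) {
  cnt <- 0
  for (j in seq_along(pos))
    if (j != i && abs(pos[j] - pos[i]) <= window) cnt <- cnt + 1
  min(cnt, cap)
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
# (point-probability method) for table rbind(c(a, b), c(c, d))
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  p_obs <- dhyper(a, m, n, k)
  xs <- lo:hi
  sum(dhyper(xs, m, n, k)[dhyper(xs, m, n, k) <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j_range <- i:m
    q[o[i]] <- min(1, min(m * p[o[j_range]] / j_range))
  }
  q
}

# closed-form mean drift of the per-allele methylation chain
drift_mean <- function(m0, gain, loss, n) {
  mstar <- gain / (gain + loss)
  mstar + (m0 - mstar) * (1 - gain - loss)^n
}

# exact variance of the clone-population methylation fraction after n
# divisions (no population cap) from a founder cell with allele states
# (s1, s2): leaves of the two allele-lineage binary trees, covariances by
# depth of the last common ancestor
oracle_population_variance <- function(s1, s2, gain, loss, n) {
  lam <- 1 - gain - loss
  mstar <- gain / (gain + loss)
  q <- function(k, s) mstar + ((if (s) 1 else 0) - mstar) * lam^k
  tree_var <- function(s) {
    mu <- q(n, s)
    total <- 2^n * mu * (1 - mu)   # diagonal terms
    for (d in 0:(n - 1)) {
      # pair of leaves whose last common ancestor sits at depth d: given the
      # ancestor state, the two leaves are independent, each n - d
      # transmissions away
      anc <- q(d, s)
      eij <- anc * q(n - d, TRUE)^2 + (1 - anc) * q(n - d, FALSE)^2
      npairs <- 2^(d + 1) * 4^(n - d - 1)
      total <- total + npairs * (eij - mu^2)
    }
    total / 4^n
  }
  (tree_var(s1) + tree_var(s2)) / 4
}
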