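# Conditioning clonal outcomes on the parental methylation state, counting
# clonal state combinations UpSet-style, and scoring observed clone
# distributions against faithful-mixture vs stochastic transmission models.

.lineage_parts <- function(mat, lineage) {
  pcol <- which(mat$samples$lineage == lineage &
                  mat$samples$role == "parental")
  ccol <- clonal_columns(mat, lineage)
  if (length(pcol) != 1 || length(ccol) < 1)
    stopf("lineage '%s' needs one parental and >= 1 clonal samples", lineage)
  list(parental = pcol, clonal = ccol)
}

#' Clonal methylation distributions conditioned on the parental state
#'
#' Sites are partitioned by the parental sample's observed state bin (see
#' [bin_state()]); all clonal values of the lineage are pooled per bin.
#'
#' @param mat A `cpg_matrix`.
#' @param lineage Lineage to analyse.
#' @return Named list (one element per parental bin) with `sites`,
#'   `clonal_values` and `histogram` (clonal values binned by state).
#' @export
conditional_distribution <- function(mat, lineage) {
  lp <- .lineage_parts(mat, lineage)
  pbin <- bin_state(mat$meth[, lp$parental])
  out <- lapply(levels(pbin), function(b) {
    rows <- which(pbin == b)
    vals <- as.numeric(mat$meth[rows, lp$clonal, drop = FALSE])
    list(parental_bin = b, sites = rows, clonal_values = vals,
         histogram = table(bin_state(vals)))
  })
  names(out) <- levels(pbin)
  out
}

#' UpSet-style counts of clonal state combinations per parental bin
#'
#' Per site, the set of distinct state bins observed across the lineage's
#' clonal lines forms an unordered combination. Combinations are counted
#' within each parental state bin; the `top_n` most frequent are reported
#' (ties broken lexicographically by bin order low to high). Truncation
#' affects reporting only: `n_sites_bin` and the distinct-state histogram
#' always cover all sites of the bin.
#'
#' @param mat A `cpg_matrix`.
#' @param lineage Lineage to analyse.
#' @param top_n Number of combinations reported per parental bin (default 5).
#' @return List per parental bin with `n_sites_bin`, `combinations`
#'   (`data.frame`: `combination`, `n_sites`) and
#'   `distinct_state_histogram` (sites by number of unique clonal bins).
#' @export
combination_counts <- function(mat, lineage, top_n = 5) {
  lp <- .lineage_parts(mat, lineage)
  pbin <- bin_state(mat$meth[, lp$parental])
  cb <- matrix(as.integer(bin_state(as.numeric(
    mat$meth[, lp$clonal, drop = FALSE]))), nrow = nrow(mat$sites))
  combo <- apply(cb, 1, function(r)
    paste(.state_bins[sort(unique(r))], collapse = "+"))
  n_distinct <- apply(cb, 1, function(r) length(unique(r)))
  out <- lapply(levels(pbin), function(b) {
    rows <- which(pbin == b)
    tab <- table(combo[rows])
    # sort by count desc, ties by bin-order-lexicographic combination key
    key <- vapply(names(tab), function(k)
      paste(match(strsplit(k, "+", fixed = TRUE)[[1]], .state_bins),
            collapse = ""), character(1))
    o <- order(-as.integer(tab), key)
    top <- head(o, top_n)
    list(parental_bin = b, n_sites_bin = length(rows),
         combinations = data.frame(combination = names(tab)[top],
                                   n_sites = as.integer(tab)[top],
                                   stringsAsFactors = FALSE),
         distinct_state_histogram = table(factor(n_distinct[rows],
                                                 levels = 1:5)))
  })
  names(out) <- levels(pbin)
  out
}

#' Founder-state composition of a parental population
#'
#' Probabilities of the three single-cell symmetric states (0, 50, 100\%)
#' among founder cells. The implied population mean is
#' `50 * p50 + 100 * p100`.
#'
#' @param p0,p50,p100 State probabilities; must sum to 1.
#' @return List of class `founder_composition`.
#' @export
founder_composition <- function(p0, p50, p100) {
  if (abs(p0 + p50 + p100 - 1) > 1e-8 || any(c(p0, p50, p100) < 0))
    stopf("founder state probabilities must be non-negative and sum to 1")
  structure(list(p0 = p0, p50 = p50, p100 = p100),
            class = "founder_composition")
}

#' Estimate a founder composition from observed clone values
#'
#' Assigns each clone value to the nearest symmetric state (0/50/100) and
#' takes smoothed frequencies (uniform prior via `pseudocount` per state).
#' The composition is not identifiable from the parental mean alone; this
#' estimator is intended for simulator validation and model scoring.
#'
#' @param clone_values Clonal methylation percentages.
#' @param pseudocount Added to each state's count (default 1).
#' @return A [founder_composition()].
#' @export
estimate_founder_composition <- function(clone_values, pseudocount = 1) {
  check_percent(clone_values)
  nearest <- c(0, 50, 100)[apply(abs(outer(clone_values, c(0, 50, 100),
                                           "-")), 1, which.min)]
  cnt <- table(factor(nearest, levels = c(0, 50, 100))) + pseudocount
  p <- as.numeric(cnt / sum(cnt))
  founder_composition(p[1], p[2], p[3])
}

.meth_distribution <- function(support, pmf, draws = numeric(0)) {
  structure(list(support = support, pmf = pmf, draws = draws),
            class = "meth_distribution")
}

#' Expected clone methylation under faithful transmission
#'
#' A clone founder is drawn from the composition; faithful expansion keeps
#' the clone population at the founder level, and the observed value is a
#' binomial read-sampling of that level at the given coverage. The result
#' is a mixture over the 0/50/100\% founder states on the 1/coverage grid.
#'
#' @param comp A [founder_composition()].
#' @param coverage Read coverage per site.
#' @param n_draws Optional number of Monte-Carlo draws to attach.
#' @return A `meth_distribution` (support in percent, exact pmf, draws).
#' @export
faithful_expectation <- function(comp, coverage, n_draws = 0) {
  k <- 0:coverage
  w <- c(comp$p0, comp$p50, comp$p100)
  lv <- c(0, 0.5, 1)
  pmf <- colSums(w * t(vapply(lv, function(p) dbinom(k, coverage, p),
                              numeric(length(k)))))
  draws <- numeric(0)
  if (n_draws > 0) {
    fl <- sample(lv, n_draws, replace = TRUE, prob = w)
    draws <- 100 * rbinom(n_draws, coverage, fl) / coverage
  }
  .meth_distribution(100 * k / coverage, pmf, draws)
}

#' Expected clone methylation under stochastic transmission
#'
#' The clone population level equals the parental mean; observed values are
#' binomial read-sampling around it (variance m(1-m)/coverage on the
#' proportion scale).
#'
#' @param parental_mean Parental methylation percentage.
#' @param coverage Read coverage per site.
#' @param n_draws Optional number of Monte-Carlo draws to attach.
#' @return A `meth_distribution`.
#' @export
stochastic_expectation <- function(parental_mean, coverage, n_draws = 0) {
  check_percent(parental_mean)
  k <- 0:coverage
  pmf <- dbinom(k, coverage, parental_mean / 100)
  draws <- numeric(0)
  if (n_draws > 0)
    draws <- 100 * rbinom(n_draws, coverage, parental_mean / 100) / coverage
  .meth_distribution(100 * k / coverage, pmf, draws)
}

#' Score observed clone values against the two transmission models
#'
#' Observed values are rounded to the 1/coverage support grid shared by the
#' two expectation distributions, and the per-site log-likelihood under
#' each model is computed with a probability floor for zero-probability
#' observations.
#'
#' @param observed Clonal methylation percentages for one site.
#' @param faithful,stochastic `meth_distribution` objects on the same
#'   support.
#' @param floor Probability floor (default 1e-12).
#' @return List: `loglik_faithful`, `loglik_stochastic`, `margin`
#'   (faithful minus stochastic) and `winner`.
#' @export
model_score <- function(observed, faithful, stochastic, floor = 1e-12) {
  if (length(faithful$support) != length(stochastic$support))
    stopf("expectation distributions must share a support discretization")
  coverage <- length(faithful$support) - 1L
  kk <- pmin(pmax(round(observed / 100 * coverage), 0), coverage) + 1L
  ll_f <- sum(log(pmax(faithful$pmf[kk], floor)))
  ll_s <- sum(log(pmax(stochastic$pmf[kk], floor)))
  margin <- ll_f - ll_s
  list(loglik_faithful = ll_f, loglik_stochastic = ll_s, margin = margin,
       winner = if (margin > 0) "faithful" else if (margin < 0)
         "stochastic" else "tie")
}
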