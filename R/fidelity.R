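# Per-CpG fidelity scores and classifications.
#
# Two interval families are implemented exactly as defined, side by side:
#  * fidelity-score intervals are closed: [0,10], [40,60], [90,100];
#  * inheritance-class intervals are half-open: faithful uses [0,10],
#    (40,60], (90,100]; probabilistic uses (10,40], (60,90].
# State bins are half-open below with 90 assigned to "high" ([90,100]),
# so no value is left unbinned.

.fidelity_member <- function(v) {
  (v >= 0 & v <= 10) | (v >= 40 & v <= 60) | (v >= 90 & v <= 100)
}

#' Fidelity score of a CpG across clonal lines
#'
#' Fraction of clonal-line methylation values lying in [0, 10], [40, 60] or
#' [90, 100] percent -- the values consistent with faithful transmission of
#' a single founder cell's symmetric methylation state (0/50/100\%). The
#' denominator is the number of clonal lines supplied (14 in the original
#' design).
#'
#' @param clonal_values Methylation percentages, one per clonal line.
#' @return A value in [0, 1].
#' @export
fidelity_score <- function(clonal_values) {
  check_percent(clonal_values)
  mean(.fidelity_member(clonal_values))
}

#' Per-site fidelity scores over a CpG matrix
#' @param mat A `cpg_matrix`.
#' @return Numeric vector, one score per site.
#' @export
fidelity_scores <- function(mat) {
  m <- mat$meth[, clonal_columns(mat), drop = FALSE]
  rowMeans(.fidelity_member(m))
}

#' Neighbour similarity score
#'
#' For each focal CpG, the closest other CpG on the same chromosome (by
#' absolute genomic distance; ties resolved to the upstream neighbour) is
#' compared per clonal line: lines where the two sites are within 10
#' percentage points (inclusive) are counted, divided by the number of
#' clonal lines. A lone site on its chromosome gets `NA`, not 0.
#'
#' @param mat A `cpg_matrix`.
#' @param clonal_only Use only clonal samples (default) or all samples.
#' @return Numeric vector in [0, 1] with `NA` for lone sites.
#' @export
neighbour_similarity <- function(mat, clonal_only = TRUE) {
  cols <- if (clonal_only) clonal_columns(mat) else seq_len(nrow(mat$samples))
  m <- mat$meth[, cols, drop = FALSE]
  out <- rep(NA_real_, nrow(mat$sites))
  for (ch in unique(mat$sites$chrom)) {
    idx <- which(mat$sites$chrom == ch)
    if (length(idx) < 2) next
    o <- order(mat$sites$pos[idx])
    idx <- idx[o]
    pos <- mat$sites$pos[idx]
    n <- length(pos)
    dprev <- c(Inf, diff(pos))
    dnext <- c(diff(pos), Inf)
    nb <- ifelse(dprev <= dnext, seq_len(n) - 1L, seq_len(n) + 1L)
    diffs <- abs(m[idx, , drop = FALSE] - m[idx[nb], , drop = FALSE])
    out[idx] <- rowMeans(diffs <= 10)
  }
  out
}

#' Local CpG density
#'
#' Number of other retained CpGs within `window` bp (inclusive) of each
#' focal CpG, truncated at `cap`. The focal CpG is excluded from its own
#' count.
#'
#' @param sites `data.frame` with columns `chrom`, `pos`.
#' @param window Distance in bp (default 100).
#' @param cap Upper limit on the count (default 30).
#' @return Integer vector of densities.
#' @export
cpg_density <- function(sites, window = 100, cap = 30) {
  out <- integer(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sort(sites$pos[idx])
    hi <- findInterval(sites$pos[idx] + window, pos)
    lo <- findInterval(sites$pos[idx] - window - 1L, pos)
    out[idx] <- pmin(hi - lo - 1L, cap)
  }
  out
}

.state_bins <- c("low", "low_intermediate", "intermediate",
                 "high_intermediate", "high")

#' Bin a methylation percentage into a state
#'
#' Bins are low [0,10), low intermediate [10,40), intermediate [40,60),
#' high intermediate [60,90) and high [90,100]. The value 90 belongs to
#' high, so every value in [0, 100] receives exactly one bin.
#'
#' @param m Methylation percentages in [0, 100].
#' @return Factor with levels low ... high.
#' @export
bin_state <- function(m) {
  check_percent(m)
  idx <- findInterval(m, c(10, 40, 60, 90)) + 1L
  factor(.state_bins[idx], levels = .state_bins)
}

#' Classify CpGs as probabilistic, faithful or other
#'
#' A CpG is faithful when every clonal line (across all lineages) lies in
#' [0,10], (40,60] or (90,100] percent; probabilistic when at least one
#' clonal line in *each* lineage lies in (10,40] or (60,90]. The two
#' definitions are mutually exclusive; remaining sites are "other".
#'
#' @param mat A `cpg_matrix` with at least one clonal line per lineage.
#' @return Factor per site with levels probabilistic/faithful/other.
#' @export
classify_inheritance <- function(mat) {
  lineages <- unique(mat$samples$lineage[mat$samples$role == "clonal"])
  in_faith <- function(v) (v >= 0 & v <= 10) | (v > 40 & v <= 60) |
    (v > 90 & v <= 100)
  in_prob <- function(v) (v > 10 & v <= 40) | (v > 60 & v <= 90)
  all_clonal <- mat$meth[, clonal_columns(mat), drop = FALSE]
  faithful <- rowMeans(in_faith(all_clonal)) == 1
  prob_per_lin <- vapply(lineages, function(lin) {
    m <- mat$meth[, clonal_columns(mat, lin), drop = FALSE]
    rowSums(in_prob(m)) >= 1
  }, logical(nrow(mat$sites)))
  prob_per_lin <- matrix(prob_per_lin, nrow = nrow(mat$sites))
  probabilistic <- rowMeans(prob_per_lin) == 1
  out <- rep("other", nrow(mat$sites))
  out[probabilistic] <- "probabilistic"
  out[faithful] <- "faithful"
  factor(out, levels = c("probabilistic", "faithful", "other"))
}

.lineage_state <- function(med) if (med < 10) "U" else if (med > 90) "M" else "I"

#' Cluster CpGs by methylation and merge clusters into groups
#'
#' Runs standard k-means (Euclidean distance on the per-sample methylation
#' percentages, fixed seed, `nstart` restarts), relabels clusters by
#' ascending median methylation, then merges clusters into groups. With
#' `scheme = "lineage"` the per-lineage cluster median gives a state (U if
#' < 10, M if > 90, else I) and the concatenated states give groups U, UI,
#' I, MI, M. With `scheme = "overall"` (the paired knockout design) the
#' overall cluster median gives U, I or M directly.
#'
#' @param mat A `cpg_matrix` with at least `k` sites.
#' @param k Number of clusters (7 for the five-group scheme, 5 for the
#'   three-group scheme in the original design).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Number of k-means restarts (default 10).
#' @param scheme `"lineage"` or `"overall"` (see above).
#' @return List with `cluster` (integer per site, ordered by median
#'   methylation), `group` (factor per site) and `cluster_median`.
#' @export
cluster_methylation <- function(mat, k, seed = 1, nstart = 10,
                                scheme = c("lineage", "overall")) {
  scheme <- match.arg(scheme)
  if (k > nrow(mat$sites))
    stopf("k = %d exceeds the %d available sites", k, nrow(mat$sites))
  set.seed(seed)
  km <- kmeans(mat$meth, centers = k, nstart = nstart, iter.max = 100)
  med <- vapply(seq_len(k), function(cl)
    median(mat$meth[km$cluster == cl, , drop = FALSE]), numeric(1))
  relabel <- match(km$cluster, order(med))
  med <- sort(med)
  groups <- vapply(seq_len(k), function(cl) {
    rows <- relabel == cl
    if (scheme == "overall")
      return(.lineage_state(median(mat$meth[rows, , drop = FALSE])))
    states <- vapply(unique(mat$samples$lineage), function(lin) {
      colsl <- mat$samples$lineage == lin
      .lineage_state(median(mat$meth[rows, colsl, drop = FALSE]))
    }, character(1))
    u <- unique(states)
    if (length(u) == 1) return(u)
    if (setequal(u, c("U", "I"))) return("UI")
    if (setequal(u, c("M", "I"))) return("MI")
    "UM"  # one lineage hypo-, the other hypermethylated; rare
  }, character(1))
  lv <- intersect(c("U", "UI", "I", "MI", "M", "UM"), groups)
  list(cluster = relabel,
       group = factor(groups[relabel], levels = lv),
       cluster_median = med)
}

#' Call faithful and unfaithful regions from per-CpG fidelity
#'
#' Scans consecutive retained CpGs per chromosome. Faithful regions are
#' maximal runs of CpGs with fidelity exactly 1; unfaithful regions are
#' built greedily: from each candidate start the run is extended to the
#' furthest CpG keeping the running mean fidelity below `unfaithful_max`
#' (longer regions are preferred), then emitted if it holds at least
#' `min_cpgs` CpGs and spans at least `min_span` bp. Regions of the same
#' kind never overlap.
#'
#' @param sites `data.frame` with `chrom`, `pos`, `fidelity`.
#' @param min_cpgs Minimum CpGs per region (default 3).
#' @param min_span Minimum span in bp (default 5).
#' @param unfaithful_max Mean-fidelity threshold for unfaithful regions
#'   (default 0.75; faithful regions require mean exactly 1).
#' @return `data.frame` of regions: `chrom`, `start`, `end`, `kind`,
#'   `n_cpgs`, `mean_fidelity`.
#' @export
call_regions <- function(sites, min_cpgs = 3, min_span = 5,
                         unfaithful_max = 0.75) {
  res <- list()
  emit <- function(chrom, pos, f, i, j, kind) {
    res[[length(res) + 1L]] <<- data.frame(
      chrom = chrom, start = pos[i], end = pos[j] + 1L, kind = kind,
      n_cpgs = j - i + 1L, mean_fidelity = mean(f[i:j]),
      stringsAsFactors = FALSE)
  }
  for (ch in unique(sites$chrom)) {
    sel <- sites[sites$chrom == ch, , drop = FALSE]
    sel <- sel[order(sel$pos), , drop = FALSE]
    pos <- sel$pos; f <- sel$fidelity; n <- nrow(sel)
    # faithful: maximal runs of fidelity == 1
    r <- rle(f == 1)
    endi <- cumsum(r$lengths); starti <- endi - r$lengths + 1L
    for (q in which(r$values)) {
      i <- starti[q]; j <- endi[q]
      if (j - i + 1L >= min_cpgs && pos[j] - pos[i] + 1L >= min_span)
        emit(ch, pos, f, i, j, "faithful")
    }
    # unfaithful: greedy maximal extension on the running mean
    i <- 1L
    while (i <= n) {
      best <- NA_integer_; s <- 0
      for (j in i:n) {
        s <- s + f[j]
        if (s / (j - i + 1L) < unfaithful_max &&
            j - i + 1L >= min_cpgs && pos[j] - pos[i] + 1L >= min_span)
          best <- j
      }
      if (!is.na(best)) {
        emit(ch, pos, f, i, best, "unfaithful")
        i <- best + 1L
      } else i <- i + 1L
    }
  }
  if (length(res) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), kind = character(), n_cpgs = integer(),
                      mean_fidelity = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Assemble the per-CpG fidelity profile
#'
#' Convenience wrapper computing, per retained site: fidelity score,
#' neighbour similarity, CpG density, per-sample state bins, k-means
#' cluster and merged group, and inheritance class.
#'
#' @param mat A `cpg_matrix`.
#' @param k Number of k-means clusters (default 7).
#' @param seed Seed for the clustering restarts.
#' @return `data.frame` with one row per site.
#' @export
fidelity_profile <- function(mat, k = 7, seed = 1) {
  cl <- cluster_methylation(mat, k = k, seed = seed)
  data.frame(mat$sites,
             fidelity = fidelity_scores(mat),
             neighbour_similarity = neighbour_similarity(mat),
             cpg_density = cpg_density(mat$sites),
             kmeans_cluster = cl$cluster,
             group = cl$group,
             inheritance_class = classify_inheritance(mat),
             stringsAsFactors = FALSE)
}
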