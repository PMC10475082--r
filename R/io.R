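# Internal coordinates are 0-based half-open; Bismark coverage I/O converts
# from/to the 1-based inclusive dialect at the boundary. A CpG site is keyed
# by the 0-based position of the C on the forward strand.

#' Construct a per-sample methylation call table
#'
#' @param sample_id Sample identifier.
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based C positions.
#' @param n_meth,n_unmeth Non-negative integer call counts. Records with
#'   `n_meth + n_unmeth == 0` are dropped.
#' @return A `data.frame` of class `methylation_table` with columns
#'   `chrom`, `pos`, `n_meth`, `n_unmeth` and a `sample_id` attribute.
#'   Methylation percentage is always recomputed as
#'   `100 * n_meth / (n_meth + n_unmeth)`.
#' @export
methylation_table <- function(sample_id, chrom, pos, n_meth, n_unmeth) {
  if (any(n_meth < 0) || any(n_unmeth < 0))
    stopf("call counts must be non-negative")
  keep <- (n_meth + n_unmeth) >= 1L
  out <- data.frame(
    chrom = as.character(chrom)[keep],
    pos = as.integer(pos)[keep],
    n_meth = as.integer(n_meth)[keep],
    n_unmeth = as.integer(n_unmeth)[keep],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(site_key(out$chrom, out$pos)))
    stopf("duplicate (chromosome, position) records in sample '%s'", sample_id)
  attr(out, "sample_id") <- as.character(sample_id)
  class(out) <- c("methylation_table", "data.frame")
  out
}

#' Read a Bismark coverage file
#'
#' Parses the 6-column tab-separated coverage format emitted by
#' `bismark_methylation_extractor` (chrom, start, end, \%meth,
#' count-methylated, count-unmethylated; 1-based inclusive coordinates).
#' The percentage column is ignored and recomputed from the counts;
#' zero-coverage records are dropped.
#'
#' @param path Path to the coverage file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   its extensions.
#' @return A [methylation_table()].
#' @export
read_bismark_cov <- function(path, sample_id = sub("\\..*$", "", basename(path))) {
  nf <- count.fields(path, sep = "\t", quote = "")
  bad <- which(nf != 6L)
  if (length(bad))
    stopf("malformed coverage line %d in '%s': expected 6 tab-separated fields, found %d",
          bad[1], path, nf[bad[1]])
  raw <- read.table(path, sep = "\t", quote = "", colClasses = "character",
                    stringsAsFactors = FALSE)
  for (j in c(2L, 5L, 6L)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    if (anyNA(v))
      stopf("malformed coverage line %d in '%s': non-numeric value '%s'",
            which(is.na(v))[1], path, raw[[j]][which(is.na(v))[1]])
    raw[[j]] <- v
  }
  methylation_table(sample_id,
                    chrom = raw[[1]],
                    pos = as.integer(raw[[2]]) - 1L,
                    n_meth = raw[[5]],
                    n_unmeth = raw[[6]])
}

#' Write a methylation table as a Bismark coverage file
#'
#' Round-trips losslessly through [read_bismark_cov()] on
#' (chromosome, position, n_meth, n_unmeth).
#'
#' @param x A [methylation_table()].
#' @param path Output path.
#' @export
write_cov <- function(x, path) {
  total <- x$n_meth + x$n_unmeth
  out <- data.frame(x$chrom, x$pos + 1L, x$pos + 1L,
                    format(100 * x$n_meth / total, trim = TRUE),
                    x$n_meth, x$n_unmeth)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-CpG score track as bedGraph
#'
#' Output intervals are 0-based half-open, one per site. Score values are
#' serialized with 4 decimal places.
#'
#' @param sites `data.frame` with columns `chrom`, `pos` (0-based).
#' @param values Numeric score per site (e.g. a fidelity track in [0, 1]).
#' @param path Output path.
#' @param track_name Optional bedGraph track name line.
#' @export
write_bedgraph <- function(sites, values, path, track_name = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  writeLines(sprintf("%s\t%d\t%d\t%.4f", sites$chrom, sites$pos,
                     sites$pos + 1L, values), con)
  invisible(path)
}

#' Combine top- and bottom-strand methylation calls at CpG sites
#'
#' Bisulfite callers report bottom-strand (G-position) calls one base past
#' the forward-strand C. Calls at position p (top) and p + 1 (bottom) are
#' summed into a single record keyed at the C position p. Bottom-strand
#' records with no pairable C are kept unmerged and flagged.
#'
#' @param top,bottom [methylation_table()] objects for the two strands.
#' @param cpg_positions `data.frame` with columns `chrom`, `pos` giving the
#'   forward-strand C positions of known CpG sites.
#' @return A [methylation_table()] with an extra `flag` column, `"ok"` for
#'   merged/top-only records and `"unpaired_bottom"` for orphans.
#' @export
merge_strands <- function(top, bottom, cpg_positions) {
  c_keys <- site_key(cpg_positions$chrom, cpg_positions$pos)
  bot_c_pos <- bottom$pos - 1L
  pairable <- site_key(bottom$chrom, bot_c_pos) %in% c_keys
  merged <- data.frame(
    chrom = c(top$chrom, bottom$chrom[pairable]),
    pos = c(top$pos, bot_c_pos[pairable]),
    n_meth = c(top$n_meth, bottom$n_meth[pairable]),
    n_unmeth = c(top$n_unmeth, bottom$n_unmeth[pairable]),
    stringsAsFactors = FALSE
  )
  key <- site_key(merged$chrom, merged$pos)
  agg_m <- rowsum(merged$n_meth, key)
  agg_u <- rowsum(merged$n_unmeth, key, reorder = TRUE)
  first <- !duplicated(key)
  ord <- match(rownames(agg_m), key[first])
  res <- data.frame(
    chrom = merged$chrom[first][ord],
    pos = merged$pos[first][ord],
    n_meth = as.integer(agg_m[, 1]),
    n_unmeth = as.integer(agg_u[, 1]),
    flag = "ok",
    stringsAsFactors = FALSE
  )
  if (any(!pairable)) {
    res <- rbind(res, data.frame(
      chrom = bottom$chrom[!pairable], pos = bottom$pos[!pairable],
      n_meth = bottom$n_meth[!pairable], n_unmeth = bottom$n_unmeth[!pairable],
      flag = "unpaired_bottom", stringsAsFactors = FALSE))
  }
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "sample_id") <- attr(top, "sample_id")
  class(res) <- c("methylation_table", "data.frame")
  res
}

#' Describe the samples of a clonal-expansion design
#'
#' @param sample_id Character vector of sample identifiers.
#' @param role `"parental"` or `"clonal"` per sample.
#' @param lineage Parental lineage each sample belongs to.
#' @param condition `"none"`, `"control"` or `"knockout"`.
#' @return A validated `data.frame` of class `sample_info`.
#' @export
sample_info <- function(sample_id, role, lineage, condition = "none") {
  role <- match.arg(role, c("parental", "clonal"), several.ok = TRUE)
  out <- data.frame(sample_id = as.character(sample_id), role = role,
                    lineage = as.character(lineage),
                    condition = rep_len(condition, length(sample_id)),
                    stringsAsFactors = FALSE)
  if (!all(out$condition %in% c("none", "control", "knockout")))
    stopf("condition must be one of none/control/knockout")
  if (anyDuplicated(out$sample_id)) stopf("duplicate sample ids")
  class(out) <- c("sample_info", "data.frame")
  out
}

#' Read a sample sheet TSV
#'
#' Expected columns: `sample_id`, `role`, `lineage`, `condition` and
#' optionally `path` (to the sample's coverage file).
#' @param path Path to the TSV.
#' @return A [sample_info()] `data.frame` (with a `path` column if present).
#' @export
read_sample_sheet <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  out <- sample_info(d$sample_id, d$role, d$lineage,
                     if ("condition" %in% names(d)) d$condition else "none")
  if ("path" %in% names(d)) out$path <- d$path
  out
}

#' Assemble the filtered cross-sample CpG matrix
#'
#' Retains the sites that reach `min_coverage` in every sample, excluding
#' listed chromosomes (aneuploid chromosomes and the X in the original
#' design; the aneuploidy call is made by the user from
#' [coverage_karyotype()], not automated). Methylation percentages are
#' recomputed from counts.
#'
#' @param tables List of [methylation_table()] objects, one per sample; the
#'   list names (or the tables' `sample_id` attributes) must match
#'   `samples$sample_id`.
#' @param samples A [sample_info()] `data.frame`.
#' @param min_coverage Minimum call count required in all samples (default 10).
#' @param excluded_chromosomes Chromosomes removed before filtering.
#' @return A `cpg_matrix`: list with `sites` (`chrom`, `pos`, ordered),
#'   `meth` and `cov` (site x sample matrices) and `samples`.
#' @export
build_cpg_matrix <- function(tables, samples, min_coverage = 10,
                             excluded_chromosomes = character()) {
  ids <- names(tables)
  if (is.null(ids)) ids <- vapply(tables, attr, "", "sample_id")
  if (!setequal(ids, samples$sample_id))
    stopf("table names and sample sheet ids do not match")
  tables <- tables[match(samples$sample_id, ids)]
  keys <- lapply(tables, function(t) {
    keep <- !(t$chrom %in% excluded_chromosomes) &
      (t$n_meth + t$n_unmeth) >= min_coverage
    site_key(t$chrom[keep], t$pos[keep])
  })
  common <- Reduce(intersect, keys)
  if (length(common) == 0)
    stopf("no sites retained: no CpG reaches %dx coverage in all %d samples",
          min_coverage, length(tables))
  t1 <- tables[[1]]
  m1 <- match(common, site_key(t1$chrom, t1$pos))
  sites <- data.frame(chrom = t1$chrom[m1], pos = t1$pos[m1],
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  skey <- site_key(sites$chrom, sites$pos)
  cov <- meth <- matrix(NA_real_, nrow(sites), length(tables),
                        dimnames = list(NULL, samples$sample_id))
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    m <- match(skey, site_key(t$chrom, t$pos))
    tot <- t$n_meth[m] + t$n_unmeth[m]
    cov[, j] <- tot
    meth[, j] <- 100 * t$n_meth[m] / tot
  }
  structure(list(sites = sites, meth = meth, cov = cov, samples = samples),
            class = "cpg_matrix")
}

#' @export
print.cpg_matrix <- function(x, ...) {
  cat(sprintf("CpG matrix: %d sites x %d samples (%d parental, %d clonal)\n",
              nrow(x$sites), nrow(x$samples),
              sum(x$samples$role == "parental"),
              sum(x$samples$role == "clonal")))
  invisible(x)
}

#' Clonal sample columns of a CpG matrix
#' @param mat A `cpg_matrix`.
#' @param lineage Optional lineage to restrict to.
#' @keywords internal
clonal_columns <- function(mat, lineage = NULL) {
  sel <- mat$samples$role == "clonal"
  if (!is.null(lineage)) sel <- sel & mat$samples$lineage == lineage
  which(sel)
}

#' Recover per-sample call-count matrices from a CpG matrix
#'
#' Inverts the percentage computation exactly: `n_meth` is
#' `meth * cov / 100` rounded to the nearest integer.
#'
#' @param mat A `cpg_matrix`.
#' @return List with matrices `meth` and `unmeth` of call counts.
#' @export
call_counts <- function(mat) {
  n_meth <- round(mat$meth * mat$cov / 100)
  list(meth = n_meth, unmeth = mat$cov - n_meth)
}

#' Construct a bisulfite read record
#'
#' @param chromosome Chromosome name.
#' @param mapq Mapping quality.
#' @param positions Strictly increasing CpG positions covered by the read.
#' @param calls Logical vector, `TRUE` for a methylated call.
#' @export
read_record <- function(chromosome, mapq, positions, calls) {
  if (is.unsorted(positions, strictly = TRUE))
    stopf("CpG positions within a read must be strictly increasing")
  if (length(positions) != length(calls))
    stopf("positions and calls must have equal length")
  structure(list(chromosome = chromosome, mapq = as.integer(mapq),
                 positions = as.integer(positions), calls = as.logical(calls)),
            class = "read_record")
}

#' Filter reads and order them by average methylation
#'
#' Drops reads with MAPQ below `min_mapq` or covering fewer than `min_cpgs`
#' CpGs, then sorts the survivors by ascending mean methylation. The sort is
#' stable: ties keep input order.
#'
#' @param reads List of [read_record()] objects.
#' @param min_mapq Minimum mapping quality (default 10).
#' @param min_cpgs Minimum number of covered CpGs (default 3).
#' @return The filtered, ordered list.
#' @export
filter_reads <- function(reads, min_mapq = 10, min_cpgs = 3) {
  keep <- vapply(reads, function(r)
    r$mapq >= min_mapq && length(r$positions) >= min_cpgs, logical(1))
  reads <- reads[keep]
  mm <- vapply(reads, function(r) mean(r$calls), numeric(1))
  reads[order(mm)]
}

#' Retain CpG sites with enough methylation calls across pooled reads
#'
#' Reads are pooled across the samples of one cell line; positions covered
#' by fewer than `min_calls` total calls are excluded.
#'
#' @param reads List of [read_record()] objects (already pooled).
#' @param min_calls Minimum total call count (default 10).
#' @return `data.frame` with columns `chrom`, `pos` of retained sites.
#' @export
site_call_filter <- function(reads, min_calls = 10) {
  if (length(reads) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  chrom <- unlist(lapply(reads, function(r)
    rep(r$chromosome, length(r$positions))))
  pos <- unlist(lapply(reads, function(r) r$positions))
  key <- site_key(chrom, pos)
  counts <- table(key)
  keep <- names(counts)[counts >= min_calls]
  i <- match(keep, key)
  out <- data.frame(chrom = chrom[i], pos = pos[i], stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Coverage-based karyotype profile
#'
#' Per chromosome, takes the mean or median of per-site coverage pooled over
#' the supplied tables, normalises by the sum across chromosomes and reports
#' the negative log2. Lower values mean higher relative coverage; chromosome
#' gains therefore dip below the diploid baseline.
#'
#' @param tables List of [methylation_table()] objects.
#' @param statistic `"mean"` or `"median"`.
#' @param chromosomes Optional chromosome universe; members with no sites
#'   are omitted with a warning.
#' @return `data.frame` with columns `chrom`, `coverage`, `neg_log2`.
#' @export
coverage_karyotype <- function(tables, statistic = c("mean", "median"),
                               chromosomes = NULL) {
  statistic <- match.arg(statistic)
  chrom <- unlist(lapply(tables, `[[`, "chrom"))
  covv <- unlist(lapply(tables, function(t) t$n_meth + t$n_unmeth))
  if (length(chrom) == 0) stopf("no sites in input tables")
  fun <- if (statistic == "mean") mean else median
  stat <- tapply(covv, chrom, fun)
  if (!is.null(chromosomes)) {
    missing <- setdiff(chromosomes, names(stat))
    if (length(missing))
      warnf("chromosome(s) with no sites omitted: %s",
            paste(missing, collapse = ", "))
  }
  norm <- stat / sum(stat)
  data.frame(chrom = names(stat), coverage = as.numeric(stat),
             neg_log2 = -log2(as.numeric(norm)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a sample sheet TSV
#' @param samples A [sample_info()] `data.frame` (optionally with `path`).
#' @param path Output path.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
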