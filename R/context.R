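# Relating methylation and fidelity to genomic context: canonical
# transcripts, expression quintiles, genic-region tiling, feature
# assignment, transposable-element summaries and peak fold enrichment.
# Interval overlap goes through GenomicRanges; internal coordinates are
# 0-based half-open.

.gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

.gr_points <- function(sites) .gr(sites$chrom, sites$pos, sites$pos + 1L)

# overlap helpers tolerant of disjoint chromosome sets
.harmonize <- function(query, subject) {
  lv <- union(GenomeInfoDb::seqlevels(query),
              GenomeInfoDb::seqlevels(subject))
  GenomeInfoDb::seqlevels(query) <- lv
  GenomeInfoDb::seqlevels(subject) <- lv
  list(query, subject)
}

.find_overlaps <- function(query, subject) {
  h <- .harmonize(query, subject)
  GenomicRanges::findOverlaps(h[[1]], h[[2]])
}

.overlaps_any <- function(query, subject) {
  h <- .harmonize(query, subject)
  IRanges::overlapsAny(h[[1]], h[[2]])
}

#' Select one canonical transcript per gene
#'
#' The canonical transcript is the most highly expressed transcript of the
#' gene on average; exact ties go to the longest transcript, then to the
#' lexicographically smallest id. Genes whose transcripts all have zero
#' expression fall back to a supplied canonical list; genes with no
#' transcripts are skipped with a warning.
#'
#' @param transcripts `data.frame` with `gene_id`, `transcript_id`,
#'   `length`.
#' @param expression `data.frame` with `transcript_id`, `mean_expr`.
#' @param fallback Named character vector `gene_id -> transcript_id` used
#'   for all-zero genes.
#' @return `data.frame` with `gene_id`, `transcript_id`.
#' @export
select_canonical <- function(transcripts, expression,
                             fallback = character(0)) {
  e <- expression$mean_expr[match(transcripts$transcript_id,
                                  expression$transcript_id)]
  e[is.na(e)] <- 0
  transcripts$.expr <- e
  picks <- lapply(split(transcripts, transcripts$gene_id), function(tt) {
    if (nrow(tt) == 0) return(NULL)
    if (all(tt$.expr == 0) && tt$gene_id[1] %in% names(fallback))
      return(data.frame(gene_id = tt$gene_id[1],
                        transcript_id = unname(fallback[tt$gene_id[1]]),
                        stringsAsFactors = FALSE))
    o <- order(-tt$.expr, -tt$length, tt$transcript_id)
    data.frame(gene_id = tt$gene_id[1], transcript_id = tt$transcript_id[o[1]],
               stringsAsFactors = FALSE)
  })
  no_tx <- setdiff(unique(transcripts$gene_id),
                   vapply(Filter(Negate(is.null), picks), `[[`, "", "gene_id"))
  if (length(no_tx))
    warnf("gene(s) with no transcripts skipped: %s",
          paste(no_tx, collapse = ", "))
  out <- do.call(rbind, Filter(Negate(is.null), picks))
  rownames(out) <- NULL
  out
}

.quintile_levels <- c("none", "low", "mid_low", "mid_high", "high")

#' Assign genes to expression groups
#'
#' Genes with exactly zero normalized expression form the "none" group; the
#' remaining genes are split by rank into four near-equal groups (low,
#' mid_low, mid_high, high). Rank ties keep input order; when the nonzero
#' count is not divisible by 4, the remainder is given to the outermost
#' groups first, so the tails stay slightly larger. The grouping is
#' invariant under monotone relabeling of the expression values.
#'
#' @param expression Numeric vector of per-gene mean normalized expression
#'   (names preserved).
#' @return Factor with levels none/low/mid_low/mid_high/high.
#' @export
expression_groups <- function(expression) {
  if (any(expression < 0)) stopf("expression must be non-negative")
  grp <- rep("none", length(expression))
  nz <- which(expression > 0)
  n <- length(nz)
  if (n > 0) {
    sizes <- rep(n %/% 4L, 4L)
    rem <- n %% 4L
    extra_order <- c(1L, 4L, 2L, 3L)
    if (rem > 0) sizes[extra_order[seq_len(rem)]] <-
        sizes[extra_order[seq_len(rem)]] + 1L
    r <- rank(expression[nz], ties.method = "first")
    g4 <- findInterval(r, cumsum(sizes)[-4L] + 0.5) + 1L
    grp[nz] <- c("low", "mid_low", "mid_high", "high")[g4]
  }
  out <- factor(grp, levels = .quintile_levels)
  names(out) <- names(expression)
  out
}

.exons_of <- function(exons, transcript_id) {
  e <- exons[exons$transcript_id == transcript_id, , drop = FALSE]
  e[order(e$exon_rank), , drop = FALSE]
}

#' Promoter interval of a gene model
#'
#' 1000 bp immediately 5' of the first exon, respecting strand.
#' @param exons Exon table of one transcript (transcription order).
#' @param width Promoter width in bp (default 1000).
#' @return `data.frame` with `chrom`, `start`, `end`.
#' @keywords internal
promoter_interval <- function(exons, width = 1000L) {
  first <- exons[exons$exon_rank == 1L, ]
  if (first$strand == "+")
    data.frame(chrom = first$chrom, start = first$start - width,
               end = first$start, stringsAsFactors = FALSE)
  else
    data.frame(chrom = first$chrom, start = first$end,
               end = first$end + width, stringsAsFactors = FALSE)
}

# tile boundaries: total length L split into n near-equal tiles, remainder
# to the 5'-most tiles
.tile_sizes <- function(L, n = 5L) {
  sz <- rep(L %/% n, n)
  rem <- L %% n
  if (rem > 0) sz[seq_len(rem)] <- sz[seq_len(rem)] + 1L
  sz
}

#' Partition a gene model into tiled genic regions
#'
#' Regions are promoter, first exon, first intron, rest of exons and rest
#' of introns ("rest" regions pool the remaining exons/introns in their
#' concatenated transcription-order coordinate space, so introns do not
#' dilute exon tiles). Each region longer than `min_bp` is divided into
#' `n_tiles` near-equal tiles ordered 5' to 3', with the length remainder
#' given to the 5'-most tiles.
#'
#' @param exons Exon table of one transcript (columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `start`, `end`, `exon_rank`).
#' @param n_tiles Tiles per region (default 5).
#' @param min_bp Regions of this length or shorter are dropped (default 6).
#' @return List of class `genic_partition`: per region, the genomic
#'   `intervals` (5' to 3' order), total `length` and tile boundaries.
#' @export
partition_gene <- function(exons, n_tiles = 5L, min_bp = 6L) {
  exons <- exons[order(exons$exon_rank), , drop = FALSE]
  if (nrow(exons) < 2) stopf("single-exon genes are excluded")
  strand <- exons$strand[1]; chrom <- exons$chrom[1]
  ivl <- function(start, end) data.frame(chrom = chrom, start = start,
                                         end = end, stringsAsFactors = FALSE)
  # introns in transcription order
  introns <- list()
  for (i in seq_len(nrow(exons) - 1L)) {
    a <- exons[i, ]; b <- exons[i + 1L, ]
    introns[[i]] <- if (strand == "+") ivl(a$end, b$start)
    else ivl(b$end, a$start)
  }
  regions <- list(
    promoter = list(promoter_interval(exons)),
    first_exon = list(ivl(exons$start[1], exons$end[1])),
    first_intron = introns[1],
    rest_exons = lapply(seq.int(2L, nrow(exons)), function(i)
      ivl(exons$start[i], exons$end[i])),
    rest_introns = if (length(introns) > 1) introns[-1] else list()
  )
  out <- list()
  for (rn in names(regions)) {
    iv <- regions[[rn]]
    if (length(iv) == 0) next
    iv <- do.call(rbind, iv)
    L <- sum(iv$end - iv$start)
    if (L <= min_bp) next
    out[[rn]] <- list(intervals = iv, length = L,
                      tile_sizes = .tile_sizes(L, n_tiles))
  }
  structure(list(gene_id = exons$gene_id[1],
                 transcript_id = exons$transcript_id[1],
                 chrom = chrom, strand = strand, regions = out),
            class = "genic_partition")
}

# map positions to (in-region concatenated offset, tile index); NA outside
.region_tile <- function(part, region, pos) {
  rg <- part$regions[[region]]
  if (is.null(rg)) return(rep(NA_integer_, length(pos)))
  off <- rep(NA_real_, length(pos))
  cum <- 0
  for (i in seq_len(nrow(rg$intervals))) {
    s <- rg$intervals$start[i]; e <- rg$intervals$end[i]
    inside <- pos >= s & pos < e
    local <- if (part$strand == "+") pos - s else (e - 1L) - pos
    off[inside] <- cum + local[inside]
    cum <- cum + (e - s)
  }
  bounds <- cumsum(rg$tile_sizes)
  findInterval(off, c(0, bounds[-length(bounds)]), left.open = FALSE)
}

#' Median and IQR of methylation and fidelity along tiled genic regions
#'
#' CpGs are assigned to region tiles through each gene's partition; per
#' (region, tile, expression group), the median and interquartile range of
#' per-CpG methylation (mean across samples) and fidelity are computed over
#' CpGs pooled across the group's genes. Regions covered by fewer than
#' `min_cpgs` CpGs in a gene are dropped for that gene; empty tiles yield
#' missing values, not zeros.
#'
#' @param mat A `cpg_matrix`.
#' @param fidelity Per-site fidelity scores (matching `mat$sites`).
#' @param partitions List of `genic_partition` objects.
#' @param quintiles Named factor (gene_id -> expression group).
#' @param min_cpgs Minimum CpGs per considered region (default 3).
#' @return `data.frame`: `region`, `tile`, `quintile`, `n_cpgs`,
#'   `meth_median`, `meth_iqr`, `fidelity_median`, `fidelity_iqr`.
#' @export
profile_by_tile <- function(mat, fidelity, partitions, quintiles,
                            min_cpgs = 3L) {
  site_meth <- rowMeans(mat$meth)
  acc <- list()
  for (part in partitions) {
    q <- as.character(quintiles[part$gene_id])
    if (length(q) != 1 || is.na(q)) next
    on_chrom <- which(mat$sites$chrom == part$chrom)
    for (rn in names(part$regions)) {
      tl <- .region_tile(part, rn, mat$sites$pos[on_chrom])
      hit <- which(!is.na(tl))
      if (length(hit) < min_cpgs) next
      acc[[length(acc) + 1L]] <- data.frame(
        region = rn, tile = tl[hit], quintile = q,
        meth = site_meth[on_chrom[hit]], fid = fidelity[on_chrom[hit]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(acc) == 0)
    return(data.frame(region = character(), tile = integer(),
                      quintile = character(), n_cpgs = integer(),
                      meth_median = numeric(), meth_iqr = numeric(),
                      fidelity_median = numeric(), fidelity_iqr = numeric()))
  long <- do.call(rbind, acc)
  sp <- split(long, list(long$region, long$tile, long$quintile), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    region = d$region[1], tile = d$tile[1], quintile = d$quintile[1],
    n_cpgs = nrow(d),
    meth_median = median(d$meth), meth_iqr = IQR(d$meth),
    fidelity_median = median(d$fid), fidelity_iqr = IQR(d$fid),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$region, out$quintile, out$tile), , drop = FALSE]
}

#' Assign each CpG a genic feature label
#'
#' Overlap with any promoter assigns "promoter"; otherwise exons, then
#' introns (first vs rest distinguished); CpGs overlapping neither a
#' transcript nor a promoter are intergenic. When models overlap, the
#' precedence is promoter > exon > intron, with "first" ranked before
#' "rest". The host gene's expression group is carried along.
#'
#' @param sites `data.frame` with `chrom`, `pos`.
#' @param exons Gene model exon table (canonical transcripts).
#' @param quintiles Named factor (gene_id -> expression group); optional.
#' @return `data.frame` with `feature` and `quintile` per site.
#' @export
assign_genic_context <- function(sites, exons, quintiles = NULL) {
  pts <- .gr_points(sites)
  n <- nrow(sites)
  feature <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  claim <- function(feature_name, chrom, start, end, gene_ids, current) {
    if (length(start) == 0) return(current)
    hits <- .find_overlaps(pts, .gr(chrom, start, end))
    i <- S4Vectors::queryHits(hits)
    take <- i[current[i]]
    feature[take] <<- feature_name
    gene[take] <<- gene_ids[S4Vectors::subjectHits(hits)][current[i]]
    current[unique(i)] <- FALSE
    current
  }
  open <- rep(TRUE, n)
  # promoters
  first_ex <- exons[exons$exon_rank == 1L, , drop = FALSE]
  prom <- do.call(rbind, lapply(seq_len(nrow(first_ex)), function(i)
    promoter_interval(first_ex[i, ])))
  open <- claim("promoter", prom$chrom, prom$start, prom$end,
                first_ex$gene_id, open)
  # exons: first, then rest
  open <- claim("first_exon", first_ex$chrom, first_ex$start, first_ex$end,
                first_ex$gene_id, open)
  rest_ex <- exons[exons$exon_rank > 1L, , drop = FALSE]
  open <- claim("rest_exon", rest_ex$chrom, rest_ex$start, rest_ex$end,
                rest_ex$gene_id, open)
  # introns from consecutive exon ranks
  intr <- list()
  for (tid in unique(exons$transcript_id)) {
    e <- .exons_of(exons, tid)
    if (nrow(e) < 2) next
    for (i in seq_len(nrow(e) - 1L)) {
      s <- min(e$end[i], e$end[i + 1L]); en <- max(e$start[i], e$start[i + 1L])
      if (e$strand[1] == "+") { s <- e$end[i]; en <- e$start[i + 1L] }
      else { s <- e$end[i + 1L]; en <- e$start[i] }
      intr[[length(intr) + 1L]] <- data.frame(
        chrom = e$chrom[1], start = s, end = en, gene_id = e$gene_id[1],
        first = i == 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(intr)) {
    intr <- do.call(rbind, intr)
    fi <- intr[intr$first, , drop = FALSE]
    ri <- intr[!intr$first, , drop = FALSE]
    open <- claim("first_intron", fi$chrom, fi$start, fi$end, fi$gene_id,
                  open)
    open <- claim("rest_intron", ri$chrom, ri$start, ri$end, ri$gene_id,
                  open)
  }
  quint <- rep(NA_character_, n)
  if (!is.null(quintiles)) {
    hit <- !is.na(gene)
    quint[hit] <- as.character(quintiles[gene[hit]])
  }
  data.frame(feature = factor(feature, levels = c(
    "promoter", "first_exon", "rest_exon", "first_intron", "rest_intron",
    "intergenic")), gene_id = gene, quintile = quint,
    stringsAsFactors = FALSE)
}

#' Summarise methylation and fidelity per transposable element
#'
#' Per TE with at least one covered CpG: mean methylation over all
#' CpG-by-sample cells, mean fidelity over CpGs, and a location class
#' resolved with precedence promoter > intronic > intergenic (a TE
#' overlapping a promoter is "promoter"; otherwise one overlapping any
#' transcript is "intronic"). TEs with no covered CpGs are omitted.
#'
#' @param mat A `cpg_matrix`.
#' @param fidelity Per-site fidelity scores.
#' @param tes TE record `data.frame` (see [read_repeatmasker_out()]).
#' @param exons Gene model exon table.
#' @return `data.frame` of TE summaries.
#' @export
te_summary <- function(mat, fidelity, tes, exons) {
  pts <- .gr_points(mat$sites)
  te_gr <- .gr(tes$chrom, tes$start, tes$end)
  hits <- .find_overlaps(te_gr, pts)
  sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  # location class
  first_ex <- exons[exons$exon_rank == 1L, , drop = FALSE]
  prom <- do.call(rbind, lapply(seq_len(nrow(first_ex)), function(i)
    promoter_interval(first_ex[i, ])))
  tx_span <- do.call(rbind, lapply(split(exons, exons$transcript_id),
                                   function(e) data.frame(
                                     chrom = e$chrom[1], start = min(e$start),
                                     end = max(e$end),
                                     stringsAsFactors = FALSE)))
  in_prom <- .overlaps_any(te_gr, .gr(prom$chrom, prom$start, prom$end))
  in_tx <- .overlaps_any(te_gr, .gr(tx_span$chrom, tx_span$start, tx_span$end))
  loc <- ifelse(in_prom, "promoter", ifelse(in_tx, "intronic", "intergenic"))
  rows <- lapply(names(sp), function(q) {
    i <- as.integer(q); s <- sp[[q]]
    data.frame(te_id = tes$te_id[i], class = tes$class[i],
               chrom = tes$chrom[i], start = tes$start[i], end = tes$end[i],
               divergence = tes$divergence[i],
               location_class = loc[i], n_cpgs = length(s),
               mean_meth = mean(mat$meth[s, , drop = FALSE]),
               mean_fidelity = mean(fidelity[s]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank correlation of TE divergence with methylation and fidelity
#'
#' Spearman correlation per TE class of sequence divergence against mean
#' methylation and against mean fidelity. Classes with fewer than 3 TEs are
#' an error; constant inputs yield `NA` coefficients with a flag.
#'
#' @param te_records Output of [te_summary()].
#' @return `data.frame`: per class and response, `rho`, `p`, `n`,
#'   `constant_input`.
#' @export
divergence_association <- function(te_records) {
  out <- list()
  for (cls in unique(te_records$class)) {
    d <- te_records[te_records$class == cls, , drop = FALSE]
    if (nrow(d) < 3)
      stopf("class '%s' has %d TEs; at least 3 required", cls, nrow(d))
    for (resp in c("mean_meth", "mean_fidelity")) {
      y <- d[[resp]]
      if (sd(d$divergence) == 0 || sd(y) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          class = cls, response = resp, rho = NA_real_, p = NA_real_,
          n = nrow(d), constant_input = TRUE, stringsAsFactors = FALSE)
      } else {
        ct <- suppressWarnings(cor.test(d$divergence, y,
                                        method = "spearman"))
        out[[length(out) + 1L]] <- data.frame(
          class = cls, response = resp, rho = unname(ct$estimate),
          p = ct$p.value, n = nrow(d), constant_input = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Mean methylation by SINE consensus position
#'
#' Each CpG inside a SINE is mapped to its position on the element's
#' consensus sequence (counted from the element's 5' end, so minus-strand
#' copies are flipped); per-position mean methylation is averaged over all
#' copies. Positions beyond `max_position` are ignored.
#'
#' @param mat A `cpg_matrix`.
#' @param sines TE records restricted to SINEs, with `consensus_begin` and
#'   `strand`.
#' @param max_position Last consensus position kept (default 200).
#' @return `data.frame` with `position`, `mean_meth`, `n_cpgs`.
#' @export
sine_position_profile <- function(mat, sines, max_position = 200L) {
  site_meth <- rowMeans(mat$meth)
  pos_all <- integer(0); meth_all <- numeric(0)
  for (i in seq_len(nrow(sines))) {
    s <- sines[i, ]
    inside <- which(mat$sites$chrom == s$chrom & mat$sites$pos >= s$start &
                      mat$sites$pos < s$end)
    if (length(inside) == 0) next
    p <- mat$sites$pos[inside]
    cons <- if (s$strand == "+") s$consensus_begin + (p - s$start)
    else s$consensus_begin + (s$end - 1L - p)
    keep <- cons >= 1L & cons <= max_position
    pos_all <- c(pos_all, cons[keep])
    meth_all <- c(meth_all, site_meth[inside][keep])
  }
  if (length(pos_all) == 0)
    return(data.frame(position = integer(), mean_meth = numeric(),
                      n_cpgs = integer()))
  agg <- tapply(meth_all, pos_all, mean)
  data.frame(position = as.integer(names(agg)),
             mean_meth = as.numeric(agg),
             n_cpgs = as.integer(table(pos_all)),
             row.names = NULL)
}

#' Fold enrichment of foreground CpGs in peak intervals
#'
#' Ratio of the fraction of foreground sites overlapping any peak to the
#' fraction of background sites doing so. Duplicated peaks do not change
#' the result. A zero background overlap fraction is undefined and yields
#' `NA` with a warning.
#'
#' @param foreground,background Site `data.frame`s (`chrom`, `pos`);
#'   foreground should be a subset of background.
#' @param peaks Interval `data.frame` (`chrom`, `start`, `end`).
#' @return Single non-negative number (or `NA`).
#' @export
fold_enrichment <- function(foreground, background, peaks) {
  if (nrow(background) == 0) stopf("background must be non-empty")
  if (nrow(peaks) == 0) {
    warnf("empty peak set: fold enrichment undefined")
    return(NA_real_)
  }
  pk <- .gr(peaks$chrom, peaks$start, peaks$end)
  f_fg <- mean(.overlaps_any(.gr_points(foreground), pk))
  f_bg <- mean(.overlaps_any(.gr_points(background), pk))
  if (f_bg == 0) {
    warnf("background overlap fraction is 0: fold enrichment undefined")
    return(NA_real_)
  }
  f_fg / f_bg
}
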