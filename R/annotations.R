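# Synthetic annotations built around the simulated genome's block structure,
# plus readers/writers for the standard annotation formats (BED12 gene
# models, RepeatMasker .out, peak BED). All internal coordinates are 0-based
# half-open.

.block_extents <- function(genome) {
  sp <- split(seq_len(nrow(genome)), genome$block)
  do.call(rbind, lapply(sp, function(i) data.frame(
    block = genome$block[i[1]], chrom = genome$chrom[i[1]],
    start = min(genome$pos[i]), end = max(genome$pos[i]) + 2L,
    type = genome$block_type[i[1]], stringsAsFactors = FALSE)))
}

#' Generate synthetic annotations matched to a simulated genome
#'
#' Builds multi-exon gene models around the genome's block structure:
#' expressed genes place their promoter over a dense hypomethylated island
#' and their introns/late exons over hypermethylated blocks; silent genes
#' (zero expression) are built over labile blocks. Transposable-element
#' intervals are placed in promoters, introns and intergenic space with
#' divergence drawn independently of methylation (a built-in null), and
#' peak files mark active-promoter-like and repressed-chromatin-like
#' intervals. All genes have at least two exons.
#'
#' @param genome Site table from [make_genome()].
#' @param seed Optional RNG seed.
#' @return List with `exons` (gene model table: `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end`, `exon_rank`), `expression`
#'   (`gene_id`, `expression`), `tes` (TE records with `location_truth`),
#'   and `peaks` (named list of interval `data.frame`s).
#' @export
make_annotations <- function(genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bl <- .block_extents(genome)
  exons <- list(); expr <- list(); tes <- list()
  gene_n <- 0L; te_n <- 0L
  te_classes <- c("SINE", "LINE", "LTR", "DNA")
  add_te <- function(chrom, start, end, location) {
    te_n <<- te_n + 1L
    len <- end - start
    cb <- sample(1:40, 1)
    tes[[te_n]] <<- data.frame(
      te_id = sprintf("TE%03d", te_n),
      class = te_classes[(te_n - 1L) %% 4L + 1L],
      chrom = chrom, start = start, end = end,
      strand = sample(c("+", "-"), 1),
      divergence = round(runif(1, 2, 30), 1),
      consensus_begin = cb, consensus_end = cb + len - 1L,
      location_truth = location, stringsAsFactors = FALSE)
  }
  make_gene <- function(prom_block, body_blocks, expressed) {
    gene_n <<- gene_n + 1L
    gid <- sprintf("G%03d", gene_n)
    tss <- prom_block$end + 21L
    b1 <- body_blocks[1, ]
    ex <- data.frame(start = tss, end = tss + 100L)
    if (nrow(body_blocks) >= 2) {
      b2 <- body_blocks[2, ]
      ex <- rbind(ex, data.frame(start = b1$end + 50L, end = b2$end + 50L))
    } else {
      ex <- rbind(ex, data.frame(start = b1$end + 50L, end = b1$end + 150L))
    }
    exons[[gene_n]] <<- data.frame(
      gene_id = gid, transcript_id = paste0(gid, ".t1"),
      chrom = prom_block$chrom, strand = "+",
      start = ex$start, end = ex$end, exon_rank = seq_len(nrow(ex)),
      stringsAsFactors = FALSE)
    expr[[gene_n]] <<- data.frame(gene_id = gid,
                                  expression = if (expressed)
                                    round(exp(runif(1, 0, 5)), 3) else 0,
                                  stringsAsFactors = FALSE)
    gid
  }
  for (ch in unique(bl$chrom)) {
    cb <- bl[bl$chrom == ch, , drop = FALSE]
    cb <- cb[order(cb$start), , drop = FALSE]
    i <- 1L
    while (i <= nrow(cb)) {
      ty <- cb$type[i]
      if (ty == "hypo_island") {
        j <- i + 1L
        while (j <= nrow(cb) && cb$type[j] == "hyper_block" && j - i <= 2L)
          j <- j + 1L
        body <- cb[seq.int(i + 1L, length.out = j - i - 1L), , drop = FALSE]
        if (nrow(body) >= 1) {
          make_gene(cb[i, ], body, expressed = TRUE)
          if (gene_n %% 3L == 1L)
            add_te(ch, cb$start[i], min(cb$start[i] + 120L, cb$end[i]),
                   "promoter")
          add_te(ch, body$start[1] - 10L, body$end[1] + 10L, "intronic")
        }
        i <- j
      } else if (ty == "labile_block") {
        j <- i + 1L
        while (j <= nrow(cb) && cb$type[j] == "labile_block" && j - i <= 2L)
          j <- j + 1L
        body <- cb[seq.int(i + 1L, length.out = j - i - 1L), , drop = FALSE]
        if (nrow(body) >= 1) make_gene(cb[i, ], body, expressed = FALSE)
        i <- j
      } else {
        if (ty == "labile_singleton" && te_n %% 2L == 0L)
          add_te(ch, cb$start[i] - 75L, cb$end[i] + 75L, "intergenic")
        i <- i + 1L
      }
    }
  }
  peaks <- list(
    H3K4me3 = {
      p <- bl[bl$type == "hypo_island", , drop = FALSE]
      data.frame(chrom = p$chrom, start = pmax(0L, p$start - 200L),
                 end = p$end + 200L, stringsAsFactors = FALSE)
    },
    H3K9me3 = {
      p <- bl[bl$type == "labile_block", , drop = FALSE]
      data.frame(chrom = p$chrom, start = pmax(0L, p$start - 200L),
                 end = p$end + 200L, stringsAsFactors = FALSE)
    }
  )
  list(exons = do.call(rbind, exons), expression = do.call(rbind, expr),
       tes = do.call(rbind, tes), peaks = peaks)
}

# ---- gene model I/O --------------------------------------------------------

#' Write gene models as BED12
#'
#' One line per transcript; the name field is `gene_id|transcript_id`.
#' @param exons Gene model exon table (see [make_annotations()]).
#' @param path Output path.
#' @export
write_gene_models <- function(exons, path) {
  lines <- vapply(split(exons, exons$transcript_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    s <- min(e$start); en <- max(e$end)
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            e$chrom[1], s, en, paste(e$gene_id[1], e$transcript_id[1],
                                     sep = "|"),
            e$strand[1], s, en, nrow(e),
            paste0(e$end - e$start, collapse = ","),
            paste0(e$start - s, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' Exon ranks follow transcription order (reversed block order on the minus
#' strand).
#' @param path Path to a BED12 file whose name field is
#'   `gene_id|transcript_id` (plain names are used for both ids).
#' @return Gene model exon table.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- list()
  for (i in seq_along(gr)) {
    nm <- strsplit(gr$name[i], "|", fixed = TRUE)[[1]]
    gid <- nm[1]; tid <- if (length(nm) > 1) nm[2] else nm[1]
    b <- gr$blocks[[i]]
    st <- as.character(strand(gr[i]))
    if (st == "*") st <- "+"
    tx_start <- start(gr[i]) - 1L          # 0-based transcript start
    starts <- tx_start + start(b) - 1L     # blocks are transcript-relative
    ends <- tx_start + end(b)
    rk <- if (st == "-") rev(seq_along(starts)) else seq_along(starts)
    out[[i]] <- data.frame(gene_id = gid, transcript_id = tid,
                           chrom = as.character(seqnames(gr[i])), strand = st,
                           start = starts, end = ends, exon_rank = rk,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ---- RepeatMasker .out I/O -------------------------------------------------

#' Read a RepeatMasker .out file
#'
#' Parses the standard whitespace-delimited dialect (3 header lines, then
#' score, divergence, deletion, insertion, query chrom/begin/end/(left),
#' strand (`+`/`C`), repeat name, class/family, consensus coordinates).
#' Divergence and consensus alignment positions are taken directly from the
#' file. Genomic coordinates are converted to 0-based half-open.
#'
#' @param path Path to the .out file.
#' @return TE record `data.frame` with columns `te_id`, `class`, `chrom`,
#'   `start`, `end`, `strand`, `divergence`, `consensus_begin`,
#'   `consensus_end`.
#' @export
read_repeatmasker_out <- function(path) {
  d <- read.table(path, skip = 3, fill = TRUE, stringsAsFactors = FALSE)
  strand <- ifelse(d$V9 == "C", "-", "+")
  cls <- sub("/.*$", "", d$V11)
  cons_begin <- as.integer(ifelse(strand == "+", as.character(d$V12),
                                  as.character(d$V14)))
  cons_end <- as.integer(d$V13)
  data.frame(te_id = paste0(d$V10, "#", seq_len(nrow(d))),
             class = cls, chrom = d$V5,
             start = as.integer(d$V6) - 1L, end = as.integer(d$V7),
             strand = strand, divergence = as.numeric(d$V2),
             consensus_begin = cons_begin, consensus_end = cons_end,
             stringsAsFactors = FALSE)
}

#' Write TE records in the RepeatMasker .out dialect
#' @param tes TE record `data.frame` (see [read_repeatmasker_out()]).
#' @param path Output path.
#' @export
write_repeatmasker_out <- function(tes, path) {
  hdr <- c("   SW   perc perc perc  queryaln      position in query     matching repeat",
           "score   div. del. ins.  sequence      begin  end    (left)   repeat        class/family  begin end (left) ID",
           "")
  body <- vapply(seq_len(nrow(tes)), function(i) {
    t <- tes[i, ]
    if (t$strand == "+") {
      sprintf("1000 %s 0.0 0.0 %s %d %d (0) + %s %s %d %d (0) %d",
              format(t$divergence, nsmall = 1), t$chrom, t$start + 1L, t$end,
              sub("#.*$", "", t$te_id), t$class,
              t$consensus_begin, t$consensus_end, i)
    } else {
      sprintf("1000 %s 0.0 0.0 %s %d %d (0) C %s %s (0) %d %d %d",
              format(t$divergence, nsmall = 1), t$chrom, t$start + 1L, t$end,
              sub("#.*$", "", t$te_id), t$class,
              t$consensus_end, t$consensus_begin, i)
    }
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- peak BED I/O ----------------------------------------------------------

#' Write intervals as BED3
#' @param intervals `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  write.table(intervals[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peak intervals from a BED file
#' @param path Path to a BED file.
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
             end = end(gr), stringsAsFactors = FALSE)
}
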