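# hand-built two-exon gene: exon1 [1000,1100), exon2 [1500,1600)
plus_gene <- function() data.frame(
  gene_id = "g1", transcript_id = "g1.t1", chrom = "chr1", strand = "+",
  start = c(1000L, 1500L), end = c(1100L, 1600L), exon_rank = 1:2,
  stringsAsFactors = FALSE)

minus_gene <- function() data.frame(
  gene_id = "g2", transcript_id = "g2.t1", chrom = "chr1", strand = "-",
  start = c(5500L, 5000L), end = c(5600L, 5100L), exon_rank = 1:2,
  stringsAsFactors = FALSE)

single_sample_matrix <- function(chrom, pos, meth) {
  structure(list(
    sites = data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE),
    meth = matrix(meth, length(pos), 1, dimnames = list(NULL, "s")),
    cov = matrix(30, length(pos), 1, dimnames = list(NULL, "s")),
    samples = sample_info("s", "parental", "L1")), class = "cpg_matrix")
}

test_that("canonical transcript selection maximises mean expression with documented tie-breaks", {
  tx <- data.frame(gene_id = c("g1", "g1", "g2", "g2", "g3"),
                   transcript_id = c("t1", "t2", "t3", "t4", "t5"),
                   length = c(500L, 900L, 700L, 700L, 300L),
                   stringsAsFactors = FALSE)
  ex <- data.frame(transcript_id = c("t1", "t2", "t3", "t4", "t5"),
                   mean_expr = c(5, 2, 1, 1, 0))
  sel <- select_canonical(tx, ex, fallback = c(g3 = "t5"))
  expect_equal(sel$transcript_id[sel$gene_id == "g1"], "t1")  # argmax
  expect_equal(sel$transcript_id[sel$gene_id == "g2"], "t3")  # tie: equal length, lexicographic
  expect_equal(sel$transcript_id[sel$gene_id == "g3"], "t5")  # fallback
  # exact tie resolved by longer transcript
  tx2 <- data.frame(gene_id = "g", transcript_id = c("a", "b"),
                    length = c(100L, 200L), stringsAsFactors = FALSE)
  ex2 <- data.frame(transcript_id = c("a", "b"), mean_expr = c(3, 3))
  expect_equal(select_canonical(tx2, ex2)$transcript_id, "b")
})

test_that("expression grouping splits zero from rank-quartiled nonzero genes", {
  expect_true(all(expression_groups(rep(0, 10)) == "none"))
  set.seed(301)
  e <- c(rep(0, 30), runif(70, 0.1, 100))
  g <- expression_groups(e)
  expect_equal(unname(table(g)),
               c(30L, 18L, 17L, 17L, 18L), ignore_attr = TRUE)
  # rank invariance under a monotone transform
  expect_equal(expression_groups(e), expression_groups(e^3))
  # nonzero genes in rank order move monotonically through the groups
  o <- order(e[e > 0])
  labs <- as.integer(g[e > 0][o])
  expect_true(all(diff(labs) >= 0))
})

test_that("gene partition builds strand-aware tiled regions and drops short ones", {
  part <- partition_gene(plus_gene())
  expect_setequal(names(part$regions),
                  c("promoter", "first_exon", "first_intron", "rest_exons"))
  expect_equal(part$regions$promoter$intervals$start, 0L)
  expect_equal(part$regions$promoter$intervals$end, 1000L)
  expect_equal(part$regions$first_intron$intervals$start, 1100L)
  expect_equal(part$regions$first_intron$intervals$end, 1500L)
  # a region of length 10 has five tiles of length 2
  p10 <- data.frame(gene_id = "g", transcript_id = "t", chrom = "chr1",
                    strand = "+", start = c(1000L, 1010L),
                    end = c(1010L, 1020L), exon_rank = 1:2)
  expect_equal(partition_gene(p10)$regions$first_exon$tile_sizes,
               rep(2L, 5))
  # length-6 regions are dropped
  p6 <- data.frame(gene_id = "g", transcript_id = "t", chrom = "chr1",
                   strand = "+", start = c(1000L, 1010L),
                   end = c(1006L, 1020L), exon_rank = 1:2)
  expect_false("first_exon" %in% names(partition_gene(p6)$regions))
  expect_error(partition_gene(plus_gene()[1, ]), "single-exon")
})

test_that("tile order follows transcription direction on the minus strand", {
  pg <- partition_gene(plus_gene())
  mg <- partition_gene(minus_gene())
  # promoter of the minus gene sits to the right of its first exon
  expect_equal(mg$regions$promoter$intervals$start, 5600L)
  expect_equal(mg$regions$promoter$intervals$end, 6600L)
  # a CpG just inside the TSS-proximal promoter edge falls in tile 5
  rt_plus <- methfidelity:::.region_tile(pg, "promoter", 999L)
  rt_minus <- methfidelity:::.region_tile(mg, "promoter", 5600L)
  expect_equal(rt_plus, 5L)
  expect_equal(rt_minus, 5L)
  # and the distal edge in tile 1
  expect_equal(methfidelity:::.region_tile(mg, "promoter", 6599L), 1L)
})

test_that("tile profiles equal brute-force per-tile medians on a hand-built gene", {
  # 10 CpGs in the first exon of a gene whose exon1 spans 1000..1100
  pos <- seq(1000L, 1090L, by = 10L)
  meth <- c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90)
  mat <- single_sample_matrix("chr1", pos, meth)
  fid <- seq(0, 0.9, by = 0.1)
  part <- partition_gene(plus_gene())
  q <- factor(setNames("high", "g1"), levels = methfidelity:::.quintile_levels)
  prof <- profile_by_tile(mat, fid, list(part), q)
  fe <- prof[prof$region == "first_exon", ]
  # exon1 length 100: tiles of 20 bp, 2 CpGs each
  expect_equal(fe$tile, 1:5)
  for (t in 1:5) {
    rows <- which((pos - 1000L) %/% 20L + 1L == t)
    expect_equal(fe$meth_median[fe$tile == t], median(meth[rows]))
    expect_equal(fe$fidelity_median[fe$tile == t], median(fid[rows]))
  }
  # tile assignment partitions the region's CpGs
  expect_equal(sum(fe$n_cpgs), length(pos))
  # a tile holding one CpG has IQR 0
  mat1 <- single_sample_matrix("chr1", c(1000L, 1005L, 1021L), c(10, 20, 80))
  prof1 <- profile_by_tile(mat1, c(1, 1, 1), list(part), q)
  fe1 <- prof1[prof1$region == "first_exon" & prof1$tile == 2, ]
  expect_equal(fe1$meth_iqr, 0)
})

test_that("genic feature assignment follows promoter > exon > intron with intergenic fallback", {
  genes <- rbind(plus_gene(), minus_gene())
  sites <- data.frame(
    chrom = "chr1",
    pos = c(500L,    # 500 bp upstream of g1's first exon -> promoter
            1050L,   # inside exon1
            1300L,   # intron
            1550L,   # exon2
            3000L,   # between genes, >1000 bp from any TSS -> intergenic
            6000L))  # within g2's promoter (minus strand)
  ctx <- assign_genic_context(sites, genes)
  expect_equal(as.character(ctx$feature),
               c("promoter", "first_exon", "first_intron", "rest_exon",
                 "intergenic", "promoter"))
  # overlap of gene A promoter and gene B intron resolves to promoter
  gb <- data.frame(gene_id = "g3", transcript_id = "g3.t1", chrom = "chr1",
                   strand = "+", start = c(200L, 2000L),
                   end = c(300L, 2100L), exon_rank = 1:2)
  ctx2 <- assign_genic_context(data.frame(chrom = "chr1", pos = 500L),
                               rbind(plus_gene(), gb))
  expect_equal(as.character(ctx2$feature), "promoter")
})

test_that("TE summaries average CpG cells and resolve location by precedence", {
  genes <- plus_gene()
  tes <- data.frame(te_id = c("t1", "t2", "t3"), class = "SINE",
                    chrom = "chr1", start = c(500L, 1200L, 3000L),
                    end = c(620L, 1320L, 3120L), strand = "+",
                    divergence = c(5, 10, 15),
                    consensus_begin = 1L, consensus_end = 120L,
                    stringsAsFactors = FALSE)
  mat <- single_sample_matrix("chr1", c(510L, 600L, 1250L),
                              c(0, 100, 50))
  ts <- te_summary(mat, c(1, 1, 0.5), tes, genes)
  expect_equal(nrow(ts), 2L)  # t3 has no covered CpGs
  expect_equal(ts$location_class, c("promoter", "intronic"))
  expect_equal(ts$mean_meth[ts$te_id == "t1"], 50)
})

test_that("divergence associations use Spearman rank correlation per class", {
  te <- data.frame(te_id = paste0("t", 1:6), class = "LTR",
                   divergence = 1:6, mean_meth = (1:6)^2,
                   mean_fidelity = c(3, 1, 4, 1, 5, 9))
  da <- divergence_association(te)
  expect_equal(da$rho[da$response == "mean_meth"], 1)
  expect_error(divergence_association(te[1:2, ]), "at least 3")
  # independence by construction: small rho, large p
  set.seed(302)
  te2 <- data.frame(te_id = paste0("t", 1:200), class = "SINE",
                    divergence = runif(200, 2, 30),
                    mean_meth = runif(200, 0, 100),
                    mean_fidelity = runif(200))
  da2 <- divergence_association(te2)
  expect_true(all(abs(da2$rho) < 0.2))
  expect_true(all(da2$p > 0.01))
  # constant input flagged, not an error
  te3 <- te; te3$mean_fidelity <- 1
  da3 <- divergence_association(te3)
  expect_true(da3$constant_input[da3$response == "mean_fidelity"])
})

test_that("SINE consensus profiles map CpGs 5' to 3' and drop positions past 200", {
  sines <- data.frame(te_id = c("s1", "s2"), class = "SINE", chrom = "chr1",
                      start = c(1000L, 2000L), end = c(1150L, 2150L),
                      strand = c("+", "-"), divergence = 10,
                      consensus_begin = c(1L, 1L),
                      consensus_end = c(150L, 150L),
                      stringsAsFactors = FALSE)
  # plus strand: consensus position = 1 + offset from the left end;
  # minus strand: counted from the right (the element's 5' end)
  mat <- single_sample_matrix("chr1", c(1010L, 2139L), c(20, 80))
  prof <- sine_position_profile(mat, sines)
  expect_equal(prof$position, 11L)
  expect_equal(prof$mean_meth, 50)  # both CpGs map to position 11
  # flat input gives a flat profile
  mat2 <- single_sample_matrix("chr1", seq(1000L, 1140L, 20L), rep(50, 8))
  prof2 <- sine_position_profile(mat2, sines[1, ])
  expect_true(all(prof2$mean_meth == 50))
  # a CpG past consensus position 200 is excluded
  s3 <- data.frame(te_id = "s3", class = "SINE", chrom = "chr1",
                   start = 3000L, end = 3300L, strand = "+",
                   divergence = 1, consensus_begin = 1L,
                   consensus_end = 300L, stringsAsFactors = FALSE)
  mat3 <- single_sample_matrix("chr1", 3250L, 50)  # consensus position 251
  expect_equal(nrow(sine_position_profile(mat3, s3)), 0L)
})

test_that("fold enrichment is the overlap-fraction ratio, robust to peak duplication", {
  bg <- data.frame(chrom = "chr1", pos = seq(100L, 1000L, 100L))
  fg_all <- bg[1:4, ]
  peaks <- data.frame(chrom = "chr1", start = 50L, end = 450L)
  # background half in peaks, foreground all in peaks -> ratio
  expect_equal(fold_enrichment(fg_all, bg, peaks), (4 / 4) / (4 / 10))
  expect_equal(fold_enrichment(bg, bg, peaks), 1)
  expect_equal(fold_enrichment(fg_all, bg, rbind(peaks, peaks)),
               fold_enrichment(fg_all, bg, peaks))
  expect_warning(out <- fold_enrichment(fg_all, bg, peaks[0, ]), "empty")
  expect_true(is.na(out))
  far <- data.frame(chrom = "chr2", start = 1L, end = 2L)
  expect_warning(out2 <- fold_enrichment(fg_all, bg, far), "undefined")
  expect_true(is.na(out2))
})

test_that("annotation files round trip through their standard formats", {
  d <- withr::local_tempdir()
  genes <- rbind(plus_gene(), minus_gene())
  gp <- file.path(d, "genes.bed")
  write_gene_models(genes, gp)
  back <- read_gene_models(gp)
  back <- back[order(back$gene_id, back$exon_rank), ]
  genes_s <- genes[order(genes$gene_id, genes$exon_rank), ]
  expect_equal(back$start, genes_s$start)
  expect_equal(back$end, genes_s$end)
  expect_equal(back$strand, genes_s$strand)
  expect_equal(back$exon_rank, genes_s$exon_rank)
  # RepeatMasker dialect
  tes <- data.frame(te_id = c("B1#1", "L1Md#2"), class = c("SINE", "LINE"),
                    chrom = "chrS1", start = c(100L, 900L),
                    end = c(250L, 1400L), strand = c("+", "-"),
                    divergence = c(12.3, 25.0),
                    consensus_begin = c(5L, 30L),
                    consensus_end = c(154L, 529L), stringsAsFactors = FALSE)
  rp <- file.path(d, "rm.out")
  write_repeatmasker_out(tes, rp)
  tback <- read_repeatmasker_out(rp)
  expect_equal(tback$start, tes$start)
  expect_equal(tback$end, tes$end)
  expect_equal(tback$strand, tes$strand)
  expect_equal(tback$divergence, tes$divergence)
  expect_equal(tback$consensus_begin, tes$consensus_begin)
  expect_equal(tback$class, tes$class)
  # peak BED
  pk <- data.frame(chrom = "chrS1", start = c(10L, 500L),
                   end = c(200L, 900L))
  pp <- file.path(d, "peaks.bed")
  write_bed(pk, pp)
  expect_equal(read_peaks(pp), pk)
})
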