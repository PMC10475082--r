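# Allele-level clonal-expansion simulator. The model is strand-symmetric:
# each diploid cell carries two alleles per CpG, each either methylated or
# not, so a single cell's site level is 0, 50 or 100%. Per division and per
# allele, a methylated template stays methylated with probability 1 - loss
# (maintenance), an unmethylated template becomes methylated with
# probability gain (de novo); daughters are independent. Sites evolve
# independently (no neighbour coupling).

#' Simulation configuration
#'
#' @param n_per_class Named integer vector: number of CpG sites per
#'   inheritance class (`faithful_hypo`, `faithful_hyper`, `imprinted`,
#'   `labile`).
#' @param n_divisions Divisions for both the parental growth and each
#'   clonal expansion. Default 21 (2^21 ~ 2e6 cells, the scale of the
#'   cultured lines).
#' @param n_clones Clonal lines per parental lineage (default 7).
#' @param n_lineages Number of parental lineages (default 2).
#' @param max_cells Population cap; once exceeded, a uniformly subsampled
#'   cohort of this size is propagated (default 10000).
#' @param depth_median Target median sequencing depth per CpG (default 32).
#' @param depth_dispersion Negative-binomial size parameter (default 5).
#' @param err_fail Probability a methylated cytosine yields an unmethylated
#'   call (bisulfite over-conversion of 5mC; default 0.005).
#' @param err_over Probability an unmethylated cytosine yields a methylated
#'   call (conversion failure; default 0.005).
#' @param gain_rate,loss_rate Per-allele per-division de novo and
#'   maintenance-failure probabilities at labile sites (default 0.1 each).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_class = c(faithful_hypo = 100, faithful_hyper = 100,
                                       imprinted = 100, labile = 100),
                       n_divisions = 21, n_clones = 7, n_lineages = 2,
                       max_cells = 10000,
                       depth_median = 32, depth_dispersion = 5,
                       err_fail = 0.005, err_over = 0.005,
                       gain_rate = 0.1, loss_rate = 0.1) {
  probs <- c(err_fail, err_over, gain_rate, loss_rate)
  if (any(probs < 0 | probs > 1)) stopf("all probabilities must lie in [0, 1]")
  structure(list(n_per_class = n_per_class, n_divisions = n_divisions,
                 n_clones = n_clones, n_lineages = n_lineages,
                 max_cells = max_cells, depth_median = depth_median,
                 depth_dispersion = depth_dispersion,
                 err_fail = err_fail, err_over = err_over,
                 gain_rate = gain_rate, loss_rate = loss_rate),
            class = "sim_config")
}

# Blocks of each class; hypo sites cluster densely (CGI-like), labile sites
# are sparse, mirroring the observation that consistently hypomethylated
# CpGs sit in CpG-dense regions.
.class_block_layout <- list(
  faithful_hypo  = list(block = 10L, gap_in = 8:15,   type = "hypo_island"),
  faithful_hyper = list(block = 5L,  gap_in = 30:80,  type = "hyper_block"),
  imprinted      = list(block = 5L,  gap_in = 15:25,  type = "imprint_island"),
  labile         = list(block = 5L,  gap_in = 50:150, type = "labile_block")
)

#' Generate a synthetic CpG genome
#'
#' Lays site blocks out on two synthetic chromosomes. Faithful hypomethylated
#' sites form dense CGI-like islands, faithful hypermethylated and imprinted
#' sites form moderate blocks, and labile sites are split between loose
#' blocks and sparse intergenic singletons. Block structure is recorded so
#' that [make_annotations()] can build gene models around it.
#'
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return `data.frame` of site specifications: `chrom`, `pos`, `class`,
#'   `gain`, `loss`, `m0` (founder methylation probability), `block`,
#'   `block_type`.
#' @export
make_genome <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  npc <- config$n_per_class
  blocks <- list()
  for (cls in names(npc)) {
    lay <- .class_block_layout[[cls]]
    n <- npc[[cls]]
    if (cls == "labile") {
      n_block_sites <- (n %/% 2) - (n %/% 2) %% lay$block
      n_single <- n - n_block_sites
      nb <- n_block_sites %/% lay$block
      sizes <- c(rep(lay$block, nb), rep(1L, n_single))
      types <- c(rep("labile_block", nb), rep("labile_singleton", n_single))
    } else {
      nb <- ceiling(n / lay$block)
      sizes <- rep(lay$block, nb)
      sizes[nb] <- n - lay$block * (nb - 1)
      types <- rep(lay$type, nb)
    }
    for (i in seq_along(sizes)) {
      blocks[[length(blocks) + 1L]] <- list(class = cls, size = sizes[i],
                                            type = types[i],
                                            gap_in = lay$gap_in)
    }
  }
  # interleave: expressed-gene loci (island + 2 hyper blocks), silent-gene
  # loci (3 labile blocks), imprint islands, then singletons spread through
  is_type <- function(t) which(vapply(blocks, function(b) b$type == t, TRUE))
  ord <- integer(0)
  hypo <- is_type("hypo_island"); hyper <- is_type("hyper_block")
  lab_b <- is_type("labile_block"); imp <- is_type("imprint_island")
  single <- is_type("labile_singleton")
  hi <- 1L
  for (i in seq_along(hypo)) {
    ord <- c(ord, hypo[i])
    take <- hyper[seq.int(hi, length.out = min(2L, length(hyper) - hi + 1L))]
    ord <- c(ord, take); hi <- hi + length(take)
  }
  li <- 1L
  while (li <= length(lab_b)) {
    take <- lab_b[seq.int(li, length.out = min(3L, length(lab_b) - li + 1L))]
    ord <- c(ord, take); li <- li + length(take)
  }
  ord <- c(ord, imp)
  # split loci across two chromosomes; sparse labile singletons form an
  # intergenic zone at the end of each chromosome
  seq2 <- function(from, to) if (to < from) integer(0) else seq.int(from, to)
  half_loci <- ceiling(length(ord) / 2)
  half_single <- ceiling(length(single) / 2)
  chrom_blocks <- list(
    c(ord[seq_len(half_loci)], single[seq_len(half_single)]),
    c(ord[seq2(half_loci + 1L, length(ord))],
      single[seq2(half_single + 1L, length(single))]))
  rows <- list()
  for (ch in 1:2) {
    idx <- chrom_blocks[[ch]]
    cur <- 1000L
    for (bi in idx) {
      b <- blocks[[bi]]
      gaps <- sample(b$gap_in, b$size - 1L, replace = TRUE)
      pos <- cur + cumsum(c(0L, gaps))
      m0 <- switch(b$class, faithful_hypo = 0, faithful_hyper = 1,
                   imprinted = 0.5, labile = runif(1, 0.2, 0.8))
      g <- if (b$class == "labile") config$gain_rate else 0
      l <- if (b$class == "labile") config$loss_rate else 0
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = paste0("chrS", ch), pos = as.integer(pos), class = b$class,
        gain = g, loss = l, m0 = m0, block = bi, block_type = b$type,
        stringsAsFactors = FALSE)
      cur <- pos[length(pos)] + sample(1500:3000, 1)
    }
  }
  genome <- do.call(rbind, rows)
  genome <- genome[order(genome$chrom, genome$pos), , drop = FALSE]
  rownames(genome) <- NULL
  genome
}

# per-allele transmission; deterministic copy where gain = loss = 0
transmit_alleles <- function(a, gain, loss) {
  out <- a
  dyn <- which(gain > 0 | loss > 0)
  if (length(dyn)) {
    p <- ifelse(a[dyn], 1 - loss[dyn], gain[dyn])
    out[dyn] <- runif(length(dyn)) < p
  }
  out
}

#' Construct a founder cell
#'
#' Allele states follow the site class: faithful hypo/hyper sites are
#' homozygous unmethylated/methylated, imprinted sites carry exactly one
#' methylated allele, labile sites draw each allele Bernoulli(m0).
#'
#' @param sites Site specification `data.frame` from [make_genome()].
#' @return List with logical vectors `a1`, `a2` (one element per site).
#' @export
founder_cell <- function(sites) {
  n <- nrow(sites)
  a1 <- a2 <- logical(n)
  a1[sites$class == "faithful_hyper"] <- TRUE
  a2[sites$class == "faithful_hyper"] <- TRUE
  a1[sites$class == "imprinted"] <- TRUE
  lab <- which(sites$class == "labile")
  a1[lab] <- runif(length(lab)) < sites$m0[lab]
  a2[lab] <- runif(length(lab)) < sites$m0[lab]
  list(a1 = a1, a2 = a2)
}

#' Divide one cell into two daughters
#'
#' Per allele and per daughter, a methylated template stays methylated with
#' probability `1 - loss`; an unmethylated template becomes methylated with
#' probability `gain`. The two daughters are independent.
#'
#' @param cell List with logical allele vectors `a1`, `a2`.
#' @param sites Site specification `data.frame` (columns `gain`, `loss`).
#' @return List of two daughter cells.
#' @export
divide_cell <- function(cell, sites) {
  list(
    list(a1 = transmit_alleles(cell$a1, sites$gain, sites$loss),
         a2 = transmit_alleles(cell$a2, sites$gain, sites$loss)),
    list(a1 = transmit_alleles(cell$a1, sites$gain, sites$loss),
         a2 = transmit_alleles(cell$a2, sites$gain, sites$loss))
  )
}

#' Expand a founder cell into a clonal population (cell-level)
#'
#' Tracks every cell's two allele states through `n_divisions` binary
#' divisions. If the population would exceed `max_cells`, a uniformly
#' subsampled cohort of constant size is propagated instead (unbiased
#' sampling; the cohort size then stays at `max_cells`).
#'
#' @param founder A cell as returned by [founder_cell()].
#' @param sites Site specification `data.frame`.
#' @param n_divisions Number of divisions (>= 0).
#' @param max_cells Population cap (default 10000).
#' @return A `cell_population`: list with logical matrices `a1`, `a2`
#'   (cells x sites) and the `sites` table.
#' @export
expand_clone <- function(founder, sites, n_divisions, max_cells = 10000) {
  a1 <- matrix(founder$a1, nrow = 1)
  a2 <- matrix(founder$a2, nrow = 1)
  gain <- sites$gain; loss <- sites$loss
  dyn <- which(gain > 0 | loss > 0)
  for (d in seq_len(n_divisions)) {
    a1 <- rbind(a1, a1); a2 <- rbind(a2, a2)
    if (length(dyn)) {
      for (m in c("a1", "a2")) {
        a <- get(m)
        sub <- a[, dyn, drop = FALSE]
        p <- ifelse(sub, rep(1 - loss[dyn], each = nrow(a)),
                    rep(gain[dyn], each = nrow(a)))
        sub[] <- runif(length(sub)) < p
        a[, dyn] <- sub
        assign(m, a)
      }
    }
    if (nrow(a1) > max_cells) {
      keep <- sample.int(nrow(a1), max_cells)
      a1 <- a1[keep, , drop = FALSE]
      a2 <- a2[keep, , drop = FALSE]
    }
  }
  structure(list(a1 = a1, a2 = a2, sites = sites), class = "cell_population")
}

#' Per-site population methylation level of a cell population
#' @param pop A `cell_population` or `site_counts` object.
#' @return Numeric vector of percentages in [0, 100].
#' @export
population_level <- function(pop) {
  if (inherits(pop, "site_counts"))
    return(100 * (pop$n1 + 2 * pop$n2) / (2 * pop$n_cells))
  100 * (colSums(pop$a1) + colSums(pop$a2)) / (2 * nrow(pop$a1))
}

#' Per-cell per-site methylation levels
#' @param pop A `cell_population`.
#' @return Matrix (cells x sites) with values in \{0, 50, 100\}.
#' @export
cell_levels <- function(pop) 50 * (pop$a1 + pop$a2)

# ---- per-site allele-count propagation -------------------------------------
# Because divisions are deterministic doublings and allele transmissions are
# independent across sites and alleles, the per-site counts of cells with
# 0/1/2 methylated alleles form a multinomial branching process that is
# distributionally exact; it is used for large expansions where tracking
# every cell is wasteful. See the methods vignette.

counts_from_cell <- function(cell) {
  k <- as.integer(cell$a1) + as.integer(cell$a2)
  structure(list(n0 = as.numeric(k == 0), n1 = as.numeric(k == 1),
                 n2 = as.numeric(k == 2), n_cells = 1), class = "site_counts")
}

# vectorized multinomial over sites: size m, probs (p0, p1, p2)
.rmultinom_sites <- function(m, p0, p1, p2) {
  x2 <- rbinom(length(m), m, p2)
  rest <- m - x2
  pc <- ifelse(p2 < 1, pmin(1, p1 / (1 - p2)), 0)
  x1 <- rbinom(length(m), rest, pc)
  list(n0 = rest - x1, n1 = x1, n2 = x2)
}

#' Expand a founder cell via per-site allele-count propagation
#'
#' Distributionally exact aggregation of [expand_clone()]: tracks, per site,
#' how many cells carry 0, 1 or 2 methylated alleles. Scales to millions of
#' cells. Subsampling beyond `max_cells` is hypergeometric per site.
#'
#' @inheritParams expand_clone
#' @return A `site_counts` object: vectors `n0`, `n1`, `n2` and `n_cells`.
#' @export
expand_counts <- function(founder, sites, n_divisions, max_cells = 10000) {
  cc <- counts_from_cell(founder)
  n0 <- cc$n0; n1 <- cc$n1; n2 <- cc$n2
  g <- sites$gain; l <- sites$loss
  # daughter allele-count distributions by parent class
  d0 <- list(p0 = (1 - g)^2, p1 = 2 * g * (1 - g), p2 = g^2)
  d1 <- list(p0 = l * (1 - g), p1 = (1 - l) * (1 - g) + l * g,
             p2 = (1 - l) * g)
  d2 <- list(p0 = l^2, p1 = 2 * l * (1 - l), p2 = (1 - l)^2)
  for (d in seq_len(n_divisions)) {
    f0 <- .rmultinom_sites(2 * n0, d0$p0, d0$p1, d0$p2)
    f1 <- .rmultinom_sites(2 * n1, d1$p0, d1$p1, d1$p2)
    f2 <- .rmultinom_sites(2 * n2, d2$p0, d2$p1, d2$p2)
    n0 <- f0$n0 + f1$n0 + f2$n0
    n1 <- f0$n1 + f1$n1 + f2$n1
    n2 <- f0$n2 + f1$n2 + f2$n2
    ncell <- n0[1] + n1[1] + n2[1]
    if (ncell > max_cells) {
      s0 <- rhyper(length(n0), n0, ncell - n0, max_cells)
      s1 <- rhyper(length(n1), n1, ncell - n0 - n1, max_cells - s0)
      n0 <- s0; n1 <- s1; n2 <- max_cells - s0 - s1
    }
  }
  structure(list(n0 = n0, n1 = n1, n2 = n2, n_cells = n0[1] + n1[1] + n2[1]),
            class = "site_counts")
}

#' Sample a single cell from a population
#'
#' Draws, per site, an allele-count state with the population frequencies
#' (sites are independent under the model), returning a founder-style cell
#' for a new clonal expansion.
#'
#' @param pop A `site_counts` or `cell_population`.
#' @return List with logical vectors `a1`, `a2`.
#' @export
sample_cell <- function(pop) {
  if (inherits(pop, "cell_population")) {
    i <- sample.int(nrow(pop$a1), 1)
    return(list(a1 = pop$a1[i, ], a2 = pop$a2[i, ]))
  }
  n <- pop$n_cells
  u <- runif(length(pop$n0)) * n
  k <- (u > pop$n0) + (u > pop$n0 + pop$n1)
  het_flip <- runif(length(k)) < 0.5
  list(a1 = k == 2 | (k == 1 & het_flip),
       a2 = k == 2 | (k == 1 & !het_flip))
}

# mu giving the requested negative-binomial median
.nb_mu_for_median <- function(target, size) {
  for (mu in seq(target * 0.8, target * 1.6, by = 0.1))
    if (qnbinom(0.5, size = size, mu = mu) == target) return(mu)
  target
}

#' Simulate a bisulfite sequencing readout of a population
#'
#' Coverage per site is negative-binomial (parameterized by target median
#' and dispersion); each call samples a random allele from the population
#' and is observed methylated with probability `1 - err_fail` if the allele
#' is methylated, else `err_over`. Zero-coverage sites are dropped.
#'
#' @param pop A `site_counts` or `cell_population`.
#' @param sites Site specification `data.frame` (for coordinates).
#' @param sample_id Sample identifier for the output table.
#' @param config A [sim_config()] supplying the depth/error model.
#' @return A [methylation_table()].
#' @export
sequence_population <- function(pop, sites, sample_id, config = sim_config()) {
  p <- population_level(pop) / 100
  mu <- .nb_mu_for_median(config$depth_median, config$depth_dispersion)
  covv <- rnbinom(length(p), size = config$depth_dispersion, mu = mu)
  p_obs <- p * (1 - config$err_fail) + (1 - p) * config$err_over
  n_meth <- rbinom(length(p), covv, p_obs)
  methylation_table(sample_id, sites$chrom, sites$pos,
                    n_meth, covv - n_meth)
}

#' Run a full clonal-expansion experiment
#'
#' Emulates the study design: per lineage, a founder cell grows into a
#' parental population; single cells sampled from it seed the clonal lines,
#' each expanded for the same number of divisions; every population is then
#' sequenced. Defaults give 2 parental + 14 clonal coverage tables.
#'
#' @param config A [sim_config()].
#' @param seed Optional RNG seed; fully determines the output.
#' @return List with `genome`, `tables` (named list of
#'   [methylation_table()]), `samples` ([sample_info()]), and `truth`
#'   (per-site class/rates plus per-clone founder levels and parental
#'   population levels).
#' @export
run_clonal_experiment <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- make_genome(config)
  tables <- list()
  ids <- character(0); roles <- character(0); lins <- character(0)
  founder_levels <- list()
  parental_levels <- list()
  for (L in seq_len(config$n_lineages)) {
    lin <- paste0("L", L)
    fndr <- founder_cell(genome)
    par_pop <- expand_counts(fndr, genome, config$n_divisions,
                             config$max_cells)
    parental_levels[[lin]] <- population_level(par_pop)
    pid <- paste0(lin, "-P")
    tables[[pid]] <- sequence_population(par_pop, genome, pid, config)
    ids <- c(ids, pid); roles <- c(roles, "parental"); lins <- c(lins, lin)
    for (cl in seq_len(config$n_clones)) {
      cid <- paste0(lin, "-C", cl)
      cf <- sample_cell(par_pop)
      founder_levels[[cid]] <- 50 * (as.integer(cf$a1) + as.integer(cf$a2))
      cpop <- expand_counts(cf, genome, config$n_divisions, config$max_cells)
      tables[[cid]] <- sequence_population(cpop, genome, cid, config)
      ids <- c(ids, cid); roles <- c(roles, "clonal"); lins <- c(lins, lin)
    }
  }
  samples <- sample_info(ids, roles, lins)
  truth <- list(sites = genome,
                clone_founder_level = do.call(cbind, founder_levels),
                parental_level = do.call(cbind, parental_levels))
  list(genome = genome, tables = tables, samples = samples, truth = truth,
       config = config)
}

#' Write the outputs of a simulated experiment to disk
#'
#' Emits one Bismark coverage file per sample, a sample sheet TSV and a
#' per-site truth TSV (class, rates, founder probability).
#'
#' @param experiment Result of [run_clonal_experiment()].
#' @param dir Output directory (created if needed).
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (id in names(experiment$tables)) {
    p <- file.path(dir, paste0(id, ".cov"))
    write_cov(experiment$tables[[id]], p)
    paths <- c(paths, p)
  }
  sheet <- experiment$samples
  sheet$path <- paths
  write_sample_sheet(sheet, file.path(dir, "samples.tsv"))
  write.table(experiment$genome, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
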