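test_that("fidelity score counts the closed faithful intervals", {
  expect_equal(fidelity_score(rep(0, 14)), 1)
  expect_equal(fidelity_score(c(rep(50, 7), rep(25, 7))), 0.5)
  v <- c(0, 5, 10, 20, 30, 40, 50, 55, 60, 70, 80, 90, 95, 100)
  expect_equal(fidelity_score(v), 10 / 14)
  expect_equal(fidelity_score(v), oracle_fidelity(v))
  expect_error(fidelity_score(c(50, 101)), "\\[0, 100\\]")
})

test_that("fidelity score matches the interval-membership oracle on random input and is permutation invariant", {
  set.seed(101)
  for (i in 1:100) {
    v <- round(runif(sample(3:20, 1), 0, 100), 1)
    f <- fidelity_score(v)
    expect_equal(f, oracle_fidelity(v))
    expect_equal(f, fidelity_score(sample(v)))
    expect_equal(f == 1, all((v >= 0 & v <= 10) | (v >= 40 & v <= 60) |
                               (v >= 90 & v <= 100)))
  }
})

test_that("neighbour similarity compares each site with its closest CpG per clonal line", {
  # 3 sites; site 2's closest is site 1 (40 bp < 60 bp)
  m <- matrix(50, 3, 16)
  mat <- toy_matrix(m, pos = c(100L, 140L, 200L))
  expect_equal(neighbour_similarity(mat), rep(1, 3))
  # neighbour differing by 50 points in every line scores 0
  m2 <- rbind(rep(0, 16), rep(50, 16))
  mat2 <- toy_matrix(m2, pos = c(100L, 140L))
  expect_equal(neighbour_similarity(mat2), c(0, 0))
  # 10.0-point difference counts, 10.1 does not
  m3 <- rbind(rep(0, 16), c(rep(NA, 0), rep(c(10, 10.1), 8)))
  mat3 <- toy_matrix(m3, pos = c(100L, 140L))
  s <- neighbour_similarity(mat3)
  # of the 14 clonal columns, 6 hold 10.0 (within) and 8 hold 10.1 (outside)
  n_in <- sum(mat3$meth[2, mat3$samples$role == "clonal"] == 10)
  expect_equal(s[1], n_in / 14)
  expect_equal(s[1], 6 / 14)
  # lone site on a chromosome is NA, not 0
  mat4 <- toy_matrix(matrix(50, 2, 16), chrom = c("chr1", "chr2"),
                     pos = c(100L, 100L))
  expect_true(all(is.na(neighbour_similarity(mat4))))
})

test_that("CpG density counts neighbours within 100 bp, capped, excluding self", {
  s1 <- data.frame(chrom = "chr1", pos = 1000L)
  expect_equal(cpg_density(s1), 0L)
  # 45 CpGs within 100 bp capped at 30
  s2 <- data.frame(chrom = "chr1", pos = c(500L, 500L + seq_len(45) * 2L))
  expect_equal(cpg_density(s2)[1], 30L)
  # boundary-inclusive window
  s3 <- data.frame(chrom = "chr1", pos = c(0L, 50L, 100L, 101L))
  expect_equal(cpg_density(s3)[1], 2L)
  # random positions against the quadratic oracle
  set.seed(103)
  pos <- sort(sample.int(2000, 60))
  s4 <- data.frame(chrom = "chr1", pos = pos)
  d <- cpg_density(s4)
  for (i in seq_along(pos)) expect_equal(d[i], oracle_density(pos, i))
})

test_that("state bins are half-open with 90 assigned to high", {
  expect_equal(as.character(bin_state(5)), "low")
  expect_equal(as.character(bin_state(40)), "intermediate")
  expect_equal(as.character(bin_state(90)), "high")
  expect_equal(as.character(bin_state(c(0, 10, 60, 89.999, 100))),
               c("low", "low_intermediate", "high_intermediate",
                 "high_intermediate", "high"))
  set.seed(104)
  for (x in runif(100, 0, 100))
    expect_equal(as.character(bin_state(x)), oracle_bin(x))
})

test_that("inheritance classification uses the printed half-open intervals", {
  # all clonal lines at 0 -> faithful
  expect_equal(as.character(classify_inheritance(
    constant_row_matrix(0))[1]), "faithful")
  # qualifying intermediate clone in each lineage -> probabilistic
  m <- matrix(0, 1, 16)
  m[1, 3] <- 25   # an L1 clone
  m[1, 11] <- 75  # an L2 clone
  expect_equal(as.character(classify_inheritance(toy_matrix(m))[1]),
               "probabilistic")
  # qualifying clone in only one lineage -> other
  m[1, 11] <- 0
  expect_equal(as.character(classify_inheritance(toy_matrix(m))[1]),
               "other")
  # exactly 10 is outside (10,40] but inside faithful [0,10]
  m2 <- matrix(0, 1, 16)
  m2[1, 3] <- 10
  expect_equal(as.character(classify_inheritance(toy_matrix(m2))[1]),
               "faithful")
  # exactly 40 is probabilistic-qualifying and breaks faithful (40,60]
  m3 <- matrix(0, 1, 16)
  m3[1, 3] <- 40; m3[1, 11] <- 40
  expect_equal(as.character(classify_inheritance(toy_matrix(m3))[1]),
               "probabilistic")
})

test_that("k-means grouping recovers separated archetypes and is deterministic", {
  set.seed(105)
  # two perfectly separated blobs
  m <- rbind(matrix(abs(rnorm(10 * 16, 1, 0.5)), 10, 16),
             matrix(100 - abs(rnorm(10 * 16, 1, 0.5)), 10, 16))
  mat <- toy_matrix(m)
  cl <- cluster_methylation(mat, k = 2, seed = 3)
  expect_equal(as.character(cl$group), rep(c("U", "M"), each = 10))
  cl2 <- cluster_methylation(mat, k = 2, seed = 3)
  expect_identical(cl$cluster, cl2$cluster)
  # five archetypes, k = 7: merged groups recover the truth
  arch <- function(l1, l2, n) {
    cbind(matrix(pmin(pmax(rnorm(n * 8, l1, 2), 0), 100), n, 8),
          matrix(pmin(pmax(rnorm(n * 8, l2, 2), 0), 100), n, 8))
  }
  m5 <- rbind(arch(2, 2, 30), arch(2, 50, 30), arch(50, 50, 30),
              arch(98, 50, 30), arch(98, 98, 30))
  truth <- rep(c("U", "UI", "I", "MI", "M"), each = 30)
  mat5 <- toy_matrix(m5)
  cl5 <- cluster_methylation(mat5, k = 7, seed = 5)
  expect_gte(mean(as.character(cl5$group) == truth), 0.9)
  # group labels do not depend on sample column order
  perm <- sample(16)
  matp <- mat5
  matp$meth <- matp$meth[, perm]
  matp$cov <- matp$cov[, perm]
  matp$samples <- matp$samples[perm, ]
  clp <- cluster_methylation(matp, k = 7, seed = 5)
  expect_equal(table(as.character(clp$group)),
               table(as.character(cl5$group)))
  expect_error(cluster_methylation(mat, k = 50), "exceeds")
})

test_that("overall grouping scheme yields U/I/M for the knockout design", {
  m <- rbind(matrix(1, 5, 16), matrix(50, 5, 16), matrix(99, 5, 16))
  cl <- cluster_methylation(toy_matrix(m), k = 3, seed = 1,
                            scheme = "overall")
  expect_equal(as.character(cl$group), rep(c("U", "I", "M"), each = 5))
})

test_that("region calling applies the span, count and mean-fidelity rules", {
  s <- data.frame(chrom = "chr1", pos = c(100L, 110L, 119L),
                  fidelity = c(1, 1, 1))
  r <- call_regions(s)
  expect_equal(nrow(r), 1L)
  expect_equal(r$kind, "faithful")
  expect_equal(r$n_cpgs, 3L)
  # two CpGs never form a region
  s2 <- data.frame(chrom = "chr1", pos = c(100L, 120L), fidelity = c(0, 0))
  expect_equal(nrow(call_regions(s2)), 0L)
  # mean 0.667 < 0.75 over 12 bp
  s3 <- data.frame(chrom = "chr1", pos = c(100L, 105L, 111L),
                   fidelity = c(0.9, 0.6, 0.5))
  r3 <- call_regions(s3)
  expect_equal(r3$kind, "unfaithful")
  expect_equal(r3$mean_fidelity, mean(c(0.9, 0.6, 0.5)))
  # regions of one kind never overlap and each meets its threshold
  set.seed(106)
  s4 <- data.frame(chrom = "chr1", pos = sort(sample.int(5000, 200)),
                   fidelity = sample(c(0, 0.5, 1), 200, replace = TRUE,
                                     prob = c(0.3, 0.2, 0.5)))
  r4 <- call_regions(s4)
  for (kind in c("faithful", "unfaithful")) {
    rk <- r4[r4$kind == kind, , drop = FALSE]
    if (nrow(rk) > 1)
      expect_true(all(rk$start[-1] >= rk$end[-nrow(rk)]))
  }
  expect_true(all(r4$mean_fidelity[r4$kind == "faithful"] == 1))
  expect_true(all(r4$mean_fidelity[r4$kind == "unfaithful"] < 0.75))
  expect_true(all(r4$n_cpgs >= 3))
  expect_true(all(r4$end - r4$start >= 5))
})

test_that("the assembled fidelity profile carries one consistent row per site", {
  set.seed(107)
  exp <- run_clonal_experiment(
    sim_config(n_per_class = c(faithful_hypo = 30, faithful_hyper = 30,
                               imprinted = 30, labile = 30),
               n_divisions = 8, max_cells = 2000), seed = 3)
  mat <- build_cpg_matrix(exp$tables, exp$samples)
  prof <- fidelity_profile(mat, k = 5, seed = 2)
  expect_equal(nrow(prof), nrow(mat$sites))
  expect_true(all(prof$fidelity >= 0 & prof$fidelity <= 1))
  expect_true(all(!is.na(prof$group)))
  expect_true(all(prof$cpg_density <= 30))
})
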