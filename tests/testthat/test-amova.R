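test_that("group-fixed alleles put all variance among groups", {
  g1 <- matrix(1L, 8, 3); g2 <- matrix(2L, 8, 3)
  t <- genotype_table(paste0("i", 1:32), c("L1", "L2", "L3"),
                      rbind(g1, g1, g2, g2), rbind(g1, g1, g2, g2),
                      rep(c("P1", "P2", "P3", "P4"), each = 8),
                      group = c(P1 = "G1", P2 = "G1", P3 = "G2", P4 = "G2"))
  a <- amova(t, n_perm = 0)
  expect_equal(unname(a$f_stats["F_CT"]), 1)
  expect_equal(unname(a$f_stats["F_SC"]), 0)
  expect_equal(a$table$percent_of_total,
               c(100, 0, 0, 0))
})

test_that("sums of squares match the brute-force oracle on a 12-individual fixture", {
  # 3 populations x 4 individuals, 1 locus, 2 groups (G1: P1+P2, G2: P3)
  a1 <- c(1, 1, 2, 1,   2, 2, 1, 3,   3, 3, 3, 2)
  a2 <- c(2, 1, 2, 3,   2, 3, 1, 3,   3, 1, 3, 2)
  pop <- rep(1:3, each = 4)
  grp <- c(1L, 1L, 2L)
  t <- genotype_table(paste0("i", 1:12), "L1", a1, a2,
                      paste0("P", pop),
                      group = c(P1 = "G1", P2 = "G1", P3 = "G2"))
  a <- amova(t, n_perm = 0)
  oracle_ss <- brute_amova_ss(a1, a2, pop, grp)
  expect_equal(a$table$sum_of_squares, unname(oracle_ss), tolerance = 1e-12)
  expect_equal(a$table$df, c(2 - 1, 3 - 2, 12 - 3, 12))
  # components solve the nested mean-square equations for those SS
  fit <- riverpg:::.amova_core(matrix(a1, ncol = 1), matrix(a2, ncol = 1),
                               pop, grp)
  ms <- oracle_ss / a$table$df
  sd2 <- ms[["wi"]]
  sc2 <- (ms[["ai"]] - sd2) / 2
  # copy-count coefficients, recomputed directly for this balanced design:
  # pops of 8 copies, groups of 16 and 8 copies, 24 copies total
  c3 <- (24 - (8^2 / 16 + 8^2 / 16 + 8^2 / 8)) / (3 - 2)
  c4 <- ((8^2 / 16 + 8^2 / 16 + 8^2 / 8) - 3 * 8^2 / 24) / (2 - 1)
  c5 <- (24 - (16^2 + 8^2) / 24) / (2 - 1)
  sb2 <- (oracle_ss[["ap"]] - 1 * (sd2 + 2 * sc2)) / c3
  sa2 <- (oracle_ss[["ag"]] - 1 * (sd2 + 2 * sc2) - c4 * sb2) / c5
  expect_equal(a$table$variance_component, c(sa2, sb2, sc2, sd2),
               tolerance = 1e-12)
})

test_that("percentages sum to 100 and the nested F identity always holds", {
  for (seed in 1:6) {
    t <- simulate_genotype_table(
      n_per_site = c(A = 15, B = 20, C = 12, D = 18, E = 25),
      n_loci = 5, n_alleles = 4, F = 0.06, F_IS = 0.2, seed = 400 + seed)
    a <- amova(t, hierarchy = c(A = "G1", B = "G1", C = "G2", D = "G2",
                                E = "G2"), n_perm = 0)
    expect_equal(sum(a$table$percent_of_total), 100, tolerance = 1e-9)
    f <- a$f_stats
    expect_equal(1 - f[["F_IT"]],
                 (1 - f[["F_CT"]]) * (1 - f[["F_SC"]]) * (1 - f[["F_IS"]]),
                 tolerance = 1e-9)
  }
})

test_that("negative variance components are reported, not truncated", {
  # panmictic data: group/population components fluctuate around zero,
  # so negative estimates must appear and percentages still sum to 100
  seen_negative <- FALSE
  for (seed in 1:10) {
    t <- simulate_genotype_table(n_per_site = c(A = 40, B = 40, C = 40, D = 40),
                                 n_loci = 6, F = 1e-4, F_IS = 0,
                                 seed = 5000 + seed)
    a <- amova(t, hierarchy = c(A = "G1", B = "G1", C = "G2", D = "G2"),
               n_perm = 0)
    if (any(a$table$variance_component < 0)) seen_negative <- TRUE
    expect_equal(sum(a$table$percent_of_total), 100, tolerance = 1e-9)
  }
  expect_true(seen_negative)
})

test_that("all F analogues are near zero for panmictic data", {
  fm <- vapply(1:20, function(i) {
    t <- simulate_genotype_table(n_per_site = c(A = 100, B = 100, C = 100,
                                                D = 100),
                                 n_loci = 8, F = 1e-4, F_IS = 0,
                                 seed = 9000 + i)
    amova(t, hierarchy = c(A = "G1", B = "G1", C = "G2", D = "G2"),
          n_perm = 0)$f_stats
  }, numeric(4))
  expect_true(all(abs(rowMeans(fm)) < 0.02))
})

test_that("single-group mode degrades gracefully and permutations work", {
  t <- simulate_genotype_table(n_per_site = c(A = 25, B = 25, C = 25),
                               n_loci = 6, F = 0.08, F_IS = 0.25, seed = 77)
  a <- amova(t, n_perm = 99, seed = 5)
  expect_true(is.na(a$f_stats[["F_CT"]]))
  expect_true(is.na(a$p_values[["F_CT"]]))
  expect_gt(a$f_stats[["F_SC"]], 0)   # plays the role of F_ST here
  expect_true(all(a$p_values[c("F_SC", "F_IS", "F_IT")] >= 1 / 100))
  # differentiated + inbred data: both tests should fire
  expect_lt(a$p_values[["F_SC"]], 0.05)
  expect_lt(a$p_values[["F_IS"]], 0.05)
  # all-identical genotypes is an error
  t0 <- genotype_table(paste0("s", 1:8), "L1", rep(1L, 8), rep(1L, 8),
                       rep(c("A", "B"), each = 4))
  expect_error(amova(t0, n_perm = 0), "zero total variance")
})
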