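test_that("Mantel r is 1 under affine transformation of the distances", {
  D1 <- random_distance_matrix(6, seed = 3)
  D2 <- 2 * D1 + 3
  diag(D2) <- 0
  m <- mantel_test(D1, D2, n_perm = 99, seed = 1)
  expect_equal(m$r, 1)
  expect_lte(m$p, 0.05)  # only relabelings reproducing D2 can tie r = 1
})

test_that("sampled permutation p agrees with exhaustive enumeration at n = 4", {
  D1 <- random_distance_matrix(4, seed = 8)
  D2 <- random_distance_matrix(4, seed = 9)
  # independent oracle: direct loop over all 4! = 24 relabelings
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4), ]
  ut <- upper.tri(D1)
  r_obs <- cor(D1[ut], D2[ut])
  rs <- apply(perms, 1, function(p) cor(D1[ut], D2[p, p][ut]))
  p_oracle <- mean(rs >= r_obs)
  m <- mantel_test(D1, D2, exhaustive = TRUE)
  expect_equal(m$p, p_oracle)
  expect_equal(m$n_permutations, 24)
  # large sampled run converges to the same value
  m2 <- mantel_test(D1, D2, n_perm = 9999, seed = 4)
  expect_equal(m2$p, p_oracle, tolerance = 0.05 / p_oracle)
})

test_that("Mantel p-values are uniform for independent matrices", {
  set.seed(7)
  ps <- vapply(1:400, function(i) {
    mantel_test(random_distance_matrix(8, seed = 2 * i),
                random_distance_matrix(8, seed = 2 * i + 1),
                n_perm = 99, seed = i)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("Mantel is deterministic by seed and invariant to joint relabeling", {
  D1 <- random_distance_matrix(7, seed = 1)
  D2 <- random_distance_matrix(7, seed = 2)
  m1 <- mantel_test(D1, D2, n_perm = 199, seed = 42)
  m2 <- mantel_test(D1, D2, n_perm = 199, seed = 42)
  expect_identical(m1$p, m2$p)
  ord <- c(3, 1, 7, 5, 2, 6, 4)
  m3 <- mantel_test(D1[ord, ord], D2[ord, ord], n_perm = 199, seed = 42)
  expect_equal(m3$r, m1$r)
  expect_error(mantel_test(D1, D2[ord, ord]), "share labels")
  Dc <- D1; Dc[upper.tri(Dc)] <- 1; Dc[lower.tri(Dc)] <- 1
  expect_error(mantel_test(D1, Dc), "zero-variance")
})

test_that("Mantel r and p agree with an independent implementation", {
  skip_if_not_installed("vegan")
  D1 <- random_distance_matrix(7, seed = 21)
  D2 <- 0.5 * D1 + random_distance_matrix(7, seed = 22)
  m <- mantel_test(D1, D2, n_perm = 999, seed = 5, tail = "greater")
  v <- vegan::mantel(stats::as.dist(D1), stats::as.dist(D2),
                     permutations = 999)
  expect_equal(m$r, unname(v$statistic), tolerance = 1e-12)
  expect_equal(m$p, v$signif, tolerance = 0.5 / v$signif)
})

test_that("the IBD suite tests each model and skips data-poor similarities", {
  # stepping-stone-like truth: genetic distance generated from geography
  geo <- site_geography(paste0("T", 1:6),
                        x_km = c(0, 10, 25, 40, 60, 85),
                        y_km = c(0, 5, -5, 10, 0, -10))
  em <- euclidean_matrix(geo)
  set.seed(10)
  theta <- 0.002 * em + matrix(stats::runif(36, 0, 0.01), 6, 6)
  theta <- (theta + t(theta)) / 2
  diag(theta) <- 0
  fst <- structure(list(sites = geo$site, theta = theta,
                        p = theta * NA, n_permutations = 0),
                   class = "fst_matrix")
  edges <- data.frame(from = "T1", to = paste0("T", 2:6), mode = "fluvial",
                      length_km = c(12, 28, 45, 66, 95))
  net <- transport_network(geo$site, edges,
                           gamma = c(large_barge = 0.71),
                           trips = data.frame(
                             vehicle_type = "large_barge",
                             from = "T1", to = paste0("T", 2:6),
                             n_trips = c(40L, 25L, 12L, 6L, 2L)))
  models <- list(euclidean = em,
                 fluvial_path = path_matrix(net, "fluvial"),
                 prpi = prpi_matrix(net))
  out <- ibd_suite(fst, models, n_perm = 499, seed = 3)
  # 6 sites -> choose(6,2) = 15 pairwise comparisons per model
  expect_equal(sum(out$scatter$model == "euclidean"), 15)
  eu <- out$results$euclidean
  expect_false(eu$test_skipped)
  expect_gt(eu$r, 0)
  expect_lt(eu$p, 0.05)
  # PrPI known only for hub pairs: 5 observations, no test
  pr <- out$results$prpi
  expect_true(pr$test_skipped)
  expect_equal(pr$n_pairs, 5)
  expect_true(is.na(pr$p))
})

test_that("collapsing sites reduces pair counts combinatorially", {
  t <- simulate_genotype_table(
    n_per_site = c(A = 10, B = 10, I1 = 10, I2 = 10, I3 = 10),
    n_loci = 3, seed = 6)
  tc <- collapse_sites(t, c("I1", "I2", "I3"), "I")
  expect_equal(nlevels(tc$site), 3L)
  expect_equal(sum(tc$site == "I"), 30)
  f <- pairwise_fst(tc, n_perm = 0)
  expect_equal(sum(upper.tri(f$theta)), choose(3, 2))
})
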