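two_pop_table <- function(n = 30, L = 8) {
  # two populations fixed for different alleles at every locus
  bind_tables(
    genotype_table(paste0("p", 1:n), paste0("L", 1:L),
                   matrix(1L, n, L), matrix(1L, n, L), rep("P", n)),
    genotype_table(paste0("q", 1:n), paste0("L", 1:L),
                   matrix(2L, n, L), matrix(2L, n, L), rep("Q", n)))
}

test_that("K = 1 is the degenerate model with Q exactly 1", {
  t <- simulate_genotype_table(n_per_site = c(A = 20), n_loci = 4, seed = 2)
  run <- gibbs_admixture(t, K = 1, burnin = 100, iters = 400, thin = 4,
                         seed = 3)
  expect_true(all(run$Q == 1))
  expect_equal(ncol(run$Q), 1L)
  # P rows are probability vectors
  for (p in run$P) expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
  expect_error(gibbs_admixture(t, K = 0), "K must be")
})

test_that("membership is recovered on fully separated populations", {
  # 12 loci of fixed differences: enough allele copies per individual that
  # the Dirichlet(alpha = 1) prior pull on Q stays below the 0.05 bound
  t <- two_pop_table(n = 30, L = 12)
  run <- gibbs_admixture(t, K = 2, burnin = 300, iters = 1500, thin = 5,
                         seed = 11)
  truth <- rbind(matrix(rep(c(1, 0), each = 30), 30, 2),
                 matrix(rep(c(0, 1), each = 30), 30, 2))
  ref <- structure(list(K = 2L, Q = truth, P = NULL),
                   class = "admixture_run")
  al <- align_labels(list(ref, run))
  expect_lt(mean(abs(al[[2]]$Q - truth)), 0.05)
  expect_equal(unname(rowSums(run$Q)), rep(1, 60), tolerance = 1e-9)
})

test_that("runs are bit-reproducible given the seed", {
  t <- simulate_genotype_table(n_per_site = c(A = 15, B = 15), n_loci = 4,
                               seed = 4)
  r1 <- gibbs_admixture(t, K = 2, burnin = 50, iters = 200, thin = 2, seed = 7)
  r2 <- gibbs_admixture(t, K = 2, burnin = 50, iters = 200, thin = 2, seed = 7)
  expect_identical(r1$loglik_trace, r2$loglik_trace)
  expect_identical(r1$Q, r2$Q)
})

test_that("lnPD penalises trace variance", {
  expect_equal(estimate_lnPD(rep(-100, 10)), -100)
  expect_equal(estimate_lnPD(c(-10, -12)), -12)  # mean -11, var 2
  base <- c(-50, -50, -50, -50)
  spread <- c(-48, -52, -48, -52)               # same mean, extra variance
  expect_lt(estimate_lnPD(spread), estimate_lnPD(base))
  expect_error(estimate_lnPD(numeric(0)), "empty trace")
})

test_that("Evanno Delta-K matches hand arithmetic and selects the elbow", {
  mk_run <- function(K, lnPD) structure(list(K = K, lnPD = lnPD),
                                        class = "admixture_run")
  # means L = (-500, -400, -390, -388); replicate pairs with sd(L(2)) = 2
  runs <- c(
    lapply(c(-501, -499), function(x) mk_run(1, x)),
    lapply(c(-400 - sqrt(2), -400 + sqrt(2)), function(x) mk_run(2, x)),
    lapply(c(-391, -389), function(x) mk_run(3, x)),
    lapply(c(-389, -387), function(x) mk_run(4, x)))
  ev <- evanno(runs)
  expect_equal(ev$mean_L, c(-500, -400, -390, -388))
  expect_equal(ev$L_prime, c(NA, 100, 10, 2))
  expect_equal(ev$L_doubleprime[2], abs(10 - 100))  # 90
  expect_equal(ev$deltaK[2], 90 / 2)                # 45
  expect_equal(attr(ev, "selected_K"), 2)
  # linear L(K): all second differences vanish
  lin <- unlist(lapply(1:4, function(K) {
    lapply(c(-1, 1), function(e) mk_run(K, -100 * K + 0.5 * e))
  }), recursive = FALSE)
  ev2 <- evanno(lin)
  expect_equal(ev2$L_doubleprime[2:3], c(0, 0))
  expect_equal(ev2$deltaK[2:3], c(0, 0))
  expect_error(evanno(runs[1:4]), "3 consecutive")
})

test_that("label alignment recovers permutations and tightens replicates", {
  sim <- simulate_admixed_table(K = 3, alpha = 0.2, n_individuals = 60,
                                n_loci = 12, seed = 15)
  run <- gibbs_admixture(sim$table, K = 3, burnin = 200, iters = 800,
                         thin = 4, seed = 21)
  al_self <- align_labels(list(run, run))
  expect_equal(attr(al_self[[2]]$Q, "perm"), 1:3)
  # swapped columns are recovered
  sw <- run
  perm <- c(3L, 1L, 2L)
  sw$Q <- run$Q[, perm]
  sw$P <- lapply(run$P, function(p) p[perm, , drop = FALSE])
  al <- align_labels(list(run, sw))
  expect_equal(al[[2]]$Q, run$Q, ignore_attr = TRUE)
  # alignment reduces across-run spread of Q
  runs <- lapply(1:4, function(s) {
    gibbs_admixture(sim$table, K = 3, burnin = 200, iters = 800, thin = 4,
                    seed = 30 + s)
  })
  spread <- function(rs) {
    qs <- lapply(rs, `[[`, "Q")
    mean(apply(simplify2array(qs), c(1, 2), stats::sd))
  }
  expect_lte(spread(align_labels(runs)), spread(runs))
  expect_error(align_labels(list(run, gibbs_admixture(sim$table, K = 2,
                                                      burnin = 50,
                                                      iters = 100, thin = 2,
                                                      seed = 1))),
               "differ in K")
})

test_that("dominant membership applies the 0.8 rule", {
  Q <- rbind(c(0.6, 0.4), c(1, 0), c(0.85, 0.15), c(0.1, 0.9))
  d <- dominant_membership(Q, c("X", "X", "Y", "Y"), threshold = 0.8)
  expect_equal(d$n_dominant, 3L)        # 0.6 is not dominant
  expect_equal(d$overall_fraction, 0.75)
  expect_equal(d$modal_cluster, 1L)
  expect_equal(d$per_site$frac_dominant, c(0.5, 1))
  expect_error(dominant_membership(Q, c("X", "X", "Y", "Y"), threshold = 1.2),
               "threshold")
  bad <- rbind(c(0.7, 0.7))
  expect_error(dominant_membership(bad, "X"), "sum to 1")
})

test_that("the likelihood is invariant to cluster label permutations", {
  sim <- simulate_admixed_table(K = 3, alpha = 0.3, n_individuals = 40,
                                n_loci = 8, seed = 44)
  run <- gibbs_admixture(sim$table, K = 3, burnin = 100, iters = 400,
                         thin = 4, seed = 45)
  ll <- admixture_loglik(sim$table, run$Q, run$P)
  perm <- c(2L, 3L, 1L)
  ll_perm <- admixture_loglik(sim$table, run$Q[, perm],
                              lapply(run$P, function(p) p[perm, ]))
  expect_equal(ll, ll_perm, tolerance = 1e-12)
})

test_that("the true K fits separated data better than K = 1", {
  t <- two_pop_table(n = 25, L = 10)
  r2 <- gibbs_admixture(t, K = 2, burnin = 200, iters = 800, thin = 4,
                        seed = 5)
  r1 <- gibbs_admixture(t, K = 1, burnin = 200, iters = 800, thin = 4,
                        seed = 5)
  expect_gt(admixture_loglik(t, r2$Q, r2$P), admixture_loglik(t, r1$Q, r1$P))
  expect_gt(r2$lnPD, r1$lnPD)
  expect_lte(r2$lnPD, max(r2$loglik_trace))
})

test_that("the interoperability export writes two rows per individual", {
  t <- simulate_genotype_table(n_per_site = c(A = 4, B = 3), n_loci = 3,
                               seed = 2)
  t$a1[1, 2] <- NA; t$a2[1, 2] <- NA
  t <- genotype_table(t$samples, t$loci, t$a1, t$a2, t$site)
  f <- withr::local_tempfile()
  write_structure_file(t, f)
  lines <- readLines(f)
  expect_length(lines, 2 * 7)
  first <- strsplit(lines[1], " ")[[1]]
  expect_length(first, 2 + 3)  # id, pop code, 3 loci
  expect_equal(strsplit(lines[1], " ")[[1]][4], "-9")
})
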