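#' Bayesian admixture clustering by Gibbs sampling
#'
#' Fits the admixture model with uncorrelated allele frequencies: each
#' individual i has admixture proportions `q_i ~ Dirichlet(alpha)` over K
#' clusters, each cluster k has independent allele-frequency vectors
#' `p_kl ~ Dirichlet(lambda)` at every locus l, and each observed allele
#' copy originates from cluster k with probability `q_ik * p_kl(a)`. The
#' Gibbs sweep alternates sampling copy origins, cluster allele
#' frequencies and admixture proportions; missing calls contribute nothing.
#' Returns posterior means of Q and P over the thinned post-burn-in draws,
#' the data log-likelihood trace, and the model log-probability estimate
#' `lnPD = mean(trace) - var(trace)/2`.
#'
#' Default chain lengths are desk-scale; `paper_protocol = TRUE` switches
#' to the heavy field protocol (1e5 burn-in, 2e5 iterations).
#'
#' @param t a [genotype_table()].
#' @param K number of clusters (>= 1).
#' @param burnin,iters,thin chain control.
#' @param alpha Dirichlet hyperparameter of the admixture proportions
#'   (fixed, not sampled).
#' @param lambda Dirichlet hyperparameter of the allele frequencies.
#' @param seed integer seed; runs are bit-reproducible given the seed.
#' @param paper_protocol use the heavy protocol chain lengths.
#' @return an `admixture_run`: `K, seed, alpha, lambda, Q, P,
#'   loglik_trace, lnPD`.
#' @export
gibbs_admixture <- function(t, K, burnin = 2000, iters = 10000,
                            thin = 10, alpha = 1.0, lambda = 1.0,
                            seed = 1L, paper_protocol = FALSE) {
  if (K < 1) stop("K must be >= 1")
  if (!n_samples(t)) stop("empty genotype table")
  if (paper_protocol) { burnin <- 1e5; iters <- 2e5 }
  # compact allele codes 1..A_l per locus
  a1 <- t$a1; a2 <- t$a2
  n_alleles <- integer(n_loci(t))
  for (l in seq_len(n_loci(t))) {
    alleles <- sort(unique(c(a1[, l], a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    n_alleles[l] <- max(1L, length(alleles))
    a1[, l] <- match(t$a1[, l], alleles)
    a2[, l] <- match(t$a2[, l], alleles)
  }
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  set.seed(seed)
  fit <- admixture_gibbs_cpp(a1, a2, n_alleles, as.integer(K),
                             as.integer(burnin), as.integer(iters),
                             as.integer(thin), alpha, lambda)
  Q <- fit$Q
  rownames(Q) <- t$samples
  structure(list(K = K, seed = seed, alpha = alpha, lambda = lambda,
                 Q = Q, P = fit$P, loglik_trace = fit$loglik_trace,
                 lnPD = estimate_lnPD(fit$loglik_trace),
                 site = t$site),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat(sprintf("<admixture_run> K = %d, %d individuals, lnPD = %.2f\n",
              x$K, nrow(x$Q), x$lnPD))
  invisible(x)
}

#' Model log-probability estimate from a log-likelihood trace
#'
#' The usual harmonic-style estimator used for cluster-number selection:
#' `lnPD = mean(trace) - var(trace)/2` (sample variance). Penalising the
#' mean by half the trace variance approximates the log model probability
#' under a normal assumption on the likelihood values.
#'
#' @param trace numeric log-likelihood trace (length >= 2).
#' @return scalar lnPD.
#' @export
estimate_lnPD <- function(trace) {
  if (length(trace) < 1) stop("empty trace")
  if (length(trace) == 1) return(trace)
  mean(trace) - stats::var(trace) / 2
}

#' Evanno Delta-K summary over replicate admixture runs
#'
#' Given replicate runs at consecutive K, computes per K the mean and sd
#' of lnPD, the first difference `L'(K) = L(K) - L(K-1)`, the absolute
#' second difference `|L''(K)| = |L'(K+1) - L'(K)|`, and
#' `DeltaK = |L''(K)| / sd(L(K))`. `selected_K` maximises DeltaK among the
#' interior K where it is defined (sd > 0).
#'
#' @param runs list of `admixture_run` objects spanning >= 3 consecutive K
#'   with >= 2 runs per K (single runs per K still yield L' and |L''|, but
#'   DeltaK needs replicate spread).
#' @return an `evanno_summary` data frame (`K, n_runs, mean_L, sd_L,
#'   L_prime, L_doubleprime, deltaK`) with attribute `selected_K`.
#' @export
evanno <- function(runs) {
  Ks <- vapply(runs, `[[`, 0, "K")
  L <- vapply(runs, `[[`, 0, "lnPD")
  ks <- sort(unique(Ks))
  if (length(ks) < 3) stop("need >= 3 consecutive K values")
  if (any(diff(ks) != 1)) stop("K values must be consecutive")
  mean_L <- vapply(ks, function(k) mean(L[Ks == k]), 0)
  sd_L <- vapply(ks, function(k) stats::sd(L[Ks == k]), 0)
  n_runs <- vapply(ks, function(k) sum(Ks == k), 0L)
  m <- length(ks)
  L_prime <- c(NA, diff(mean_L))                    # L'(K), defined from 2nd K
  L_dp <- rep(NA_real_, m)
  for (i in 2:(m - 1)) L_dp[i] <- abs(L_prime[i + 1] - L_prime[i])
  deltaK <- rep(NA_real_, m)
  for (i in 2:(m - 1)) {
    if (!is.na(sd_L[i]) && sd_L[i] > 0) deltaK[i] <- L_dp[i] / sd_L[i]
  }
  out <- data.frame(K = ks, n_runs = n_runs, mean_L = mean_L, sd_L = sd_L,
                    L_prime = L_prime, L_doubleprime = L_dp, deltaK = deltaK)
  sel <- if (all(is.na(deltaK))) NA_integer_ else ks[which.max(deltaK)]
  attr(out, "selected_K") <- sel
  class(out) <- c("evanno_summary", "data.frame")
  out
}

#' Align cluster labels across admixture runs
#'
#' Repairs label switching: for each run, finds the cluster permutation
#' maximising the total overlap `sum_i sum_k min(Q_ref[i,k], Q[i,perm(k)])`
#' with a reference run, by greedy assignment on the K x K overlap matrix
#' (always a bijection).
#'
#' @param runs list of `admixture_run` objects with equal K over the same
#'   individuals.
#' @param reference index of the reference run (default 1).
#' @return the runs, relabeled; each carries the permutation used as
#'   attribute `perm` on its `Q`.
#' @export
align_labels <- function(runs, reference = 1L) {
  K <- runs[[reference]]$K
  if (any(vapply(runs, `[[`, 0, "K") != K)) stop("runs differ in K")
  Qref <- runs[[reference]]$Q
  lapply(runs, function(run) {
    S <- matrix(0, K, K)
    for (k1 in seq_len(K)) for (k2 in seq_len(K)) {
      S[k1, k2] <- sum(pmin(Qref[, k1], run$Q[, k2]))
    }
    perm <- integer(K)   # perm[k1] = column of run matching ref cluster k1
    Sw <- S
    for (step in seq_len(K)) {
      ij <- which(Sw == max(Sw), arr.ind = TRUE)[1, ]
      perm[ij[1]] <- ij[2]
      Sw[ij[1], ] <- -Inf; Sw[, ij[2]] <- -Inf
    }
    run$Q <- run$Q[, perm, drop = FALSE]
    run$P <- lapply(run$P, function(p) p[perm, , drop = FALSE])
    attr(run$Q, "perm") <- perm
    run
  })
}

#' Dominant-membership summary of a Q matrix
#'
#' An individual is "dominant" when its largest membership coefficient
#' exceeds `threshold`. Reports the overall fraction of dominant
#' individuals, the overall modal cluster (the cluster that is the argmax
#' for the most individuals), the fraction of individuals dominant *to the
#' modal cluster*, and per-site fractions of individuals dominant to the
#' site's own modal cluster and to the overall modal cluster.
#'
#' @param Q membership matrix (rows sum to 1).
#' @param site_of factor/character of site labels per individual.
#' @param threshold dominance cutoff in (0, 1); default 0.8.
#' @return list: `overall_fraction`, `modal_cluster`,
#'   `modal_cluster_fraction`, `n_dominant`, `n_total`, `per_site` (data
#'   frame).
#' @export
dominant_membership <- function(Q, site_of, threshold = 0.8) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must lie in (0, 1)")
  if (any(abs(rowSums(Q) - 1) > 1e-6)) stop("Q rows must sum to 1")
  site_of <- factor(site_of)
  top <- apply(Q, 1, which.max)
  qmax <- Q[cbind(seq_len(nrow(Q)), top)]
  dominant <- qmax > threshold
  modal <- as.integer(names(which.max(table(top))))
  per_site <- do.call(rbind, lapply(levels(site_of), function(s) {
    idx <- site_of == s
    site_modal <- as.integer(names(which.max(table(top[idx]))))
    data.frame(site = s, n = sum(idx),
               modal_cluster = site_modal,
               frac_dominant = mean(dominant[idx]),
               frac_dominant_site_modal =
                 mean(dominant[idx] & top[idx] == site_modal),
               frac_dominant_overall_modal =
                 mean(dominant[idx] & top[idx] == modal))
  }))
  list(overall_fraction = mean(dominant),
       modal_cluster = modal,
       modal_cluster_fraction = mean(dominant & top == modal),
       n_dominant = sum(dominant), n_total = nrow(Q),
       per_site = per_site)
}

#' Data log-likelihood of a genotype table under given Q and P
#'
#' Evaluates `sum log(sum_k q_ik p_kl(a))` over all non-missing allele
#' copies; used for model comparison and invariance checks.
#'
#' @param t a [genotype_table()].
#' @param Q membership matrix.
#' @param P list of per-locus K x A allele-frequency matrices (allele
#'   columns follow the sorted distinct alleles at each locus).
#' @return scalar log-likelihood.
#' @export
admixture_loglik <- function(t, Q, P) {
  ll <- 0
  for (l in seq_len(n_loci(t))) {
    alleles <- sort(unique(c(t$a1[, l], t$a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    for (copy in list(t$a1[, l], t$a2[, l])) {
      a <- match(copy, alleles)
      keep <- which(!is.na(a))
      if (!length(keep)) next
      probs <- rowSums(Q[keep, , drop = FALSE] *
                         t(P[[l]])[a[keep], , drop = FALSE])
      ll <- ll + sum(log(pmax(probs, 1e-300)))
    }
  }
  ll
}

#' Replicate admixture runs over a range of K
#'
#' @param t a [genotype_table()].
#' @param K_range integer vector of K values (must be consecutive).
#' @param n_runs replicate runs per K.
#' @param seed base seed; run (K, r) uses `seed + 1000*K + r`.
#' @param ... passed to [gibbs_admixture()].
#' @return flat list of `admixture_run` objects.
#' @export
admixture_sweep <- function(t, K_range = 1:6, n_runs = 3, seed = 1L, ...) {
  runs <- list()
  for (K in K_range) for (r in seq_len(n_runs)) {
    runs[[length(runs) + 1L]] <-
      gibbs_admixture(t, K, seed = seed + 1000L * K + r, ...)
  }
  runs
}

#' Write genotypes in the one-row-per-allele-copy interoperability format
#'
#' Two rows per individual (one per allele copy), integer allele labels,
#' `-9` for missing — the layout expected by the classic clustering
#' program.
#'
#' @param t a [genotype_table()].
#' @param path output path.
#' @export
write_structure_file <- function(t, path) {
  con <- file(path, "w")
  on.exit(close(con))
  popcode <- as.integer(t$site)
  for (i in seq_len(n_samples(t))) {
    for (m in c("a1", "a2")) {
      row <- t[[m]][i, ]
      row[is.na(row)] <- -9L
      writeLines(paste(c(t$samples[i], popcode[i], row), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Q-matrix TSV (individual, site, q_1..q_K)
#' @param run an `admixture_run`.
#' @param path output path.
#' @export
write_q_matrix <- function(run, path) {
  df <- data.frame(individual = rownames(run$Q),
                   site = as.character(run$site))
  for (k in seq_len(run$K)) df[[paste0("q_", k)]] <- run$Q[, k]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
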