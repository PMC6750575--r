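#' Conditional probability of a genotype array given its allele counts
#'
#' Levene's distribution: for `n` diploid individuals with genotype counts
#' `n_ij` and implied allele counts `n_i` (total `2n` gene copies), the
#' probability of the array under Hardy-Weinberg equilibrium, conditional on
#' the allele counts, is
#' `P = n! * prod(n_i!) * 2^H / ((2n)! * prod(n_ij!))`,
#' with `H` the number of heterozygous individuals. This is the reference
#' distribution of the exact test.
#'
#' @param counts genotype counts: either a named numeric vector with names
#'   `"i/j"` (`i <= j` allele labels) or a symmetric-storage matrix as
#'   produced by [genotype_count_matrix()].
#' @param log return the log probability.
#' @return probability in (0, 1\].
#' @export
genotype_array_probability <- function(counts, log = FALSE) {
  cm <- .as_pair_counts(counts)
  n <- sum(cm$count)
  if (n == 0) stop("empty genotype array")
  k <- max(cm$j)
  ni <- numeric(k)
  for (r in seq_len(nrow(cm))) {
    ni[cm$i[r]] <- ni[cm$i[r]] + cm$count[r]
    ni[cm$j[r]] <- ni[cm$j[r]] + cm$count[r]
  }
  H <- sum(cm$count[cm$i != cm$j])
  lp <- lgamma(n + 1) + sum(lgamma(ni + 1)) + H * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(cm$count + 1))
  if (log) lp else exp(lp)
}

.as_pair_counts <- function(counts) {
  if (is.matrix(counts)) {
    k <- nrow(counts)
    ij <- which(upper.tri(counts, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(i = ij[, 1], j = ij[, 2],
                     count = counts[upper.tri(counts, diag = TRUE)])
  } else {
    nm <- strsplit(names(counts), "/", fixed = TRUE)
    if (any(lengths(nm) != 2)) stop("genotype names must be 'i/j'")
    i <- as.integer(vapply(nm, `[`, "", 1))
    j <- as.integer(vapply(nm, `[`, "", 2))
    df <- data.frame(i = pmin(i, j), j = pmax(i, j),
                     count = as.numeric(counts))
  }
  if (any(df$count < 0) || any(df$count != round(df$count))) {
    stop("inconsistent genotype counts")
  }
  df[df$count > 0, , drop = FALSE]
}

#' Genotype count matrix at one site and locus
#'
#' @inheritParams allele_frequencies
#' @return a `k x k` matrix of genotype counts over the distinct alleles
#'   present (counts stored in the upper triangle, `i <= j` after mapping
#'   alleles to their rank); attribute `alleles` holds the allele labels.
#' @export
genotype_count_matrix <- function(t, site, locus) {
  idx <- which(t$site == site)
  j <- match(locus, t$loci)
  a1 <- t$a1[idx, j]; a2 <- t$a2[idx, j]
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  m <- matrix(0L, k, k)
  if (k) {
    r1 <- match(a1, alleles); r2 <- match(a2, alleles)
    for (i in seq_along(r1)) {
      a <- min(r1[i], r2[i]); b <- max(r1[i], r2[i])
      m[a, b] <- m[a, b] + 1L
    }
  }
  attr(m, "alleles") <- alleles
  m
}

# enumerate all genotype arrays with the given allele counts; calls
# fun(count_matrix) for each.  ni = allele copy counts (sum even).
.enumerate_arrays <- function(ni, fun) {
  k <- length(ni)
  pairs <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  m <- matrix(0L, k, k)
  recurse <- function(p, rem) {
    if (p > nrow(pairs)) {
      if (all(rem == 0)) fun(m)
      return(invisible())
    }
    i <- pairs[p, 1]; j <- pairs[p, 2]
    cap <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (c in 0:cap) {
      m[i, j] <<- c
      rem2 <- rem
      rem2[i] <- rem2[i] - c
      rem2[j] <- rem2[j] - c
      # feasibility: copies remaining must be assignable by later pairs
      recurse(p + 1L, rem2)
      m[i, j] <<- 0L
    }
  }
  recurse(1L, ni)
  invisible()
}

#' Exact Hardy-Weinberg test by full enumeration
#'
#' Enumerates every genotype array with the observed allele counts and sums
#' the Levene probabilities of arrays no more probable than the observed one
#' (two-sided exact test in the conditional-probability ordering). Intended
#' for small problems (the default guard refuses > 4 alleles or > 25
#' individuals); it is also the oracle against which the Markov-chain engine
#' is validated.
#'
#' @inheritParams allele_frequencies
#' @param max_alleles,max_n guard rails for the enumeration.
#' @return a `hwe_result` list: `site, locus, p_value, engine, mc_se,
#'   chain_steps, dememorization_steps`.
#' @export
hwe_exact_enumeration <- function(t, site, locus,
                                  max_alleles = 4L, max_n = 25L) {
  m <- genotype_count_matrix(t, site, locus)
  k <- nrow(m); n <- sum(m)
  if (n == 0) stop("no data at (", site, ", ", locus, ")")
  if (k > max_alleles || n > max_n) {
    stop("enumeration bound exceeded (", k, " alleles, ", n,
         " individuals); use hwe_exact_mcmc()")
  }
  if (k <= 1) {
    return(.hwe_result(site, locus, 1, "enumeration"))
  }
  ni <- .allele_copy_counts(m)
  lp_obs <- genotype_array_probability(m, log = TRUE)
  tol <- .hwe_tie_tol(lp_obs)
  acc <- 0
  .enumerate_arrays(ni, function(arr) {
    lp <- genotype_array_probability(arr, log = TRUE)
    if (lp <= lp_obs + tol) acc <<- acc + exp(lp)
  })
  .hwe_result(site, locus, min(acc, 1), "enumeration")
}

# tie tolerance for "probability <= observed" comparisons, on the log
# scale and proportional to the magnitude of the observed log-probability:
# distinct probability classes of small arrays are separated by far more
# than this, while genuinely tied classes computed along different
# arithmetic paths agree to well within it
.hwe_tie_tol <- function(lp_obs) 1e-9 * (1 + abs(lp_obs))

.allele_copy_counts <- function(m) {
  k <- nrow(m)
  ni <- integer(k)
  for (i in seq_len(k)) for (j in i:k) {
    ni[i] <- ni[i] + m[i, j]
    ni[j] <- ni[j] + m[i, j]
  }
  ni
}

.hwe_result <- function(site, locus, p, engine, mc_se = 0,
                        steps = 0L, burnin = 0L) {
  structure(list(site = site, locus = locus, p_value = p, engine = engine,
                 mc_se = mc_se, chain_steps = steps,
                 dememorization_steps = burnin),
            class = "hwe_result")
}

#' Exact Hardy-Weinberg test by Markov chain Monte Carlo
#'
#' A random-pairing chain over genotype arrays with fixed allele counts:
#' the `2n` observed gene copies are kept as an explicit pairing into `n`
#' individuals, and each step proposes swapping two copies between two
#' individuals (the classic two-genotype partner switch). The uniform
#' distribution over pairings induces exactly the Levene conditional
#' distribution over arrays, and the swap proposal is symmetric, so every
#' proposal is accepted. The p-value is the fraction of post-burn-in states
#' whose array probability does not exceed the observed one. A batch-means
#' Monte Carlo standard error is reported.
#'
#' @inheritParams allele_frequencies
#' @param steps Markov chain steps after burn-in (field-protocol default
#'   1e6).
#' @param burnin dememorization steps (default 1e5).
#' @param seed integer seed; the chain is bit-reproducible given the seed.
#' @return a `hwe_result` (see [hwe_exact_enumeration()]).
#' @export
hwe_exact_mcmc <- function(t, site, locus, steps = 1e6, burnin = 1e5,
                           seed = 1L) {
  m <- genotype_count_matrix(t, site, locus)
  k <- nrow(m); n <- sum(m)
  if (n == 0) stop("no data at (", site, ", ", locus, ")")
  if (k <= 1) {
    return(.hwe_result(site, locus, 1, "mcmc", 0, as.integer(steps),
                       as.integer(burnin)))
  }
  # explicit copy layout: individuals in sequence, each two copies
  ij <- which(upper.tri(m, diag = TRUE) & m > 0, arr.ind = TRUE)
  c1 <- integer(0); c2 <- integer(0)
  for (r in seq_len(nrow(ij))) {
    cnt <- m[ij[r, 1], ij[r, 2]]
    c1 <- c(c1, rep.int(ij[r, 1], cnt))
    c2 <- c(c2, rep.int(ij[r, 2], cnt))
  }
  lp_obs <- genotype_array_probability(m, log = TRUE)
  set.seed(seed)
  res <- hwe_swap_chain(c1, c2, k, as.integer(steps), as.integer(burnin),
                        lp_obs + .hwe_tie_tol(lp_obs))
  p <- res$p_hat
  .hwe_result(site, locus, p, "mcmc", res$mc_se, as.integer(steps),
              as.integer(burnin))
}

#' Sidak family-wise correction threshold
#'
#' Per-test significance level giving family-wise level `alpha` over `m`
#' independent tests: `1 - (1 - alpha)^(1/m)`.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests, >= 1.
#' @return per-test threshold.
#' @examples
#' sidak_threshold(0.05, 72)  # 0.00071 at 5 dp
#' @export
sidak_threshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  1 - (1 - alpha)^(1 / m)
}

#' Hardy-Weinberg tests for every (site, locus) cell
#'
#' Runs the enumeration engine where it is feasible (small arrays) and the
#' Markov-chain engine elsewhere, then applies a Sidak correction across all
#' testable cells.
#'
#' @param t a [genotype_table()].
#' @param steps,burnin Markov-chain lengths for the MCMC engine.
#' @param alpha family-wise significance level.
#' @param n_tests_override use this `m` in the Sidak correction instead of
#'   the number of cells tested (some workflows count monomorphic cells).
#' @param seed base seed; each cell uses `seed + cell index`.
#' @return data frame: `site, locus, p_value, engine, mc_se,
#'   significant_after_sidak`.
#' @export
hwe_table <- function(t, steps = 1e5, burnin = 1e4, alpha = 0.05,
                      n_tests_override = NULL, seed = 1L) {
  rows <- list()
  cell <- 0L
  for (s in sites(t)) for (l in t$loci) {
    cell <- cell + 1L
    m <- genotype_count_matrix(t, s, l)
    if (sum(m) == 0) next
    # auto-switch: full enumeration only where its array space is small
    # (4-allele spaces explode combinatorially well before n = 25)
    r <- if (nrow(m) <= 3 && sum(m) <= 25) {
      hwe_exact_enumeration(t, s, l)
    } else {
      hwe_exact_mcmc(t, s, l, steps = steps, burnin = burnin,
                     seed = seed + cell)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      site = s, locus = l, p_value = r$p_value, engine = r$engine,
      mc_se = r$mc_se)
  }
  out <- do.call(rbind, rows)
  m_tests <- if (is.null(n_tests_override)) nrow(out) else n_tests_override
  thr <- sidak_threshold(alpha, m_tests)
  out$significant_after_sidak <- out$p_value < thr
  attr(out, "sidak_threshold") <- thr
  attr(out, "n_tests") <- m_tests
  out
}
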