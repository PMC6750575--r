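# shared fixture builders (everything generated in code; no data files)

# genotype table holding a single site's genotype array, from a count matrix
# (upper triangle: counts of unordered allele pairs i <= j)
table_from_counts <- function(m, site = "A") {
  k <- nrow(m)
  a1 <- integer(0); a2 <- integer(0)
  for (i in 1:k) for (j in i:k) {
    if (m[i, j] > 0) {
      a1 <- c(a1, rep(i, m[i, j]))
      a2 <- c(a2, rep(j, m[i, j]))
    }
  }
  genotype_table(paste0("s", seq_along(a1)), "L1", a1, a2,
                 rep(site, length(a1)))
}

# all distinct genotype arrays with <= `k_max` alleles and exactly n
# individuals, as a list of count matrices
all_arrays <- function(n, k_max = 3) {
  cats <- expand.grid(rep(list(0:n), k_max * (k_max + 1) / 2))
  cats <- cats[rowSums(cats) == n, , drop = FALSE]
  ij <- which(upper.tri(diag(k_max), diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 2], ij[, 1]), , drop = FALSE]  # expand.grid order
  lapply(seq_len(nrow(cats)), function(r) {
    m <- matrix(0L, k_max, k_max)
    for (c in seq_len(nrow(ij))) m[ij[c, 1], ij[c, 2]] <- as.integer(cats[r, c])
    m
  })
}

# tiny labelled symmetric matrix from a coordinate cloud
random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  m <- as.matrix(stats::dist(matrix(stats::rnorm(2 * n), n, 2)))
  dimnames(m) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  m
}

# independent brute-force AMOVA oracle: explicit sums of allele-identity
# distances over gene copies, one locus, complete data
brute_amova_ss <- function(a1, a2, pop, grp_of_pop) {
  copies <- c(a1, a2)
  cpop <- c(pop, pop)
  cgrp <- grp_of_pop[cpop]
  ind <- c(seq_along(a1), seq_along(a1))
  dsum <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) s <- s + (copies[i] != copies[j])
    s / 2  # each unordered pair counted once
  }
  ss_set <- function(idx) dsum(idx) / length(idx)
  all_idx <- seq_along(copies)
  ss_total <- ss_set(all_idx)
  ss_wg <- sum(vapply(unique(cgrp), function(g) ss_set(all_idx[cgrp == g]), 0))
  ss_wp <- sum(vapply(unique(cpop), function(p) ss_set(all_idx[cpop == p]), 0))
  ss_wi <- sum(vapply(unique(ind), function(i) ss_set(all_idx[ind == i]), 0))
  c(ag = ss_total - ss_wg, ap = ss_wg - ss_wp, ai = ss_wp - ss_wi,
    wi = ss_wi)
}

# two-site table fixed for different alleles at every locus
fixed_difference_table <- function(n = 10, L = 2) {
  bind_tables(
    genotype_table(paste0("a", 1:n), paste0("L", 1:L),
                   matrix(1L, n, L), matrix(1L, n, L), rep("A", n)),
    genotype_table(paste0("b", 1:n), paste0("L", 1:L),
                   matrix(2L, n, L), matrix(2L, n, L), rep("B", n)))
}
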