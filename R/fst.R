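#' Multilocus Weir-Cockerham theta for two populations
#'
#' Variance-component estimator of F_ST (Weir & Cockerham's theta) for a
#' pair of populations, combining loci and alleles by the ratio-of-sums
#' rule: the among-population (`a`) components are summed over every allele
#' at every locus, likewise the total (`a + b + c`) components, and the
#' ratio of the two sums is returned. Monomorphic loci contribute zero to
#' both sums.
#'
#' @param a1x,a2x,a1y,a2y integer allele matrices (individuals x loci) for
#'   the two populations (`NA` = missing call).
#' @return theta estimate (`NaN` when no locus is polymorphic across the
#'   pair).
#' @keywords internal
theta_pair <- function(a1x, a2x, a1y, a2y) {
  num <- 0; den <- 0
  L <- ncol(a1x)
  for (j in seq_len(L)) {
    comp <- .wc_components_locus(a1x[, j], a2x[, j], a1y[, j], a2y[, j])
    num <- num + comp[1]
    den <- den + comp[2]
  }
  num / den
}

# Weir-Cockerham (1984) a, a+b+c sums over alleles at one locus, r = 2 pops
.wc_components_locus <- function(x1, x2, y1, y2) {
  kx <- !is.na(x1); ky <- !is.na(y1)
  n1 <- sum(kx); n2 <- sum(ky)
  if (n1 < 1 || n2 < 1) return(c(0, 0))
  alleles <- sort(unique(c(x1[kx], x2[kx], y1[ky], y2[ky])))
  if (length(alleles) < 2) return(c(0, 0))
  r <- 2
  nbar <- (n1 + n2) / 2
  if (nbar <= 1) return(c(0, 0))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  num <- 0; den <- 0
  for (al in alleles) {
    p1 <- (sum(x1[kx] == al) + sum(x2[kx] == al)) / (2 * n1)
    p2 <- (sum(y1[ky] == al) + sum(y2[ky] == al)) / (2 * n2)
    h1 <- sum((x1[kx] == al) != (x2[kx] == al)) / n1
    h2 <- sum((y1[ky] == al) != (y2[ky] == al)) / n2
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  c(num, den)
}

#' Pairwise F_ST matrix with permutation significance
#'
#' Computes multilocus Weir-Cockerham theta for every site pair and, when
#' `n_perm > 0`, a permutation p-value per pair obtained by shuffling
#' individuals between the two sites (site sizes fixed) and counting
#' permuted thetas at least as large as the observed one, with add-one
#' smoothing: `p = (count + 1) / (n_perm + 1)`.
#'
#' @param t a [genotype_table()] with at least two sites.
#' @param n_perm permutations per pair (field-protocol default 10000; 0
#'   skips the test and leaves `p` as `NA`).
#' @param seed integer seed for the permutations.
#' @return an object of class `fst_matrix`: list with `sites`, `theta`
#'   (symmetric, zero diagonal; `NA` for pairs with no shared polymorphic
#'   locus), `p` (same shape) and `n_permutations`.
#' @export
pairwise_fst <- function(t, n_perm = 10000, seed = 1L) {
  sl <- sites(t)
  if (length(sl) < 2) stop("need at least two sites")
  if (any(tabulate(t$site) < 2)) stop("every site needs >= 2 individuals")
  k <- length(sl)
  th <- matrix(0, k, k, dimnames = list(sl, sl))
  pv <- matrix(NA_real_, k, k, dimnames = list(sl, sl))
  set.seed(seed)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ix <- which(t$site == sl[i]); iy <- which(t$site == sl[j])
    obs <- theta_pair(t$a1[ix, , drop = FALSE], t$a2[ix, , drop = FALSE],
                      t$a1[iy, , drop = FALSE], t$a2[iy, , drop = FALSE])
    th[i, j] <- th[j, i] <- obs
    if (n_perm > 0 && is.finite(obs)) {
      pool <- c(ix, iy); nx <- length(ix)
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        sh <- sample(pool)
        px <- sh[seq_len(nx)]; py <- sh[-seq_len(nx)]
        tp <- theta_pair(t$a1[px, , drop = FALSE], t$a2[px, , drop = FALSE],
                         t$a1[py, , drop = FALSE], t$a2[py, , drop = FALSE])
        if (is.finite(tp) && tp >= obs) cnt <- cnt + 1L
      }
      pv[i, j] <- pv[j, i] <- (cnt + 1) / (n_perm + 1)
    }
  }
  structure(list(sites = sl, theta = th, p = pv, n_permutations = n_perm),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("<fst_matrix> ", length(x$sites), " sites, ",
      x$n_permutations, " permutations\n", sep = "")
  print(round(x$theta, 4))
  invisible(x)
}

#' Write a pairwise F_ST matrix as a lower-triangle TSV
#'
#' Layout mirrors the conventional pairwise-F_ST table: lower triangle of
#' estimates with `*` marking pairs significant at `alpha`.
#'
#' @param fst an `fst_matrix` from [pairwise_fst()].
#' @param path output path.
#' @param alpha significance level for the stars.
#' @export
write_fst_matrix <- function(fst, path, alpha = 0.05) {
  k <- length(fst$sites)
  m <- matrix("", k, k, dimnames = list(fst$sites, fst$sites))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j < i) {
      star <- if (!is.na(fst$p[i, j]) && fst$p[i, j] < alpha) "*" else ""
      m[i, j] <- paste0(signif(fst$theta[i, j], 5), star)
    } else if (i == j) m[i, j] <- "0"
  }
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
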