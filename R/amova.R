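#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Four-level nested AMOVA on diploid gene copies under the allele-identity
#' distance (0 for identical allele labels, 1 otherwise): variation is
#' partitioned among groups, among populations within groups, among
#' individuals within populations, and within individuals. Sums of squares
#' are computed per locus (individuals missing at a locus are excluded from
#' that locus only) and summed; variance components follow from the nested
#' expected-mean-square equations with unequal-size coefficients. Negative
#' components are reported as estimated, never truncated.
#'
#' F-statistic analogues: `F_CT = s2_a/s2_T` (among groups),
#' `F_SC = s2_b/(s2_b+s2_c+s2_d)` (among populations within groups),
#' `F_IS = s2_c/(s2_c+s2_d)` (among individuals within populations) and
#' `F_IT = (s2_a+s2_b+s2_c)/s2_T`, which satisfy
#' `(1-F_IT) = (1-F_CT)(1-F_SC)(1-F_IS)` identically.
#'
#' Permutation significance: populations are permuted among groups for
#' `F_CT`; individuals among populations within groups for `F_SC`; gene
#' copies among individuals within populations for `F_IS`; and gene copies
#' among individuals across the whole sample for `F_IT`. P-values use
#' add-one smoothing.
#'
#' With a single group (or `hierarchy = NULL` and no group map on the
#' table) the among-groups level is degenerate: its component is 0 and
#' `F_CT` is `NA`; `F_SC` is then the ordinary `F_ST`.
#'
#' @param t a [genotype_table()]; sites are the populations.
#' @param hierarchy named character vector mapping site labels to group
#'   labels; defaults to `t$group`, else all sites in one group.
#' @param n_perm permutations per statistic (0 skips the tests).
#' @param seed integer seed for the permutations.
#' @return an `amova_result`: data frame `table` (df, sum_of_squares,
#'   variance_component, percent_of_total per level), named numerics
#'   `f_stats` and `p_values`.
#' @export
amova <- function(t, hierarchy = NULL, n_perm = 10000, seed = 1L) {
  if (is.null(hierarchy)) hierarchy <- t$group
  sl <- sites(t)
  if (is.null(hierarchy)) {
    hierarchy <- stats::setNames(rep("all", length(sl)), sl)
  }
  if (!all(sl %in% names(hierarchy))) {
    stop("hierarchy must map every site: missing ",
         paste(setdiff(sl, names(hierarchy)), collapse = ", "))
  }
  popi <- as.integer(t$site)
  grp_of_pop <- as.integer(factor(hierarchy[sl]))
  fit <- .amova_core(t$a1, t$a2, popi, grp_of_pop)
  if (!is.finite(fit$sigma_total) || fit$sigma_total == 0) {
    stop("zero total variance: all genotypes identical")
  }

  pv <- c(F_CT = NA_real_, F_SC = NA_real_, F_IS = NA_real_,
          F_IT = NA_real_)
  if (n_perm > 0) {
    set.seed(seed)
    n_pop <- length(sl)
    multi_group <- length(unique(grp_of_pop)) > 1
    cnt <- c(0L, 0L, 0L, 0L)
    for (b in seq_len(n_perm)) {
      if (multi_group) {
        f1 <- .amova_core(t$a1, t$a2, popi, sample(grp_of_pop))
        if (is.finite(f1$f["F_CT"]) && f1$f["F_CT"] >= fit$f["F_CT"])
          cnt[1] <- cnt[1] + 1L
      }
      # individuals among populations within groups
      popi2 <- popi
      for (g in unique(grp_of_pop)) {
        members <- which(popi %in% which(grp_of_pop == g))
        popi2[members] <- sample(popi[members])
      }
      f2 <- .amova_core(t$a1, t$a2, popi2, grp_of_pop)
      if (is.finite(f2$f["F_SC"]) && f2$f["F_SC"] >= fit$f["F_SC"])
        cnt[2] <- cnt[2] + 1L
      # gene copies among individuals within populations
      rp <- .repair_copies(t$a1, t$a2, within = popi)
      f3 <- .amova_core(rp$a1, rp$a2, popi, grp_of_pop)
      if (is.finite(f3$f["F_IS"]) && f3$f["F_IS"] >= fit$f["F_IS"])
        cnt[3] <- cnt[3] + 1L
      # gene copies among individuals across the whole sample
      rp <- .repair_copies(t$a1, t$a2, within = rep(1L, nrow(t$a1)))
      f4 <- .amova_core(rp$a1, rp$a2, popi, grp_of_pop)
      if (is.finite(f4$f["F_IT"]) && f4$f["F_IT"] >= fit$f["F_IT"])
        cnt[4] <- cnt[4] + 1L
    }
    pv <- (cnt + 1) / (n_perm + 1)
    names(pv) <- c("F_CT", "F_SC", "F_IS", "F_IT")
    if (!multi_group) pv["F_CT"] <- NA_real_
  }

  tab <- data.frame(
    level = c("among_groups", "among_populations_within_groups",
              "among_individuals_within_populations", "within_individuals"),
    df = fit$df,
    sum_of_squares = fit$ss,
    variance_component = fit$sigma,
    percent_of_total = 100 * fit$sigma / fit$sigma_total
  )
  structure(list(table = tab, f_stats = fit$f, p_values = pv,
                 n_permutations = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  print(x$table, row.names = FALSE)
  f <- x$f_stats
  for (nm in names(f)) {
    cat(sprintf("  %s = %s  (p = %s)\n", nm,
                format(round(f[[nm]], 5)),
                format(x$p_values[[nm]], digits = 3)))
  }
  invisible(x)
}

# per-locus pooled copies re-pairing within the given strata
.repair_copies <- function(a1, a2, within) {
  for (l in seq_len(ncol(a1))) {
    keep <- which(!is.na(a1[, l]))
    for (g in unique(within[keep])) {
      idx <- keep[within[keep] == g]
      if (length(idx) < 2) next
      copies <- sample(c(a1[idx, l], a2[idx, l]))
      m <- length(idx)
      a1[idx, l] <- copies[seq_len(m)]
      a2[idx, l] <- copies[m + seq_len(m)]
    }
  }
  list(a1 = a1, a2 = a2)
}

# Nested sums of squares, EMS coefficients and variance components.
# popi: population index per individual; grp_of_pop: group index per pop.
.amova_core <- function(a1, a2, popi, grp_of_pop) {
  L <- ncol(a1)
  ss <- c(ag = 0, ap = 0, ai = 0, wi = 0)
  df <- c(ag = 0, ap = 0, ai = 0, wi = 0)
  d_c3 <- 0; d_c4 <- 0; d_c5 <- 0   # sum over loci of df * coefficient
  for (l in seq_len(L)) {
    keep <- which(!is.na(a1[, l]))
    if (length(keep) < 2) next
    x1 <- a1[keep, l]; x2 <- a2[keep, l]
    p <- popi[keep]
    g <- grp_of_pop[p]
    pops <- sort(unique(p)); groups <- sort(unique(grp_of_pop[pops]))
    I <- length(keep); P <- length(pops); G <- length(groups)

    ss_of <- function(alleles) {
      m <- length(alleles)
      if (m == 0) return(0)
      cnt <- table(alleles)
      ((m^2 - sum(cnt^2)) / 2) / m
    }
    copies <- c(x1, x2)
    cpop <- c(p, p); cgrp <- c(g, g)
    ss_tot <- ss_of(copies)
    ss_wg <- sum(vapply(groups, function(gg) ss_of(copies[cgrp == gg]), 0))
    ss_wp <- sum(vapply(pops, function(pp) ss_of(copies[cpop == pp]), 0))
    ss_wi <- sum(x1 != x2) / 2

    ss["ag"] <- ss["ag"] + (ss_tot - ss_wg)
    ss["ap"] <- ss["ap"] + (ss_wg - ss_wp)
    ss["ai"] <- ss["ai"] + (ss_wp - ss_wi)
    ss["wi"] <- ss["wi"] + ss_wi

    df_l <- c(ag = G - 1, ap = P - G, ai = I - P, wi = I)
    df <- df + df_l

    # copy-count coefficients for the unequal-size EMS equations
    Nc <- 2 * I
    Ncp <- 2 * tabulate(match(p, pops), nbins = P)
    Ncg <- 2 * vapply(groups, function(gg) sum(p %in% pops[grp_of_pop[pops] == gg]), 0)
    sum_p2_g <- vapply(seq_along(groups), function(gi) {
      pp <- pops[grp_of_pop[pops] == groups[gi]]
      sum(Ncp[match(pp, pops)]^2) / Ncg[gi]
    }, 0)
    if (P > G) {
      c3 <- (sum(Ncg) - sum(sum_p2_g)) / (P - G)
      d_c3 <- d_c3 + df_l[["ap"]] * c3
    }
    if (G > 1) {
      c4 <- (sum(sum_p2_g) - sum(Ncp^2) / Nc) / (G - 1)
      c5 <- (Nc - sum(Ncg^2) / Nc) / (G - 1)
      d_c4 <- d_c4 + df_l[["ag"]] * c4
      d_c5 <- d_c5 + df_l[["ag"]] * c5
    }
  }

  sigma_d <- if (df["wi"] > 0) ss[["wi"]] / df[["wi"]] else NaN
  sigma_c <- if (df["ai"] > 0) (ss[["ai"]] / df[["ai"]] - sigma_d) / 2 else 0
  sigma_b <- if (df["ap"] > 0 && d_c3 > 0) {
    (ss[["ap"]] - df[["ap"]] * (sigma_d + 2 * sigma_c)) / d_c3
  } else 0
  sigma_a <- if (df["ag"] > 0 && d_c5 > 0) {
    (ss[["ag"]] - df[["ag"]] * (sigma_d + 2 * sigma_c) - d_c4 * sigma_b) / d_c5
  } else 0
  sigma <- c(sigma_a, sigma_b, sigma_c, sigma_d)
  st <- sum(sigma)
  # a ratio whose denominator carries no variance at all is 0 when the
  # numerator is also 0 (that level explains nothing), NaN otherwise
  ratio <- function(num, den) {
    if (den != 0) num / den else if (num == 0) 0 else NaN
  }
  f <- c(
    F_CT = if (df[["ag"]] > 0) ratio(sigma_a, st) else NA_real_,
    F_SC = ratio(sigma_b, sigma_b + sigma_c + sigma_d),
    F_IS = ratio(sigma_c, sigma_c + sigma_d),
    F_IT = ratio(sigma_a + sigma_b + sigma_c, st)
  )
  list(ss = unname(ss), df = unname(df), sigma = sigma, sigma_total = st,
       f = f)
}

#' Write an AMOVA table as TSV
#' @param x an `amova_result`.
#' @param path output path.
#' @export
write_amova <- function(x, path) {
  tab <- x$table
  tab$F_statistic <- c(
    paste0("F_CT=", format(x$f_stats[["F_CT"]], digits = 5)),
    paste0("F_SC=", format(x$f_stats[["F_SC"]], digits = 5)),
    paste0("F_IS=", format(x$f_stats[["F_IS"]], digits = 5)),
    paste0("F_IT=", format(x$f_stats[["F_IT"]], digits = 5)))
  tab$p_value <- unname(x$p_values)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
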