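#' Allele frequencies at one site and locus
#'
#' @param t a [genotype_table()].
#' @param site site label.
#' @param locus locus label.
#' @return a list with `freq` (named numeric, sums to 1), `count` (number of
#'   gene copies, `2 * N`) and `N` (individuals with a non-missing call).
#' @export
allele_frequencies <- function(t, site, locus) {
  idx <- which(t$site == site)
  if (!length(idx)) stop("unknown site: ", site)
  j <- match(locus, t$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  alleles <- c(t$a1[idx, j], t$a2[idx, j])
  alleles <- alleles[!is.na(alleles)]
  if (!length(alleles)) {
    stop("no non-missing calls at (", site, ", ", locus, ")")
  }
  tab <- table(alleles)
  list(freq = stats::setNames(as.numeric(tab) / length(alleles), names(tab)),
       count = length(alleles), N = length(alleles) / 2L)
}

#' Observed heterozygosity at one site and locus
#'
#' Proportion of individuals with two distinct alleles among those with a
#' non-missing call.
#'
#' @inheritParams allele_frequencies
#' @return proportion in \[0, 1\].
#' @export
observed_heterozygosity <- function(t, site, locus) {
  idx <- which(t$site == site)
  j <- match(locus, t$loci)
  a1 <- t$a1[idx, j]; a2 <- t$a2[idx, j]
  keep <- !is.na(a1)
  if (!any(keep)) stop("no non-missing calls at (", site, ", ", locus, ")")
  mean(a1[keep] != a2[keep])
}

#' Unbiased expected heterozygosity (gene diversity) at one site and locus
#'
#' Nei's small-sample-corrected gene diversity,
#' `He = 2n/(2n - 1) * (1 - sum(p^2))`, where `2n` is the number of gene
#' copies observed. Zero for a monomorphic locus.
#'
#' @inheritParams allele_frequencies
#' @return value in \[0, 1\].
#' @export
expected_heterozygosity_unbiased <- function(t, site, locus) {
  af <- allele_frequencies(t, site, locus)
  m <- af$count
  if (m <= 1) return(0)
  (m / (m - 1)) * (1 - sum(af$freq^2))
}

#' Per-site, per-locus diversity and inbreeding table
#'
#' For every (site, locus) cell with data: sample size `N`, observed (`Ho`)
#' and unbiased expected (`He`) heterozygosity, and the inbreeding
#' coefficient `Fis = 1 - Ho/He` (Nei's G_IS form; `NA` with
#' `fis_undefined = TRUE` where `He = 0`). The multilocus per-site summary
#' weights loci by their per-locus sample sizes:
#' `Fis_ML = 1 - sum(Ho_l * N_l) / sum(He_l * N_l)`.
#'
#' Negative `Fis` indicates heterozygote excess; positive values a deficit
#' (inbreeding, null alleles, or substructure).
#'
#' @param t a [genotype_table()].
#' @return a data frame with one row per (site, locus) plus one `All loci`
#'   row per site; columns `site, locus, N, Ho, He, Fis, fis_undefined`.
#' @export
fis_table <- function(t) {
  if (!n_samples(t)) stop("empty genotype table")
  rows <- list()
  for (s in sites(t)) {
    num <- 0; den <- 0; any_defined <- FALSE
    for (l in t$loci) {
      idx <- which(t$site == s)
      j <- match(l, t$loci)
      keep <- !is.na(t$a1[idx, j])
      N <- sum(keep)
      if (N == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          site = s, locus = l, N = 0L, Ho = NA_real_, He = NA_real_,
          Fis = NA_real_, fis_undefined = TRUE)
        next
      }
      Ho <- observed_heterozygosity(t, s, l)
      He <- expected_heterozygosity_unbiased(t, s, l)
      undef <- He <= 0
      Fis <- if (undef) NA_real_ else 1 - Ho / He
      if (!undef) {
        num <- num + Ho * N; den <- den + He * N; any_defined <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, locus = l, N = N, Ho = Ho, He = He, Fis = Fis,
        fis_undefined = undef)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      site = s, locus = "All loci", N = NA_integer_,
      Ho = NA_real_, He = NA_real_,
      Fis = if (any_defined) 1 - num / den else NA_real_,
      fis_undefined = !any_defined)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multilocus Fis per site
#'
#' Convenience accessor over [fis_table()]: the sample-size-weighted
#' multilocus inbreeding coefficient for each site.
#'
#' @param t a [genotype_table()].
#' @return named numeric vector (one value per site).
#' @export
multilocus_fis <- function(t) {
  ft <- fis_table(t)
  ml <- ft[ft$locus == "All loci", ]
  stats::setNames(ml$Fis, ml$site)
}

#' Write a diversity table as TSV (site blocks x loci columns)
#' @param ft output of [fis_table()].
#' @param path output path.
#' @export
write_fis_table <- function(ft, path) {
  utils::write.table(ft, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
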