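#' Diploid microsatellite genotype table
#'
#' The central container of the package: diploid calls for a set of samples
#' at a set of microsatellite loci, together with the sampling site of each
#' individual and an optional site-to-group map for hierarchical analyses.
#' Allele calls are stored as two integer matrices (`a1`, `a2`, samples in
#' rows, loci in columns) with the unordered pair canonicalised so that
#' `a1 <= a2`; a missing call has `NA` in both matrices.
#'
#' @param samples character vector of unique sample identifiers.
#' @param loci character vector of unique locus identifiers.
#' @param a1,a2 integer matrices (`length(samples)` x `length(loci)`) of
#'   allele labels (positive integers), `NA` where the call is missing.
#'   The pair is unordered; it is stored sorted.
#' @param site character or factor of length `length(samples)` giving the
#'   sampling site of each individual.
#' @param group optional named character vector mapping site labels to
#'   higher-level group labels (used by [amova()]).
#'
#' @return An object of class `genotype_table`.
#' @seealso [read_genepop()], [read_csv_genotypes()], [allele_frequencies()]
#' @export
genotype_table <- function(samples, loci, a1, a2, site, group = NULL) {
  samples <- as.character(samples)
  loci <- as.character(loci)
  a1 <- matrix(as.integer(a1), nrow = length(samples), ncol = length(loci))
  a2 <- matrix(as.integer(a2), nrow = length(samples), ncol = length(loci))
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (anyDuplicated(loci)) stop("duplicate locus ids")
  if (length(site) != length(samples)) {
    stop("`site` must have one entry per sample")
  }
  # canonicalise the unordered pair and force joint missingness
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  miss <- is.na(a1) | is.na(a2)
  lo[miss] <- NA_integer_
  hi[miss] <- NA_integer_
  if (any(lo[!is.na(lo)] < 1L)) stop("allele labels must be >= 1")
  site <- factor(as.character(site))
  if (!is.null(group)) {
    group <- vapply(group, as.character, character(1))
    unknown <- setdiff(names(group), levels(site))
    if (length(unknown)) {
      stop("group map refers to unknown sites: ",
           paste(unknown, collapse = ", "))
    }
  }
  dimnames(lo) <- dimnames(hi) <- list(samples, loci)
  structure(
    list(samples = samples, loci = loci, a1 = lo, a2 = hi,
         site = site, group = group),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> ", length(x$samples), " samples x ",
      length(x$loci), " loci, ", nlevels(x$site), " sites\n", sep = "")
  miss <- mean(is.na(x$a1))
  cat("  sites: ", paste(levels(x$site), " (", tabulate(x$site), ")",
                         sep = "", collapse = ", "), "\n", sep = "")
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$samples), length(x$loci))

#' Number of samples / loci / site labels of a genotype table
#' @param t a [genotype_table()].
#' @return `n_samples()` and `n_loci()` return integer counts; `sites()`
#'   returns the site labels (factor levels).
#' @export
n_samples <- function(t) length(t$samples)

#' @rdname n_samples
#' @export
n_loci <- function(t) length(t$loci)

#' @rdname n_samples
#' @export
sites <- function(t) levels(t$site)

#' Subset a genotype table by samples
#'
#' @param t a [genotype_table()].
#' @param which logical or integer index over samples.
#' @param drop_sites drop unused site levels (default `TRUE`).
#' @return a `genotype_table` with the selected samples.
#' @export
subset_samples <- function(t, which, drop_sites = TRUE) {
  site <- t$site[which]
  if (drop_sites) site <- droplevels(site)
  genotype_table(t$samples[which], t$loci,
                 t$a1[which, , drop = FALSE], t$a2[which, , drop = FALSE],
                 site, t$group)
}

#' Merge several sites of a table into one population
#'
#' Used to pool sampling locations (e.g. all Iquitos sub-sites into a single
#' "Iquitos" population before isolation-by-distance analysis against a
#' transport network that only resolves whole towns).
#'
#' @param t a [genotype_table()].
#' @param sites character vector of site labels to merge.
#' @param into label of the merged population.
#' @return a `genotype_table` with the sites collapsed.
#' @export
collapse_sites <- function(t, sites, into) {
  lv <- levels(t$site)
  if (!all(sites %in% lv)) stop("unknown site in `sites`")
  s <- as.character(t$site)
  s[s %in% sites] <- into
  group <- t$group
  if (!is.null(group)) {
    group <- group[!(names(group) %in% sites)]
    if (length(group) == 0) group <- NULL
  }
  genotype_table(t$samples, t$loci, t$a1, t$a2, s, group)
}

#' Combine genotype tables sharing the same loci
#' @param ... genotype tables with identical locus sets.
#' @return a single `genotype_table`.
#' @export
bind_tables <- function(...) {
  ts <- list(...)
  loci <- ts[[1]]$loci
  for (t in ts) {
    if (!identical(t$loci, loci)) stop("tables have different loci")
  }
  genotype_table(
    unlist(lapply(ts, `[[`, "samples")), loci,
    do.call(rbind, lapply(ts, `[[`, "a1")),
    do.call(rbind, lapply(ts, `[[`, "a2")),
    unlist(lapply(ts, function(t) as.character(t$site))),
    NULL
  )
}

#' Tables are compared on calls, sites and groups
#' @param t1,t2 genotype tables.
#' @return `TRUE` if the tables describe the same data.
#' @export
tables_equal <- function(t1, t2) {
  identical(t1$samples, t2$samples) &&
    identical(t1$loci, t2$loci) &&
    identical(t1$a1, t2$a1) && identical(t1$a2, t2$a2) &&
    identical(as.character(t1$site), as.character(t2$site))
}
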