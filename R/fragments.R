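#' Raw microsatellite fragment-size panel
#'
#' Holds the two real-valued fragment lengths (base pairs) scored per sample
#' and locus before allele binning, plus each locus's repeat-motif length.
#'
#' @param samples character vector of sample ids.
#' @param loci character vector of locus ids.
#' @param f1,f2 numeric matrices (samples x loci) of fragment lengths in bp;
#'   `NA` for missing calls.
#' @param motif named integer vector (per locus) of repeat-unit length in bp;
#'   must be in 2..6.
#' @param site optional site label per sample (carried into the binned
#'   genotype table).
#' @return an object of class `fragment_panel`.
#' @export
fragment_panel <- function(samples, loci, f1, f2, motif, site = NULL) {
  samples <- as.character(samples); loci <- as.character(loci)
  f1 <- matrix(as.numeric(f1), length(samples), length(loci))
  f2 <- matrix(as.numeric(f2), length(samples), length(loci))
  if (is.null(names(motif))) names(motif) <- loci
  motif <- as.integer(motif[loci])
  if (any(is.na(motif)) || any(!motif %in% 2:6)) {
    stop("motif_length must be defined for every locus and lie in 2..6")
  }
  if (any(f1 <= 0 | f2 <= 0, na.rm = TRUE)) stop("fragment lengths must be > 0")
  if (is.null(site)) site <- rep("S1", length(samples))
  names(motif) <- loci
  dimnames(f1) <- dimnames(f2) <- list(samples, loci)
  structure(list(samples = samples, loci = loci, f1 = f1, f2 = f2,
                 motif = motif, site = factor(as.character(site))),
            class = "fragment_panel")
}

#' Bin raw fragment sizes into integer allele calls
#'
#' Per locus, the observed fragment sizes are clustered by single-linkage
#' with a gap threshold: sorted unique sizes are split wherever consecutive
#' sizes differ by at least `gap_fraction * motif_length`. Each cluster
#' becomes one allele, labelled by its repeat-number offset from the
#' smallest cluster: `1 + round((cluster_mean - smallest_cluster_mean) /
#' motif_length)`. Labels are therefore invariant to a constant shift of all
#' sizes at a locus and strictly increase with fragment size.
#'
#' @param panel a [fragment_panel()].
#' @param gap_fraction split threshold as a fraction of the motif length,
#'   in (0, 1); default 0.5.
#' @return a [genotype_table()] with the binned calls.
#' @export
bin_fragments <- function(panel, gap_fraction = 0.5) {
  stopifnot(inherits(panel, "fragment_panel"))
  if (!(gap_fraction > 0 && gap_fraction < 1)) {
    stop("gap_fraction must lie in (0, 1)")
  }
  n <- length(panel$samples); L <- length(panel$loci)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    sizes <- c(panel$f1[, j], panel$f2[, j])
    obs <- sizes[!is.na(sizes)]
    if (!length(obs)) next
    map <- .gap_cluster_labels(sort(unique(obs)), panel$motif[j],
                               gap_fraction, panel$loci[j])
    lab <- map$label[match(sizes, map$size)]
    a1[, j] <- lab[seq_len(n)]
    a2[, j] <- lab[n + seq_len(n)]
  }
  genotype_table(panel$samples, panel$loci, a1, a2, panel$site)
}

# single-linkage gap clustering of sorted unique sizes at one locus
.gap_cluster_labels <- function(u, motif, gap_fraction, locus) {
  thr <- gap_fraction * motif
  cl <- cumsum(c(1, diff(u) >= thr))
  means <- tapply(u, cl, mean)
  labels <- 1L + as.integer(round((means - means[1]) / motif))
  if (anyDuplicated(labels)) {
    d <- labels[duplicated(labels)][1]
    stop("binning conflict at locus ", locus, ": clusters with means ",
         paste(signif(means[labels == d], 6), collapse = " and "),
         " map to the same allele label ", d)
  }
  if (is.unsorted(labels, strictly = TRUE)) {
    stop("binning conflict at locus ", locus,
         ": allele labels not strictly increasing with size")
  }
  data.frame(size = u, label = labels[cl])
}
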