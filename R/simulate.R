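#' Balding-Nichols per-site allele frequencies
#'
#' The standard drift model for differentiated subpopulations: each site's
#' allele-frequency vector is an independent Dirichlet draw with parameter
#' `ancestral * (1 - F) / F`, so that each allele's frequency has mean
#' `p` and variance `p (1 - p) F` across sites and the expected pairwise
#' F_ST between sites is approximately `F`.
#'
#' @param ancestral ancestral allele-frequency vector (sums to 1).
#' @param F differentiation parameter, in (0, 1).
#' @param n_sites number of site-specific frequency vectors to draw.
#' @param seed integer seed.
#' @return a matrix (`n_sites` x alleles) of site frequencies.
#' @export
balding_nichols_frequencies <- function(ancestral, F, n_sites, seed = 1L) {
  if (abs(sum(ancestral) - 1) > 1e-8) stop("ancestral must sum to 1")
  if (!(F > 0 && F < 1)) stop("F must lie in (0, 1)")
  if (length(ancestral) < 2 || any(ancestral == 1)) {
    warning("degenerate ancestral frequencies: returned unchanged")
    return(matrix(rep(ancestral, each = n_sites), nrow = n_sites))
  }
  set.seed(seed)
  conc <- ancestral * (1 - F) / F
  out <- matrix(0, n_sites, length(ancestral))
  for (s in seq_len(n_sites)) {
    g <- stats::rgamma(length(conc), shape = conc, rate = 1)
    out[s, ] <- g / sum(g)
  }
  out
}

#' Sample diploid genotypes at one site under an inbreeding mixture
#'
#' Each individual, independently at each locus: with probability `F_IS`
#' one allele is drawn from the site frequencies and duplicated (identical
#' by descent); otherwise two alleles are drawn independently. Under this
#' mixture the expected heterozygosity deficit of the site equals `F_IS`,
#' so the diversity module's multilocus Fis is directly recoverable.
#'
#' @param freqs list of per-locus allele-frequency vectors for this site
#'   (names or positions give allele labels; unnamed vectors use labels
#'   `1..k`).
#' @param n_individuals individuals to draw.
#' @param F_IS inbreeding coefficient, in \[0, 1).
#' @param seed integer seed.
#' @param site site label.
#' @param sample_prefix prefix for generated sample ids.
#' @return a [genotype_table()] fragment with one site.
#' @export
sample_genotypes <- function(freqs, n_individuals, F_IS = 0, seed = 1L,
                             site = "S1", sample_prefix = site) {
  if (!(F_IS >= 0 && F_IS < 1)) stop("F_IS must lie in [0, 1)")
  set.seed(seed)
  L <- length(freqs)
  a1 <- matrix(NA_integer_, n_individuals, L)
  a2 <- matrix(NA_integer_, n_individuals, L)
  for (l in seq_len(L)) {
    p <- freqs[[l]]
    labels <- if (is.null(names(p))) seq_along(p) else as.integer(names(p))
    ibd <- stats::runif(n_individuals) < F_IS
    x1 <- labels[sample.int(length(p), n_individuals, replace = TRUE, prob = p)]
    x2 <- labels[sample.int(length(p), n_individuals, replace = TRUE, prob = p)]
    x2[ibd] <- x1[ibd]
    a1[, l] <- x1; a2[, l] <- x2
  }
  genotype_table(paste0(sample_prefix, "_", seq_len(n_individuals)),
                 paste0("L", seq_len(L)), a1, a2,
                 rep(site, n_individuals))
}

#' Simulate a multi-site genotype table under Balding-Nichols drift
#'
#' Convenience wrapper tying [balding_nichols_frequencies()] and
#' [sample_genotypes()] together: site-specific frequencies are drawn per
#' locus around shared ancestral frequencies, then genotypes per site with
#' a common inbreeding level. Defaults emulate the study design this
#' package targets: 8 microsatellite loci scored over 9 sites with 20-76
#' individuals each and low-to-moderate differentiation.
#'
#' @param n_per_site integer vector of site sample sizes (names become
#'   site labels; default the 9 field site sizes).
#' @param n_loci number of loci.
#' @param n_alleles alleles per locus (equifrequent ancestral).
#' @param F Balding-Nichols differentiation parameter.
#' @param F_IS within-site inbreeding coefficient.
#' @param seed integer seed.
#' @return a [genotype_table()].
#' @export
simulate_genotype_table <- function(
    n_per_site = c(BarrioFlorida = 31, Aucayo = 20, IndianaMazan = 32,
                   Nauta = 55, Tamshiaco = 76, IquitosA = 21, IquitosB = 40,
                   IquitosC = 35, IquitosD = 29),
    n_loci = 8, n_alleles = 5, F = 0.05, F_IS = 0.15, seed = 1L) {
  if (is.null(names(n_per_site))) {
    names(n_per_site) <- paste0("S", seq_along(n_per_site))
  }
  k <- length(n_per_site)
  ancestral <- rep(1 / n_alleles, n_alleles)
  site_freqs <- lapply(seq_len(n_loci), function(l) {
    balding_nichols_frequencies(ancestral, F, k, seed = seed + 37L * l)
  })
  tabs <- lapply(seq_len(k), function(s) {
    freqs <- lapply(site_freqs, function(m) m[s, ])
    sample_genotypes(freqs, n_per_site[s], F_IS,
                     seed = seed + 1000L + s,
                     site = names(n_per_site)[s])
  })
  do.call(bind_tables, tabs)
}

#' Simulate genotypes from the admixture model
#'
#' Each individual draws admixture proportions `q ~ Dirichlet(alpha 1_K)`;
#' each allele copy picks a source cluster with probability `q_k` and then
#' an allele from that cluster's locus frequencies. This mirrors exactly
#' the model fitted by [gibbs_admixture()], so recovery of Q and of the
#' true K is a well-posed test.
#'
#' @param K number of ancestral clusters.
#' @param alpha symmetric Dirichlet admixture parameter (small = nearly
#'   pure individuals).
#' @param cluster_freqs list over loci of K x A allele-frequency matrices
#'   (each row a simplex), or `NULL` to draw well-separated frequencies
#'   from Dirichlet(0.2) per cluster.
#' @param n_individuals individuals to draw.
#' @param n_loci,n_alleles used only when `cluster_freqs` is `NULL`.
#' @param seed integer seed.
#' @return list: `table` (a [genotype_table()], site label `ADM`), `Q`
#'   (true admixture proportions), `cluster_freqs`.
#' @export
simulate_admixed_table <- function(K, alpha = 0.3, cluster_freqs = NULL,
                                   n_individuals = 150, n_loci = 20,
                                   n_alleles = 5, seed = 1L) {
  set.seed(seed)
  if (is.null(cluster_freqs)) {
    cluster_freqs <- lapply(seq_len(n_loci), function(l) {
      m <- matrix(stats::rgamma(K * n_alleles, shape = 0.2), K, n_alleles)
      m / rowSums(m)
    })
  }
  n_loci <- length(cluster_freqs)
  Q <- matrix(stats::rgamma(n_individuals * K, shape = alpha),
              n_individuals, K)
  Q <- Q / rowSums(Q)
  a1 <- matrix(NA_integer_, n_individuals, n_loci)
  a2 <- matrix(NA_integer_, n_individuals, n_loci)
  draw_copy <- function(q, p) {
    k <- sample.int(nrow(p), 1, prob = q)
    sample.int(ncol(p), 1, prob = p[k, ])
  }
  for (i in seq_len(n_individuals)) for (l in seq_len(n_loci)) {
    a1[i, l] <- draw_copy(Q[i, ], cluster_freqs[[l]])
    a2[i, l] <- draw_copy(Q[i, ], cluster_freqs[[l]])
  }
  tab <- genotype_table(paste0("adm_", seq_len(n_individuals)),
                        paste0("L", seq_len(n_loci)), a1, a2,
                        rep("ADM", n_individuals))
  list(table = tab, Q = Q, cluster_freqs = cluster_freqs)
}

#' Simulate the hub-and-spoke study region
#'
#' A seven-town river-basin layout emulating an Amazonian trade hub and
#' its satellite settlements: a single large hub city, one highway (the
#' only terrestrial edge, hub to its road-connected neighbour), fluvial
#' edges from the hub to every town, pairwise straight-line distances
#' spanning roughly 15-125 km, and a star-shaped trips table concentrated
#' on the hub. Default infestation probabilities per vehicle type are the
#' field survey rates: large barges 0.71, medium barges 0.35, buses 0.125.
#'
#' @param seed integer seed (trip counts are drawn around the star
#'   pattern; geometry is fixed).
#' @return list: `geography` (a [site_geography()]) and `network` (a
#'   [transport_network()]).
#' @export
simulate_study_region <- function(seed = 1L) {
  set.seed(seed)
  geo <- site_geography(
    site = c("Iquitos", "Nauta", "IndianaMazan", "Tamshiaco", "Aucayo",
             "BarrioFlorida", "Mishana"),
    x_km = c(0, -22, 25, 12, 22, 30, -28),
    y_km = c(0, -80, 35, -28, -17, 12, -18),
    population = c(406340, 13983, 6594, 4583, 806, 728, 400))
  # fluvial routes follow the rivers: ~20-40% longer than straight line
  fl <- function(a, b, stretch) {
    d <- sqrt(sum((unlist(geo[geo$site == a, 2:3]) -
                     unlist(geo[geo$site == b, 2:3]))^2))
    round(d * stretch, 1)
  }
  edges <- data.frame(
    from = "Iquitos",
    to = c("Nauta", "IndianaMazan", "Tamshiaco", "Aucayo",
           "BarrioFlorida", "Mishana"),
    mode = "fluvial",
    length_km = c(fl("Iquitos", "Nauta", 1.35),
                  fl("Iquitos", "IndianaMazan", 1.25),
                  fl("Iquitos", "Tamshiaco", 1.2),
                  fl("Iquitos", "Aucayo", 1.3),
                  fl("Iquitos", "BarrioFlorida", 1.3),
                  fl("Iquitos", "Mishana", 1.25)))
  edges <- rbind(edges,
                 data.frame(from = "Iquitos", to = "Nauta",
                            mode = "terrestrial", length_km = 95))
  gamma <- c(large_barge = 0.71, medium_barge = 0.35, bus = 0.125)
  towns <- setdiff(geo$site, "Iquitos")
  base <- c(Nauta = 30, IndianaMazan = 40, Tamshiaco = 45, Aucayo = 10,
            BarrioFlorida = 4, Mishana = 6)
  trips <- do.call(rbind, lapply(towns, function(tn) {
    data.frame(
      vehicle_type = c("large_barge", "medium_barge", "bus"),
      from = "Iquitos", to = tn,
      n_trips = c(stats::rpois(1, base[tn]),
                  stats::rpois(1, base[tn] * 1.5),
                  if (tn == "Nauta") stats::rpois(1, 25) else 0L))
  }))
  trips <- trips[trips$n_trips > 0, ]
  list(geography = geo,
       network = transport_network(geo$site, edges, gamma, trips))
}

#' Simulate a raw fragment-size panel from a genotype table
#'
#' Inverse of [bin_fragments()] for round-trip testing: fragment length =
#' locus base length + allele label x motif + Gaussian noise.
#'
#' @param t a [genotype_table()].
#' @param motif_length repeat-unit size in bp (scalar or per locus).
#' @param size_noise_sd Gaussian measurement noise, bp (should be well
#'   below `motif_length / 4` for unambiguous binning).
#' @param base_length fragment length of allele label 0 (scalar or per
#'   locus).
#' @param seed integer seed.
#' @return a [fragment_panel()].
#' @export
simulate_fragment_panel <- function(t, motif_length = 3, size_noise_sd = 0,
                                    base_length = 100, seed = 1L) {
  set.seed(seed)
  L <- n_loci(t)
  motif <- rep_len(as.integer(motif_length), L)
  base <- rep_len(base_length, L)
  n <- n_samples(t)
  noise <- function() stats::rnorm(n * L, 0, size_noise_sd)
  f1 <- sweep(t$a1 * rep(motif, each = n), 2, -base) + noise()
  f2 <- sweep(t$a2 * rep(motif, each = n), 2, -base) + noise()
  fragment_panel(t$samples, t$loci, f1, f2,
                 stats::setNames(motif, t$loci), site = t$site)
}
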