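#' Mantel test between two labelled distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with
#' significance from joint row-and-column permutations of the second
#' matrix. P-values use add-one smoothing, `p = (count + 1) / (n_perm +
#' 1)`, counting permutations at least as extreme in the requested tail.
#'
#' @param D1,D2 symmetric matrices with identical labels in identical
#'   order (e.g. a genetic-distance and a geographic-distance matrix).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param tail `"greater"` (default; positive association), `"less"`, or
#'   `"two_sided"`.
#' @param exhaustive enumerate all `n!` relabelings instead of sampling
#'   (only sensible for very small matrices); `n_perm` is then ignored and
#'   the identity relabeling is part of the reference set.
#' @return a `mantel_result` list: `r`, `p`, `n_permutations`, `n_sites`,
#'   `tail`.
#' @export
mantel_test <- function(D1, D2, n_perm = 10000, seed = 1L,
                        tail = c("greater", "less", "two_sided"),
                        exhaustive = FALSE) {
  tail <- match.arg(tail)
  if (!identical(rownames(D1), rownames(D2))) {
    stop("matrices must share labels in the same order")
  }
  n <- nrow(D1)
  if (n < 4) stop("need at least 4 sites for a Mantel test")
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  if (stats::sd(v1) == 0 || stats::sd(D2[ut]) == 0) {
    stop("zero-variance distance triangle: r undefined")
  }
  r_obs <- stats::cor(v1, D2[ut])
  score <- function(perm) {
    Dp <- D2[perm, perm]
    stats::cor(v1, Dp[ut])
  }
  extreme <- function(r) switch(tail,
    greater = r >= r_obs,
    less = r <= r_obs,
    two_sided = abs(r) >= abs(r_obs))
  if (exhaustive) {
    perms <- .all_permutations(n)
    rs <- vapply(perms, score, 0)
    p <- mean(vapply(rs, extreme, NA))
    n_used <- length(perms)
  } else {
    set.seed(seed)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      if (extreme(score(sample.int(n)))) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p, n_permutations = n_used, n_sites = n,
                 tail = tail),
            class = "mantel_result")
}

.all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    i <- i + 1L
    out[[i]] <- append(s, n, after = pos - 1L)
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.4f, p = %.4g (%s, %d permutations, %d sites)\n",
              x$r, x$p, x$tail, x$n_permutations, x$n_sites))
  invisible(x)
}

#' Isolation-by-distance suite over several distance models
#'
#' Runs one Mantel test of the pairwise F_ST matrix against each distance
#' model and exports the per-pair scatter data used for IBD plots. Models
#' flagged as similarities (e.g. the propagule pressure index) are tested
#' with the `"less"` tail, since stronger transport linkage predicts lower
#' genetic differentiation; plain distances use the `"greater"` tail.
#'
#' A model whose matrix has fewer than `min_pairs` pairs with data (after
#' dropping `NA`/infinite entries) is not tested: its result carries
#' `test_skipped = TRUE`, the descriptive `r` over the available pairs,
#' and no p-value. This is the situation of a trips-survey PrPI known only
#' between a hub and its satellite towns.
#'
#' @param fst an `fst_matrix` from [pairwise_fst()] (sites must match the
#'   distance models; collapse sub-sites first with [collapse_sites()] if
#'   the transport data only resolve whole towns).
#' @param models named list of `distance_matrix` objects.
#' @param n_perm,seed passed to [mantel_test()].
#' @param min_pairs minimum complete pairs required to run a test.
#' @return list with `results` (one `mantel_result`-like record per model)
#'   and `scatter` (data frame: pair, model, distance, fst).
#' @export
ibd_suite <- function(fst, models, n_perm = 10000, seed = 1L,
                      min_pairs = 6L) {
  sl <- fst$sites
  res <- list(); scat <- list()
  for (nm in names(models)) {
    D <- models[[nm]]
    if (!all(sl %in% rownames(D))) {
      stop("model '", nm, "' missing sites: ",
           paste(setdiff(sl, rownames(D)), collapse = ", "))
    }
    D <- D[sl, sl]
    ut <- which(upper.tri(D), arr.ind = TRUE)
    pairs <- data.frame(
      pair = paste(sl[ut[, 1]], sl[ut[, 2]], sep = "-"),
      model = nm, distance = D[upper.tri(D)],
      fst = fst$theta[upper.tri(fst$theta)])
    scat[[nm]] <- pairs
    ok <- is.finite(pairs$distance) & is.finite(pairs$fst)
    similarity <- isTRUE(attr(models[[nm]], "similarity"))
    if (sum(ok) < min_pairs || sum(ok) < nrow(pairs)) {
      # incomplete matrix: report descriptive r only
      r <- if (sum(ok) >= 3 && stats::sd(pairs$distance[ok]) > 0)
        stats::cor(pairs$distance[ok], pairs$fst[ok]) else NA_real_
      res[[nm]] <- list(model = nm, r = r, p = NA_real_,
                        n_pairs = sum(ok), test_skipped = TRUE)
      next
    }
    mt <- mantel_test(fst$theta, unclass(D), n_perm = n_perm, seed = seed,
                      tail = if (similarity) "less" else "greater")
    res[[nm]] <- list(model = nm, r = mt$r, p = mt$p,
                      n_pairs = nrow(pairs), test_skipped = FALSE)
  }
  list(results = res, scatter = do.call(rbind, c(scat, make.row.names = FALSE)))
}
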