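#' Load a run configuration
#'
#' Reads a YAML configuration (or accepts an equivalent list) and fills in
#' desk-scale defaults. `paper_protocol: true` switches every Monte Carlo
#' engine to the heavy field-protocol lengths (1e6 HWE chain steps / 1e5
#' dememorization, 10000 permutations, 1e5/2e5 admixture chains).
#'
#' @param x path to a YAML file, or a named list.
#' @return a `run_config` list.
#' @export
run_config <- function(x = list()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  dflt <- list(
    seed = 1L,
    out_dir = "riverpg-results",
    paper_protocol = FALSE,
    input = list(),              # genepop/site_names/metadata/network paths
    simulate = list(F = 0.05, F_IS = 0.15, n_loci = 8, n_alleles = 5),
    hierarchy = NULL,
    collapse = NULL,             # list(sites=..., into=...)
    hwe = list(steps = 2e4, burnin = 2e3, alpha = 0.05,
               n_tests_override = NULL),
    fst = list(n_perm = 199),
    amova = list(n_perm = 199),
    mantel = list(n_perm = 999, min_pairs = 6),
    admixture = list(K_range = 1:6, n_runs = 3, burnin = 500, iters = 2000,
                     thin = 5, alpha = 1.0, lambda = 1.0,
                     dominance_threshold = 0.8)
  )
  cfg <- utils::modifyList(dflt, cfg)
  if (isTRUE(cfg$paper_protocol)) {
    cfg$hwe$steps <- 1e6; cfg$hwe$burnin <- 1e5
    cfg$fst$n_perm <- 10000; cfg$amova$n_perm <- 10000
    cfg$mantel$n_perm <- 10000
    cfg$admixture$burnin <- 1e5; cfg$admixture$iters <- 2e5
    cfg$admixture$n_runs <- 10; cfg$admixture$K_range <- 1:10
  }
  cfg$admixture$K_range <- seq(min(cfg$admixture$K_range),
                               max(cfg$admixture$K_range))
  class(cfg) <- "run_config"
  cfg
}

#' Read a transport network from edge/trips/gamma CSV files
#'
#' @param edges_csv CSV `from, to, mode, length_km`.
#' @param gamma_csv CSV `vehicle_type, infestation_prob`.
#' @param trips_csv CSV `vehicle_type, from, to, n_trips` (optional).
#' @param nodes node labels; default every site appearing in the edges.
#' @return a [transport_network()].
#' @export
read_network_csvs <- function(edges_csv, gamma_csv, trips_csv = NULL,
                              nodes = NULL) {
  edges <- utils::read.csv(edges_csv)
  gdf <- utils::read.csv(gamma_csv)
  gamma <- stats::setNames(gdf$infestation_prob, gdf$vehicle_type)
  trips <- if (!is.null(trips_csv)) utils::read.csv(trips_csv) else
    data.frame(vehicle_type = character(0), from = character(0),
               to = character(0), n_trips = integer(0))
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  transport_network(nodes, edges, gamma, trips)
}

#' Write a transport network (and geography) as CSV files
#' @param region output of [simulate_study_region()].
#' @param dir output directory.
#' @export
write_region_csvs <- function(region, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(region$geography, file.path(dir, "sites.csv"),
                   row.names = FALSE)
  utils::write.csv(region$network$edges, file.path(dir, "edges.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(vehicle_type = names(region$network$gamma),
                              infestation_prob = unname(region$network$gamma)),
                   file.path(dir, "gamma.csv"), row.names = FALSE)
  utils::write.csv(region$network$trips, file.path(dir, "trips.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Reproduces the complete analysis sequence on one genotype table:
#' per-site diversity and inbreeding, exact Hardy-Weinberg tests with
#' Sidak correction, pairwise F_ST on all sites and on the collapsed
#' (town-level) sites, hierarchical AMOVA, the three geographic distance
#' models plus the propagule pressure index, Mantel isolation-by-distance
#' tests, an admixture K-sweep with Evanno Delta-K model choice, and the
#' dominant-membership summary. Every stage is seeded from the config,
#' logged, and written as TSV under `out_dir`; a markdown report collects
#' the headline numbers. A failing stage is recorded and later
#' independent stages still run.
#'
#' @param config a [run_config()] (or list/path coercible to one).
#' @param table optionally, a pre-built [genotype_table()] (otherwise
#'   loaded from `config$input` or simulated).
#' @param region optionally, a pre-built study region (geography +
#'   network); otherwise loaded or simulated.
#' @return list of stage results (invisibly); side effect: files under
#'   `config$out_dir`.
#' @export
run_all <- function(config = run_config(), table = NULL, region = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  results <- list(failed = character(0))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      logf("[%s] FAILED: %s", name, conditionMessage(e))
      results$failed <<- c(results$failed, name)
      NULL
    })
    logf("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, "secs"))
    res
  }
  cat("", file = log_path)
  logf("riverpg run, seed %d", config$seed)

  # ---- inputs -----------------------------------------------------------
  if (is.null(table)) {
    table <- if (!is.null(config$input$genepop)) {
      read_genepop(config$input$genepop,
                   site_names = config$input$site_names)
    } else {
      sim <- config$simulate
      simulate_genotype_table(F = sim$F, F_IS = sim$F_IS,
                              n_loci = sim$n_loci,
                              n_alleles = sim$n_alleles,
                              seed = config$seed)
    }
  }
  if (is.null(region)) {
    region <- if (!is.null(config$input$network_dir)) {
      d <- config$input$network_dir
      geo <- utils::read.csv(file.path(d, "sites.csv"))
      list(geography = site_geography(geo$site, geo$x_km, geo$y_km,
                                      geo$population),
           network = read_network_csvs(file.path(d, "edges.csv"),
                                       file.path(d, "gamma.csv"),
                                       file.path(d, "trips.csv")))
    } else {
      simulate_study_region(seed = config$seed)
    }
  }
  hierarchy <- config$hierarchy
  if (!is.null(hierarchy)) hierarchy <- unlist(hierarchy)

  # ---- diversity --------------------------------------------------------
  div <- stage("diversity", {
    ft <- fis_table(table)
    write_fis_table(ft, file.path(out, "diversity.tsv"))
    ft
  })
  results$diversity <- div

  # ---- HWE --------------------------------------------------------------
  hwe_res <- stage("hwe", {
    h <- hwe_table(table, steps = config$hwe$steps,
                   burnin = config$hwe$burnin, alpha = config$hwe$alpha,
                   n_tests_override = config$hwe$n_tests_override,
                   seed = config$seed)
    utils::write.table(h, file.path(out, "hwe.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    h
  })
  results$hwe <- hwe_res

  # ---- pairwise F_ST: all sites, then collapsed -------------------------
  fst_full <- stage("fst_full", {
    f <- pairwise_fst(table, n_perm = config$fst$n_perm,
                      seed = config$seed)
    write_fst_matrix(f, file.path(out, "fst_full.tsv"))
    f
  })
  results$fst_full <- fst_full

  collapsed <- table
  if (!is.null(config$collapse)) {
    collapsed <- collapse_sites(table, unlist(config$collapse$sites),
                                config$collapse$into)
  }
  fst_coll <- stage("fst_collapsed", {
    f <- pairwise_fst(collapsed, n_perm = config$fst$n_perm,
                      seed = config$seed + 1L)
    write_fst_matrix(f, file.path(out, "fst_collapsed.tsv"))
    f
  })
  results$fst_collapsed <- fst_coll

  # ---- AMOVA ------------------------------------------------------------
  am <- stage("amova", {
    a <- amova(table, hierarchy = hierarchy,
               n_perm = config$amova$n_perm, seed = config$seed)
    write_amova(a, file.path(out, "amova.tsv"))
    a
  })
  results$amova <- am

  # ---- distance models + Mantel -----------------------------------------
  ibd <- stage("ibd", {
    geo <- region$geography
    keep <- geo$site %in% sites(collapsed)
    geo2 <- site_geography(geo$site[keep], geo$x_km[keep], geo$y_km[keep],
                           geo$population[keep])
    models <- list(
      euclidean = euclidean_matrix(geo2),
      fluvial_path = path_matrix(region$network, "fluvial")[geo2$site, geo2$site],
      shortest_path = path_matrix(region$network)[geo2$site, geo2$site],
      prpi = prpi_matrix(region$network, geo2$site))
    attr(models$fluvial_path, "similarity") <- FALSE
    attr(models$shortest_path, "similarity") <- FALSE
    attr(models$prpi, "similarity") <- TRUE
    fst_geo <- fst_coll
    ord <- match(geo2$site, fst_geo$sites)
    fst_geo$sites <- fst_geo$sites[ord]
    fst_geo$theta <- fst_geo$theta[ord, ord]
    fst_geo$p <- fst_geo$p[ord, ord]
    s <- ibd_suite(fst_geo, models, n_perm = config$mantel$n_perm,
                   seed = config$seed, min_pairs = config$mantel$min_pairs)
    utils::write.table(s$scatter, file.path(out, "ibd_scatter.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(s$results, file.path(out, "mantel.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    s
  })
  results$ibd <- ibd

  # ---- admixture sweep + Evanno + membership ----------------------------
  adm <- stage("admixture", {
    ax <- config$admixture
    runs <- admixture_sweep(table, K_range = ax$K_range,
                            n_runs = ax$n_runs, seed = config$seed,
                            burnin = ax$burnin, iters = ax$iters,
                            thin = ax$thin, alpha = ax$alpha,
                            lambda = ax$lambda)
    ev <- evanno(runs)
    utils::write.table(ev, file.path(out, "evanno.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    selK <- attr(ev, "selected_K")
    best <- runs[vapply(runs, `[[`, 0, "K") == selK]
    best <- align_labels(best)
    Qbar <- Reduce(`+`, lapply(best, `[[`, "Q")) / length(best)
    run_bar <- best[[1]]; run_bar$Q <- Qbar
    write_q_matrix(run_bar, file.path(out, "q_matrix.tsv"))
    dom <- dominant_membership(Qbar, table$site,
                               threshold = ax$dominance_threshold)
    utils::write.table(dom$per_site, file.path(out, "membership.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(evanno = ev, selected_K = selK, Q = Qbar, dominance = dom)
  })
  results$admixture <- adm

  stage("report", .write_report(results, config, out))
  invisible(results)
}

.write_report <- function(results, config, out) {
  p <- file.path(out, "report.md")
  con <- file(p, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# riverpg analysis report")
  w("")
  w("Seed: %d", config$seed)
  if (length(results$failed)) {
    w("")
    w("**Failed stages:** %s", paste(results$failed, collapse = ", "))
  }
  if (!is.null(results$hwe)) {
    h <- results$hwe
    n_dev <- sum(h$significant_after_sidak)
    w("")
    w("## Hardy-Weinberg")
    w("%d of %d tests in equilibrium (%s) at Sidak threshold %.5g.",
      nrow(h) - n_dev, attr(h, "n_tests"),
      format_percent(nrow(h) - n_dev, attr(h, "n_tests")),
      attr(h, "sidak_threshold"))
  }
  if (!is.null(results$fst_full)) {
    th <- results$fst_full$theta
    v <- th[upper.tri(th)]
    w("")
    w("## Pairwise F_ST")
    w("%d pairs; theta range %.4f to %.4f (median %.4f).",
      length(v), min(v, na.rm = TRUE), max(v, na.rm = TRUE),
      stats::median(v, na.rm = TRUE))
  }
  if (!is.null(results$amova)) {
    w("")
    w("## AMOVA")
    tab <- results$amova$table
    for (i in seq_len(nrow(tab))) {
      w("- %s: %.2f%% of variance", tab$level[i], tab$percent_of_total[i])
    }
  }
  if (!is.null(results$ibd)) {
    w("")
    w("## Isolation by distance")
    for (r in results$ibd$results) {
      if (isTRUE(r$test_skipped)) {
        w("- %s: r = %s over %d pairs (no test: too few pairs)",
          r$model, format(round(r$r, 3)), r$n_pairs)
      } else {
        w("- %s: Mantel r = %.3f, p = %.4f", r$model, r$r, r$p)
      }
    }
  }
  if (!is.null(results$admixture)) {
    a <- results$admixture
    w("")
    w("## Admixture")
    w("Selected K = %d by Delta-K; %d of %d individuals (%s) show dominant",
      a$selected_K, a$dominance$n_dominant, a$dominance$n_total,
      format_percent(a$dominance$n_dominant, a$dominance$n_total))
    w("membership (> %.2f) to a single cluster.",
      config$admixture$dominance_threshold)
  }
  invisible(p)
}
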