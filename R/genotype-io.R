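#' Read a GenePop 4.x genotype file
#'
#' Parses the classic GenePop text dialect: a title line, one locus name per
#' line (or a single comma-separated line), then `POP` blocks with lines of
#' the form `id , 001002 003003 ...`. Alleles may be coded with 2 or 3
#' digits; `00`/`000` denotes a missing allele and a call with either allele
#' missing is treated as a missing call.
#'
#' @param path path to a GenePop file.
#' @param site_names optional character vector naming the `POP` blocks in
#'   file order; defaults to `POP1`, `POP2`, ...
#' @return a [genotype_table()] with one site per `POP` block.
#' @export
read_genepop <- function(path, site_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("not a GenePop file: fewer than 3 lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a GenePop file: no POP line")
  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  pop_starts <- which(is_pop)
  n_pop <- length(pop_starts)
  if (is.null(site_names)) site_names <- paste0("POP", seq_len(n_pop))
  if (length(site_names) != n_pop) {
    stop("site_names has length ", length(site_names),
         " but file has ", n_pop, " POP blocks")
  }
  ids <- character(0); site <- character(0)
  a1 <- NULL; a2 <- NULL
  for (b in seq_len(n_pop)) {
    from <- pop_starts[b] + 1L
    to <- if (b < n_pop) pop_starts[b + 1L] - 1L else length(lines)
    for (ln in seq(from, length.out = max(0L, to - from + 1L))) {
      raw <- lines[ln]
      if (!nzchar(trimws(raw))) next
      parts <- strsplit(raw, ",")[[1]]
      if (length(parts) < 2) {
        stop("line ", ln, ": expected 'id , genotypes' but got: ", raw)
      }
      id <- trimws(parts[1])
      gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
      if (length(gts) != length(loci)) {
        stop("line ", ln, ": ", length(gts), " genotypes for ",
             length(loci), " loci")
      }
      row <- .decode_genepop_calls(gts, ln)
      ids <- c(ids, id); site <- c(site, site_names[b])
      a1 <- rbind(a1, row[1, ]); a2 <- rbind(a2, row[2, ])
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample id: ", ids[duplicated(ids)][1])
  }
  genotype_table(ids, loci, a1, a2, site)
}

.decode_genepop_calls <- function(gts, ln) {
  nc <- nchar(gts)
  if (!all(nc %in% c(4L, 6L))) {
    stop("line ", ln, ": genotype strings must be 4 or 6 digits, got '",
         gts[which(!(nc %in% c(4L, 6L)))[1]], "'")
  }
  if (any(grepl("[^0-9]", gts))) {
    stop("line ", ln, ": non-numeric genotype field")
  }
  w <- nc / 2L
  x1 <- as.integer(substr(gts, 1L, w))
  x2 <- as.integer(substr(gts, w + 1L, nc))
  miss <- x1 == 0L | x2 == 0L
  x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
  rbind(x1, x2)
}

#' Write a genotype table as canonical GenePop text
#'
#' Writes 3-digit alleles, one locus name per line, and one `POP` block per
#' site (site order = site factor levels). GenePop has no population-name
#' field, so site labels are not stored in the file; pass them back to
#' [read_genepop()] via `site_names` for a lossless round trip.
#'
#' @param t a [genotype_table()].
#' @param path output path.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(t, path, title = "riverpg export") {
  if (any(t$a2 > 999, na.rm = TRUE)) {
    stop("allele labels > 999 cannot be written as 3-digit GenePop")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(t$loci, con)
  for (s in levels(t$site)) {
    writeLines("POP", con)
    idx <- which(t$site == s)
    for (i in idx) {
      g1 <- t$a1[i, ]; g2 <- t$a2[i, ]
      g1[is.na(g1)] <- 0L; g2[is.na(g2)] <- 0L
      writeLines(paste0(t$samples[i], " , ",
                        paste0(sprintf("%03d", g1), sprintf("%03d", g2),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read genotypes from a CSV file
#'
#' Expected columns: `sample`, `site`, then one column per locus containing
#' `a1/a2` allele-label pairs; `-` marks a missing allele (so `-/-` is a
#' missing call).
#'
#' @param path path to the CSV file.
#' @param loci optional character vector restricting/ordering the locus
#'   columns; defaults to every column after `sample` and `site`.
#' @return a [genotype_table()].
#' @export
read_csv_genotypes <- function(path, loci = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  for (col in c("sample", "site")) {
    if (!col %in% names(df)) stop("schema error: missing column '", col, "'")
  }
  if (is.null(loci)) loci <- setdiff(names(df), c("sample", "site"))
  if (!all(loci %in% names(df))) {
    stop("schema error: missing locus column(s): ",
         paste(setdiff(loci, names(df)), collapse = ", "))
  }
  n <- nrow(df)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (j in seq_along(loci)) {
    parts <- strsplit(df[[loci[j]]], "/", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) {
      stop("malformed genotype '", df[[loci[j]]][which(bad)[1]],
           "' at locus ", loci[j])
    }
    m <- matrix(trimws(unlist(parts)), ncol = 2, byrow = TRUE)
    miss <- m[, 1] == "-" | m[, 2] == "-"
    a1[, j] <- ifelse(miss, NA_integer_, suppressWarnings(as.integer(m[, 1])))
    a2[, j] <- ifelse(miss, NA_integer_, suppressWarnings(as.integer(m[, 2])))
    if (any(is.na(a1[, j]) & !miss)) {
      stop("non-integer allele at locus ", loci[j])
    }
  }
  genotype_table(df$sample, loci, a1, a2, df$site)
}

#' @rdname read_csv_genotypes
#' @param t a [genotype_table()] to write.
#' @export
write_csv_genotypes <- function(t, path) {
  enc <- function(x1, x2) {
    out <- paste0(x1, "/", x2)
    out[is.na(x1)] <- "-/-"
    out
  }
  df <- data.frame(sample = t$samples, site = as.character(t$site),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(t$loci)) df[[t$loci[j]]] <- enc(t$a1[, j], t$a2[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read site metadata (coordinates, groups, human population)
#'
#' @param path CSV with columns `site`, optionally `group`, `x_km`, `y_km`,
#'   `population`.
#' @return a data frame with one row per site.
#' @export
read_site_metadata <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"site" %in% names(df)) stop("schema error: missing column 'site'")
  if (anyDuplicated(df$site)) stop("duplicate site in metadata")
  df
}
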