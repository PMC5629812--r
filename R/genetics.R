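#' Codominant genotype table
#'
#' Container for diploid, codominant (microsatellite-style) genotypes:
#' individuals with site labels, an ordered set of loci, two allele calls
#' per individual and locus (positive integer codes; 0 is the reserved
#' missing code), and projected site coordinates.
#'
#' @param individuals data frame with `individual_id`, `site_id`.
#' @param loci character vector of locus names.
#' @param calls integer matrix, one row per individual, columns
#'   `<locus>_1`, `<locus>_2` per locus in order; missing = 0.
#' @param sites data frame with `site_id`, `x`, `y` (projected meters).
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(individuals, loci, calls, sites) {
  if (nrow(individuals) < 1L || length(loci) < 1L) stopf("need >= 1 individual and >= 1 locus")
  if (anyDuplicated(individuals$individual_id))
    stopf("duplicate individual_id: %s",
          paste(unique(individuals$individual_id[duplicated(individuals$individual_id)]),
                collapse = ", "))
  if (!all(individuals$site_id %in% sites$site_id))
    stopf("individuals reference site_ids missing from the sites table: %s",
          paste(setdiff(individuals$site_id, sites$site_id), collapse = ", "))
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(individuals) || ncol(calls) != 2L * length(loci))
    stopf("calls must be %d x %d", nrow(individuals), 2L * length(loci))
  if (any(calls < 0L)) stopf("allele codes must be positive integers (0 = missing)")
  colnames(calls) <- paste0(rep(loci, each = 2L), c("_1", "_2"))
  keep_cols <- intersect(c("site_id", "x", "y", "species"), names(sites))
  structure(list(individuals = individuals, loci = loci, calls = calls,
                 sites = sites[, keep_cols]),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d loci, %d sites, %.1f%% missing calls\n",
              nrow(x$individuals), length(x$loci), nrow(x$sites),
              100 * mean(x$calls == 0L)))
  invisible(x)
}

#' Read genotypes from CSV or Genepop
#'
#' CSV dialect: one row per individual with columns `individual_id`,
#' `site_id`, then `<locus>_1`, `<locus>_2` per locus; missing = 0. Genepop
#' files ("Pop"-delimited, 2- or 3-digit concatenated alleles) are also
#' accepted; site labels are assigned per Pop block. Site coordinates come
#' from a sidecar CSV (`site_id`, `x`, `y`) when the format lacks them.
#'
#' @param path genotype file.
#' @param format `"csv"` or `"genepop"`.
#' @param sites_path sidecar coordinates CSV; defaults to
#'   `<path minus extension>_sites.csv` if it exists, else sites get
#'   placeholder (0, 0) coordinates with a message.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("csv", "genepop"),
                           sites_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  parsed <- if (format == "csv") read_genotypes_csv(path) else read_genepop(path)
  if (is.null(sites_path)) {
    cand <- paste0(sub("\\.[^.]+$", "", path), "_sites.csv")
    if (file.exists(cand)) sites_path <- cand
  }
  sites <- if (!is.null(sites_path)) {
    s <- read.csv(sites_path, stringsAsFactors = FALSE)
    if (!all(c("site_id", "x", "y") %in% names(s)))
      stopf("sites sidecar must have columns site_id, x, y")
    s
  } else {
    log_msg("genetics", "no site coordinates found; using placeholder (0, 0)")
    data.frame(site_id = unique(parsed$individuals$site_id), x = 0, y = 0,
               stringsAsFactors = FALSE)
  }
  tab <- genotype_table(parsed$individuals, parsed$loci, parsed$calls, sites)
  log_msg("genetics", "read %d individuals x %d loci from %s",
          nrow(tab$individuals), length(tab$loci), path)
  tab
}

read_genotypes_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("individual_id", "site_id") %in% names(df)))
    stopf("CSV must start with individual_id, site_id columns")
  locus_cols <- setdiff(names(df), c("individual_id", "site_id"))
  bad <- locus_cols[!grepl("_[12]$", locus_cols)]
  if (length(bad)) stopf("unknown locus columns (need <locus>_1/<locus>_2): %s",
                         paste(bad, collapse = ", "))
  loci <- unique(sub("_[12]$", "", locus_cols))
  need <- paste0(rep(loci, each = 2L), c("_1", "_2"))
  if (!all(need %in% locus_cols))
    stopf("incomplete locus column pairs for: %s",
          paste(loci[!(paste0(loci, "_1") %in% locus_cols &
                       paste0(loci, "_2") %in% locus_cols)], collapse = ", "))
  calls <- suppressWarnings(
    matrix(as.integer(as.matrix(df[, need, drop = FALSE])), nrow = nrow(df),
           dimnames = list(NULL, need)))
  if (anyNA(calls)) stopf("non-integer or missing allele codes in %s", path)
  list(individuals = df[, c("individual_id", "site_id")], loci = loci,
       calls = calls)
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stopf("genepop file too short: %s", path)
  body <- lines[-1L]  # first line is a title/comment
  pop_rows <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_rows) == 0L) stopf("no 'Pop' delimiter found in %s", path)
  locus_lines <- body[seq_len(pop_rows[1] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  ind_id <- character(0); site_id <- character(0); rows <- list()
  block <- 0L
  for (i in seq.int(pop_rows[1], length(body))) {
    ln <- body[i]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) { block <- block + 1L; next }
    halves <- strsplit(ln, ",")[[1]]
    if (length(halves) != 2L) stopf("genepop line %d lacks a single comma: %s",
                                    i + 1L, ln)
    id <- trimws(halves[1])
    toks <- strsplit(trimws(halves[2]), "\\s+")[[1]]
    if (length(toks) != length(loci))
      stopf("genepop line %d has %d genotypes, expected %d", i + 1L,
            length(toks), length(loci))
    w <- nchar(toks[1]) / 2L
    if (!w %in% c(2L, 3L)) stopf("genepop alleles must be 2 or 3 digits per allele")
    a1 <- as.integer(substr(toks, 1L, w))
    a2 <- as.integer(substr(toks, w + 1L, 2L * w))
    ind_id <- c(ind_id, id)
    site_id <- c(site_id, sprintf("pop%d", block))
    rows[[length(rows) + 1L]] <- as.vector(rbind(a1, a2))
  }
  calls <- do.call(rbind, rows)
  colnames(calls) <- paste0(rep(loci, each = 2L), c("_1", "_2"))
  list(individuals = data.frame(individual_id = ind_id, site_id = site_id,
                                stringsAsFactors = FALSE),
       loci = loci, calls = calls)
}

#' Write a genotype table as CSV (plus sites sidecar)
#'
#' @param table a [genotype_table()].
#' @param path output CSV; the sites sidecar is written next to it as
#'   `<path minus extension>_sites.csv`.
#' @export
write_genotypes_csv <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  df <- cbind(table$individuals, as.data.frame(table$calls))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  write.csv(table$sites, paste0(sub("\\.[^.]+$", "", path), "_sites.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

missing_fraction <- function(table) {
  rowMeans(table$calls == 0L)
}

#' Filter individuals by missing-call fraction
#'
#' Removes individuals whose fraction of missing allele calls (missing calls
#' over 2 x number of loci) exceeds `max_missing`; the inequality is strict,
#' so an individual at exactly the threshold is retained. Sites left empty
#' are dropped with a warning and recorded in the `dropped_sites` attribute.
#'
#' @param table a [genotype_table()].
#' @param max_missing maximum tolerated missing fraction (default 0.35).
#' @return filtered [genotype_table()] with a `filter_log` attribute
#'   (removed counts per site).
#' @export
filter_individuals <- function(table, max_missing = 0.35) {
  stopifnot(inherits(table, "genotype_table"))
  if (max_missing < 0 || max_missing > 1) stopf("max_missing must be in [0, 1]")
  frac <- missing_fraction(table)
  keep <- frac <= max_missing
  removed <- table(factor(table$individuals$site_id[!keep],
                          levels = table$sites$site_id))
  out <- table
  out$individuals <- table$individuals[keep, , drop = FALSE]
  out$calls <- table$calls[keep, , drop = FALSE]
  empty <- setdiff(table$sites$site_id, unique(out$individuals$site_id))
  if (length(empty)) {
    warnf("site(s) left with 0 individuals after filtering, dropped: %s",
          paste(empty, collapse = ", "))
    out$sites <- out$sites[!out$sites$site_id %in% empty, , drop = FALSE]
  }
  attr(out, "filter_log") <- as.data.frame(removed, stringsAsFactors = FALSE) |>
    setNames(c("site_id", "n_removed"))
  attr(out, "dropped_sites") <- empty
  log_msg("genetics", "filter: removed %d of %d individuals (> %.0f%% missing)",
          sum(!keep), length(keep), 100 * max_missing)
  out
}

#' Encode genotypes as within-individual allele frequencies
#'
#' One column per observed (locus, allele) combination; an individual's
#' entry is its count of that allele (0, 1 or 2) divided by 2, so per-locus
#' row sums are 1 for fully observed loci. A locus with any missing call is
#' treated as missing for that individual and imputed with the site-mean of
#' each of the locus's columns (global mean where a whole site lacks the
#' locus), keeping site centroids unbiased.
#'
#' @param table a [genotype_table()] (typically after [filter_individuals()]).
#' @return numeric matrix, rows = individuals, with a `site_id` attribute;
#'   column names `<locus>.<allele>`.
#' @export
encode_multivariate <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  n <- nrow(table$individuals)
  site <- table$individuals$site_id
  cols <- list()
  for (l in seq_along(table$loci)) {
    a1 <- table$calls[, 2L * l - 1L]
    a2 <- table$calls[, 2L * l]
    obs <- sort(unique(c(a1[a1 > 0L], a2[a2 > 0L])))
    if (length(obs) == 0L) next
    m <- matrix(0, n, length(obs),
                dimnames = list(NULL, paste0(table$loci[l], ".", obs)))
    for (k in seq_along(obs)) {
      m[, k] <- ((a1 == obs[k]) + (a2 == obs[k])) / 2
    }
    miss <- a1 == 0L | a2 == 0L
    if (any(miss)) {
      m[miss, ] <- NA_real_
      for (s in unique(site[miss])) {
        rows_s <- site == s
        fill <- colMeans(m[rows_s, , drop = FALSE], na.rm = TRUE)
        if (anyNA(fill)) fill <- colMeans(m, na.rm = TRUE)
        idx <- which(rows_s & miss)
        m[idx, ] <- matrix(fill, length(idx), length(obs), byrow = TRUE)
      }
    }
    cols[[table$loci[l]]] <- m
  }
  out <- do.call(cbind, cols)
  if (is.null(out) || ncol(out) < 2L)
    stopf("dataset is monomorphic; multivariate encoding undefined")
  attr(out, "site_id") <- site
  out
}

#' Among-population covariance and distance matrices
#'
#' Computes site centroids of the encoded genotypes, grand-centers them, and
#' forms the among-population covariance C = Xc Xc' / (p - 1) and the
#' squared-distance-style matrix D with D_ij = C_ii + C_jj - 2 C_ij.
#'
#' @param encoded matrix from [encode_multivariate()].
#' @param site_id site assignment per row; defaults to the matrix's
#'   `site_id` attribute.
#' @return a `population_matrix_set`: list with `site_order`, `C`, `D`,
#'   `n_per_site`.
#' @export
population_covariance <- function(encoded, site_id = attr(encoded, "site_id")) {
  if (is.null(site_id)) stopf("site_id required")
  sites <- unique(site_id)
  if (length(sites) < 3L) stopf("need >= 3 sites for a population graph")
  counts <- table(site_id)
  if (any(counts < 2L))
    stopf("every site needs >= 2 individuals; too few at: %s",
          paste(names(counts)[counts < 2L], collapse = ", "))
  cent <- do.call(rbind, lapply(sites, function(s)
    colMeans(encoded[site_id == s, , drop = FALSE])))
  rownames(cent) <- sites
  Xc <- sweep(cent, 2L, colMeans(cent))
  C <- Xc %*% t(Xc) / (ncol(Xc) - 1L)
  D <- outer(diag(C), diag(C), "+") - 2 * C
  D[D < 0 & D > -1e-12] <- 0  # clamp fp negatives
  stopifnot(max(abs(C - t(C))) < 1e-10, max(abs(D - t(D))) < 1e-10)
  structure(list(site_order = sites, C = C, D = D,
                 n_per_site = as.integer(counts[sites])),
            class = "population_matrix_set")
}
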