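# Genotype container and file readers/writers.
#
# Genotypes are diploid biallelic SNP calls coded as the count of the
# reference allele in {0, 1, 2}; NA is the missing sentinel and is never
# imputed. Every individual carries a collection key (population, spawn
# year, detection site).

#' Construct a genotype matrix
#'
#' Bundles an individuals x loci matrix of reference-allele dosages with the
#' per-individual collection labels (population, spawn year, detection site)
#' that every downstream analysis groups by.
#'
#' @param calls integer matrix, individuals in rows, loci in columns; entries
#'   in \{0, 1, 2\} or `NA` for missing.
#' @param population character vector, one population name per individual.
#' @param year integer vector of spawn years, one per individual.
#' @param site character vector of detection-site names, one per individual.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls` (the matrix, with individual ids as rownames and locus ids as
#'   colnames) and `labels` (a data frame with columns `individual`,
#'   `population`, `year`, `site`).
#' @export
genotype_matrix <- function(calls, population, year, site) {
  if (!is.matrix(calls)) stop("calls must be a matrix", call. = FALSE)
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("calls must be in {0,1,2} or NA", call. = FALSE)
  n <- nrow(calls)
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("ind%04d", seq_len(n))
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("loc%04d", seq_len(ncol(calls)))
  if (anyDuplicated(colnames(calls))) stop("locus ids must be unique", call. = FALSE)
  if (length(population) != n || length(year) != n || length(site) != n)
    stop("labels must have one entry per individual", call. = FALSE)
  labels <- data.frame(
    individual = rownames(calls),
    population = as.character(population),
    year = as.integer(year),
    site = as.character(site),
    stringsAsFactors = FALSE
  )
  structure(list(calls = calls, labels = labels), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d populations, %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$labels$population)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param g a [genotype_matrix()].
#' @param individuals logical/integer/character index over individuals.
#' @param loci logical/integer/character index over loci.
#' @return A `genotype_matrix`.
#' @export
gm_subset <- function(g, individuals = NULL, loci = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  lab <- g$labels
  if (!is.null(individuals)) {
    if (is.character(individuals)) individuals <- match(individuals, rownames(calls))
    calls <- calls[individuals, , drop = FALSE]
    lab <- lab[individuals, , drop = FALSE]
  }
  if (!is.null(loci)) calls <- calls[, loci, drop = FALSE]
  rownames(lab) <- NULL
  structure(list(calls = calls, labels = lab), class = "genotype_matrix")
}

# ---------------------------------------------------------------------------
# Readers / writers: a labelled CSV dialect and the classic genepop dialect.

#' Read a genotype table
#'
#' Two dialects are supported. `csv` expects header columns `individual`,
#' `population`, `year`, `site`, then one column per locus holding dosages
#' in \{0, 1, 2\} (empty/`NA` = missing). `genepop` expects the classic
#' layout: a title line, locus names (one per line or comma separated),
#' `Pop` separators, and per-individual lines `id , 0101 0102 ...` with 2- or
#' 3-digit allele codes (`00`/`000` = missing). Dosage is counted against the
#' numerically smallest allele code observed at each locus; a locus showing
#' more than two alleles is an error. Unparseable allele codes become missing
#' with a single summary warning.
#'
#' Genepop carries no year/site metadata; ids written by [write_genotypes()]
#' encode `population|year|site|individual` and are decoded on read. Other
#' ids fall back to population `Pop<k>` for section `k` with `NA` year/site.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"genepop"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") read_genotypes_csv(path) else read_genotypes_genepop(path)
}

read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("individual", "population", "year", "site")
  if (!all(need %in% names(df)))
    stop("malformed header: need columns ", paste(need, collapse = ", "), call. = FALSE)
  loci <- setdiff(names(df), need)
  if (!length(loci)) stop("malformed header: no locus columns", call. = FALSE)
  raw <- as.matrix(df[loci])
  mode(raw) <- "character"
  calls <- matrix(suppressWarnings(as.integer(raw)), nrow(raw), ncol(raw),
                  dimnames = dimnames(raw))
  calls[!is.na(calls) & !(calls %in% 0:2)] <- NA_integer_
  n_bad <- sum(is.na(calls) & !is.na(raw) & nzchar(trimws(raw)) & trimws(raw) != "NA")
  if (n_bad > 0)
    warning(n_bad, " unparseable genotype codes set to missing", call. = FALSE)
  rownames(calls) <- df$individual
  genotype_matrix(calls, df$population, df$year, df$site)
}

read_genotypes_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("malformed header: truncated genepop file", call. = FALSE)
  body <- lines[-1L]                      # drop title line
  is_pop <- tolower(trimws(body)) == "pop"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop) || first_pop == 1L)
    stop("malformed header: no locus names before first Pop", call. = FALSE)
  locus_lines <- trimws(body[seq_len(first_pop - 1L)])
  loci <- unlist(strsplit(paste(locus_lines, collapse = ","), ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("malformed header: duplicate locus names", call. = FALSE)

  sec <- cumsum(is_pop)
  ind_lines <- body[!is_pop & sec >= 1L]
  ind_sec <- sec[!is_pop & sec >= 1L]
  n <- length(ind_lines)
  L <- length(loci)
  a1 <- matrix(NA_character_, n, L)
  a2 <- matrix(NA_character_, n, L)
  ids <- character(n)
  n_unparseable <- 0L
  for (i in seq_len(n)) {
    parts <- strsplit(ind_lines[i], ",")[[1L]]
    if (length(parts) < 2L) stop("malformed genepop individual line: ", ind_lines[i], call. = FALSE)
    ids[i] <- trimws(parts[1L])
    toks <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "[[:space:]]+")[[1L]]
    if (length(toks) != L)
      stop("individual ", ids[i], " has ", length(toks), " genotypes for ", L, " loci", call. = FALSE)
    w <- nchar(toks)
    ok <- grepl("^[0-9]+$", toks) & (w == 4L | w == 6L)
    n_unparseable <- n_unparseable + sum(!ok)
    half <- ifelse(w == 6L, 3L, 2L)
    x1 <- substr(toks, 1L, half)
    x2 <- substr(toks, half + 1L, 2L * half)
    x1[!ok] <- NA; x2[!ok] <- NA
    miss <- function(z) !is.na(z) & as.integer(z) == 0L
    x1[miss(x1) | miss(x2)] <- NA
    x2[is.na(x1)] <- NA
    a1[i, ] <- x1; a2[i, ] <- x2
  }
  if (n_unparseable > 0)
    warning(n_unparseable, " unparseable genotype codes set to missing", call. = FALSE)

  calls <- matrix(NA_integer_, n, L, dimnames = list(ids, loci))
  for (l in seq_len(L)) {
    al <- c(a1[, l], a2[, l])
    obs <- sort(unique(as.integer(al[!is.na(al)])))
    if (length(obs) > 2L)
      stop("locus ", loci[l], " shows more than 2 alleles", call. = FALSE)
    if (!length(obs)) next
    ref <- obs[1L]
    calls[, l] <- (!is.na(a1[, l]) & as.integer(a1[, l]) == ref) +
      (!is.na(a2[, l]) & as.integer(a2[, l]) == ref)
    calls[is.na(a1[, l]), l] <- NA_integer_
  }

  meta <- decode_genepop_ids(ids, ind_sec)
  rownames(calls) <- meta$individual
  genotype_matrix(calls, meta$population, meta$year, meta$site)
}

decode_genepop_ids <- function(ids, sec) {
  has_key <- grepl("|", ids, fixed = TRUE)
  pop <- paste0("Pop", sec)
  year <- rep(NA_integer_, length(ids))
  site <- rep(NA_character_, length(ids))
  ind <- ids
  if (any(has_key)) {
    parts <- strsplit(ids[has_key], "|", fixed = TRUE)
    pop[has_key] <- vapply(parts, `[`, "", 1L)
    year[has_key] <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    site[has_key] <- vapply(parts, `[`, "", 3L)
    ind[has_key] <- vapply(parts, function(p) paste(p[-(1:3)], collapse = "|"), "")
  }
  list(individual = ind, population = pop, year = year, site = site)
}

#' Write a genotype table
#'
#' Inverse of [read_genotypes()]. The genepop dialect writes one `Pop`
#' section per population and encodes `population|year|site|individual` in
#' the id field so labels survive a round trip; reference allele is written
#' as `01` and the alternate as `02`.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param dialect `"csv"` or `"genepop"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("csv", "genepop")) {
  stopifnot(inherits(g, "genotype_matrix"))
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- cbind(g$labels, as.data.frame(g$calls, check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    lab <- g$labels
    code <- c("0202", "0102", "0101")    # dosage 0,1,2 of reference allele 01
    out <- c("rivergsi genepop export", colnames(g$calls))
    for (p in unique(lab$population)) {
      out <- c(out, "Pop")
      idx <- which(lab$population == p)
      for (i in idx) {
        gi <- g$calls[i, ]
        tok <- ifelse(is.na(gi), "0000", code[gi + 1L])
        id <- paste(lab$population[i], lab$year[i], lab$site[i], lab$individual[i], sep = "|")
        out <- c(out, paste0(id, " , ", paste(tok, collapse = " ")))
      }
    }
    writeLines(out, path)
  }
  invisible(path)
}
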