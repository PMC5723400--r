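# Reading, validating and summarizing multilocus genotype tables.
#
# A genotype matrix holds diploid allele calls for N ramet samples at L loci
# for a single site x species. Allele labels are opaque text (microsatellite
# fragment sizes and SNP bases both pass through unchanged); a call is missing
# as a whole if either allele carries the missing code.

#' Construct a genotype matrix
#'
#' Container for per-site diploid multilocus genotypes: `N` samples by `L`
#' loci, each call an unordered pair of allele labels. Pairs are stored
#' order-normalized (lexicographically, so `(A,B)` and `(B,A)` are the same
#' call) and a call is missing as a whole when either allele is `NA`.
#'
#' @param site_id Site identifier (length-1 character).
#' @param species Species name (length-1 character).
#' @param sample_ids Character vector of unique sample identifiers (length N).
#' @param locus_ids Character vector of locus identifiers (length L).
#' @param allele1,allele2 N x L character matrices of allele labels. `NA`
#'   marks a missing call; if either matrix is `NA` at a cell both are set
#'   `NA`.
#' @return An object of class `genotype_matrix` with elements `site_id`,
#'   `species`, `sample_ids`, `locus_ids`, `allele1`, `allele2` (after
#'   order normalization `allele1 <= allele2` elementwise).
#' @examples
#' g <- genotype_matrix("S1", "H. ovalis", c("r1", "r2"), c("locA"),
#'                      matrix(c("124", "120")), matrix(c("120", "120")))
#' g$allele1  # normalized: 120 first
#' @export
genotype_matrix <- function(site_id, species, sample_ids, locus_ids,
                            allele1, allele2) {
  stopifnot(is.character(site_id), length(site_id) == 1L)
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "character"
  storage.mode(allele2) <- "character"
  n <- length(sample_ids)
  l <- length(locus_ids)
  if (n == 0L || l == 0L)
    stop("empty genotype table: need at least one sample and one locus")
  if (!all(dim(allele1) == c(n, l)) || !all(dim(allele2) == c(n, l)))
    stop("allele matrices must be N x L (", n, " x ", l, ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id within site '", site_id, "': ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  # whole-call missingness: either allele NA -> both NA
  miss <- is.na(allele1) | is.na(allele2)
  allele1[miss] <- NA_character_
  allele2[miss] <- NA_character_
  # order-normalize pairs lexicographically
  swap <- !miss & (allele1 > allele2)
  if (any(swap)) {
    tmp <- allele1[swap]
    allele1[swap] <- allele2[swap]
    allele2[swap] <- tmp
  }
  dimnames(allele1) <- dimnames(allele2) <- list(sample_ids, locus_ids)
  structure(
    list(site_id = site_id, species = species, sample_ids = sample_ids,
         locus_ids = locus_ids, allele1 = allele1, allele2 = allele2),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$allele1))
  cat("Genotype matrix: site ", x$site_id, " (", x$species, ")\n",
      "  ", length(x$sample_ids), " samples x ", length(x$locus_ids),
      " loci; ", n_miss, " missing calls\n", sep = "")
  invisible(x)
}

#' Number of samples / loci in a genotype matrix
#' @param g A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(g) length(g$sample_ids)

#' @rdname n_samples
#' @export
n_loci <- function(g) length(g$locus_ids)

#' Read a multilocus genotype table
#'
#' Parses a delimited genotype file into one [genotype_matrix()] per
#' population. Two dialects are supported:
#'
#' * `"genalex_wide"`: header row of locus names over paired allele columns,
#'   one row per sample; first two columns are sample id and population/site.
#'   A locus name is taken from the first column of its pair; the second
#'   header cell may repeat the name or be empty.
#' * `"genepop"`: title line, one locus name per line (or one comma-separated
#'   line), populations delimited by `POP` lines, samples as
#'   `id , 0101 0202 ...` with 4-digit (2+2) or 6-digit (3+3) diploid allele
#'   encodings; `0000`/`000000` is missing.
#'
#' @param path Path to the file.
#' @param dialect `"genalex_wide"` or `"genepop"`.
#' @param missing_code Allele label treated as missing (genalex dialect;
#'   default `"0"`). A call with either allele equal to this code is missing.
#' @param delim Field delimiter for `genalex_wide` (default comma).
#' @param species Species label attached to the result (metadata only).
#' @param simplify If `TRUE` (default) and the file holds a single
#'   population, return the `genotype_matrix` itself rather than a
#'   length-one list.
#' @return A `genotype_matrix`, or a named list of them (one per population)
#'   when the file holds several.
#' @export
read_genotype_table <- function(path,
                                dialect = c("genalex_wide", "genepop"),
                                missing_code = "0", delim = ",",
                                species = NA_character_, simplify = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  out <- switch(dialect,
                genalex_wide = read_genalex_wide(path, missing_code, delim,
                                                 species),
                genepop = read_genepop(path, species))
  if (simplify && length(out) == 1L) out[[1L]] else out
}

read_genalex_wide <- function(path, missing_code, delim, species) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("empty genotype table: ", path)
  cells <- strsplit(lines, delim, fixed = TRUE)
  header <- trimws(cells[[1L]])
  if (length(header) < 4L)
    stop("genalex_wide needs sample id, site and at least one locus pair")
  allele_cols <- header[-(1:2)]
  # a new locus starts wherever the header cell is non-empty and differs
  # from the previous cell; an empty cell or a repeat of the same name marks
  # the pair's second column
  starts <- integer(0)
  prev <- ""
  for (i in seq_along(allele_cols)) {
    cur <- allele_cols[i]
    if (nzchar(cur) && cur != prev) starts <- c(starts, i)
    prev <- cur
  }
  locus_ids <- allele_cols[starts]
  widths <- diff(c(starts, length(allele_cols) + 1L))
  bad <- widths != 2L
  if (any(bad))
    stop("format error: locus '", locus_ids[which(bad)[1L]],
         "' does not span exactly two allele columns")
  body <- cells[-1L]
  ncol_expected <- 2L + length(allele_cols)
  sample_ids <- character(length(body))
  pops <- character(length(body))
  a1 <- matrix(NA_character_, length(body), length(locus_ids))
  a2 <- matrix(NA_character_, length(body), length(locus_ids))
  for (r in seq_along(body)) {
    row <- trimws(body[[r]])
    if (length(row) < ncol_expected)
      row <- c(row, rep("", ncol_expected - length(row)))
    sample_ids[r] <- row[1L]
    pops[r] <- row[2L]
    al <- row[-(1:2)]
    a1[r, ] <- al[starts]
    a2[r, ] <- al[starts + 1L]
  }
  a1[a1 == missing_code | a1 == ""] <- NA_character_
  a2[a2 == missing_code | a2 == ""] <- NA_character_
  split_to_matrices(sample_ids, pops, locus_ids, a1, a2, species)
}

read_genepop <- function(path, species) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("empty genotype table: ", path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("genepop file has no POP line: ", path)
  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  locus_ids <- trimws(unlist(strsplit(locus_lines, ",", fixed = TRUE)))
  locus_ids <- locus_ids[nzchar(locus_ids)]
  pop_idx <- cumsum(is_pop)
  sample_ids <- character(0); pops <- character(0)
  a1 <- NULL; a2 <- NULL
  rows1 <- list(); rows2 <- list()
  for (i in seq(first_pop + 1L, length(lines))) {
    if (is_pop[i]) next
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("malformed genepop sample line: ", lines[i])
    id <- trimws(parts[1L])
    calls <- strsplit(trimws(paste(parts[-1L], collapse = ",")),
                      "[[:space:]]+")[[1L]]
    calls <- calls[nzchar(calls)]
    if (length(calls) != length(locus_ids))
      stop("sample '", id, "' has ", length(calls), " calls for ",
           length(locus_ids), " loci")
    w <- nchar(calls)
    if (!all(w %in% c(4L, 6L)))
      stop("genepop alleles must be 4- or 6-digit; sample '", id, "'")
    half <- w %/% 2L
    g1 <- substr(calls, 1L, half)
    g2 <- substr(calls, half + 1L, w)
    zero <- strrep("0", half)
    g1[g1 == zero] <- NA_character_
    g2[g2 == zero] <- NA_character_
    sample_ids <- c(sample_ids, id)
    pops <- c(pops, paste0("pop", pop_idx[i]))
    rows1[[length(rows1) + 1L]] <- g1
    rows2[[length(rows2) + 1L]] <- g2
  }
  a1 <- do.call(rbind, rows1)
  a2 <- do.call(rbind, rows2)
  split_to_matrices(sample_ids, pops, locus_ids, a1, a2, species)
}

split_to_matrices <- function(sample_ids, pops, locus_ids, a1, a2, species) {
  if (length(sample_ids) == 0L) stop("empty genotype table")
  out <- lapply(unique(pops), function(p) {
    sel <- pops == p
    genotype_matrix(p, species, sample_ids[sel], locus_ids,
                    a1[sel, , drop = FALSE], a2[sel, , drop = FALSE])
  })
  names(out) <- unique(pops)
  out
}

#' Write a genotype matrix in the genalex-style wide dialect
#'
#' Inverse of [read_genotype_table()] for `dialect = "genalex_wide"`:
#' re-reading the written file reproduces calls, sample order and missing
#' flags exactly.
#'
#' @param g A `genotype_matrix`.
#' @param path Output path.
#' @param missing_code Label written for missing alleles (default `"0"`).
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path, missing_code = "0", delim = ",") {
  stopifnot(inherits(g, "genotype_matrix"))
  header <- c("sample", "site",
              as.vector(rbind(g$locus_ids, g$locus_ids)))
  a1 <- g$allele1; a2 <- g$allele2
  a1[is.na(a1)] <- missing_code
  a2[is.na(a2)] <- missing_code
  body <- vapply(seq_along(g$sample_ids), function(r) {
    paste(c(g$sample_ids[r], g$site_id,
            as.vector(rbind(a1[r, ], a2[r, ]))), collapse = delim)
  }, character(1))
  writeLines(c(paste(header, collapse = delim), body), path)
  invisible(path)
}

#' Allele frequencies per locus
#'
#' Computes, for each locus, the frequency of every allele over the
#' non-missing genotypes: `p_i = count(allele i) / (2 * n_used)` where
#' `n_used` is the number of samples with a non-missing call at that locus.
#' Loci with no non-missing genotypes are dropped with a warning.
#'
#' @param g A `genotype_matrix`.
#' @return A data frame of class `allele_freq_table` with columns `locus`,
#'   `allele`, `freq`, `n_used`; frequencies at each locus sum to 1.
#' @examples
#' g <- genotype_matrix("S1", "sp", c("r1", "r2"), "L1",
#'                      matrix(c("A", "A")), matrix(c("A", "B")))
#' allele_frequencies(g)  # p_A = 0.75, p_B = 0.25
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  rows <- lapply(seq_along(g$locus_ids), function(j) {
    al <- c(g$allele1[, j], g$allele2[, j])
    al <- al[!is.na(al)]
    if (length(al) == 0L) return(NULL)
    tab <- table(al)
    data.frame(locus = g$locus_ids[j], allele = names(tab),
               freq = as.numeric(tab) / length(al),
               n_used = length(al) %/% 2L,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  dropped <- g$locus_ids[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("dropping loci with no non-missing genotypes: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all loci entirely missing")
  class(out) <- c("allele_freq_table", "data.frame")
  out
}
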