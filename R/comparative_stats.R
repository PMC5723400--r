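# Cross-species and spatial comparisons of clonal richness.

#' Compare clonal richness distributions between species
#'
#' Reports a Kruskal-Wallis rank test (with tie correction) for differences
#' in location across species, a Mood's median test (counts above vs not
#' above the grand median, chi-squared on the 2 x k table) for differences
#' in distribution about the common median, and the per-group medians. Both
#' tests are always reported so that either reading of "the medians differ"
#' vs "the distributions differ" is covered.
#'
#' @param groups Named list of numeric vectors (clonal richness per site),
#'   one element per species; at least two groups of at least two values.
#' @return A list of class `species_comparison`: `kruskal` (statistic `H`,
#'   `df`, `p`), `median_test` (`chisq`, `df`, `p`), `medians` (named
#'   vector).
#' @examples
#' species_comparison(list(a = c(.1, .2, .3), b = c(.7, .8, .9)))
#' @export
species_comparison <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least two observations")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    # fully tied data carry no rank information: no evidence of difference
    kw <- list(statistic = c(H = 0), parameter = length(groups) - 1L,
               p.value = 1)
  } else {
    kw <- stats::kruskal.test(groups)
  }
  gm <- stats::median(pooled)
  above <- vapply(groups, function(x) sum(x > gm), integer(1))
  below <- vapply(groups, length, integer(1)) - above
  tab <- rbind(above = above, not_above = below)
  if (all(above == 0L) || all(below == 0L)) {
    med <- list(statistic = 0, parameter = length(groups) - 1L, p.value = 1)
  } else {
    med <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  }
  structure(list(
    kruskal = list(H = unname(kw$statistic), df = unname(kw$parameter),
                   p = kw$p.value),
    median_test = list(chisq = unname(med$statistic),
                       df = unname(med$parameter), p = med$p.value,
                       table = tab),
    medians = vapply(groups, stats::median, numeric(1))),
    class = "species_comparison")
}

#' @export
print.species_comparison <- function(x, ...) {
  cat("Kruskal-Wallis: H =", format(x$kruskal$H, digits = 4),
      ", df =", x$kruskal$df, ", p =", format.pval(x$kruskal$p), "\n")
  cat("Median test:    chisq =", format(x$median_test$chisq, digits = 4),
      ", df =", x$median_test$df, ", p =", format.pval(x$median_test$p),
      "\n")
  cat("Medians:", paste(names(x$medians),
                        format(x$medians, digits = 3), sep = " = ",
                        collapse = ", "), "\n")
  invisible(x)
}

#' Correlation of clonal richness with latitude
#'
#' Pearson correlation of per-site clonal richness against latitude for one
#' species, with the two-sided p-value from the t distribution on n - 2
#' degrees of freedom. By default latitude enters as its absolute value
#' (distance from the equator), appropriate for a study area lying entirely
#' in one hemisphere; set `absolute = FALSE` to use signed latitude.
#'
#' @param samples Data frame with columns `latitude` (decimal degrees,
#'   negative south) and `R`.
#' @param absolute Use \|latitude\| (default `TRUE`).
#' @return A list with `r`, `p`, `n`, and `latitude_scale`.
#' @export
latitude_correlation <- function(samples, absolute = TRUE) {
  stopifnot(all(c("latitude", "R") %in% names(samples)))
  lat <- samples$latitude
  if (absolute) lat <- abs(lat)
  pearson_cor(lat, samples$R,
              scale = if (absolute) "absolute" else "signed")
}

#' Correlation of clonal richness between co-occurring species
#'
#' Pearson correlation of per-site clonal richness for two species at their
#' shared sites, asking whether local-scale processes drive both species
#' alike.
#'
#' @param r_x,r_y Numeric vectors of richness for the two species at the
#'   same sites, in matching order; at least three shared sites.
#' @return A list with `r`, `p`, `n`.
#' @export
cooccurrence_correlation <- function(r_x, r_y) {
  stopifnot(length(r_x) == length(r_y))
  pearson_cor(r_x, r_y)
}

pearson_cor <- function(x, y, scale = NULL) {
  n <- length(x)
  if (n < 3L) stop("need at least three paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = n)
  if (!is.null(scale)) out$latitude_scale <- scale
  out
}
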