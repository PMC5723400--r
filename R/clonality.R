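# Clone identification, marker power (probability of identity) and clonal
# richness.
#
# Samples sharing a multilocus genotype (MLG) are treated as ramets of one
# genet. Marker power is quantified by the probability of identity P_ID --
# the chance two random individuals share an MLG under Hardy-Weinberg
# equilibrium -- accumulated over increasing locus combinations.

#' Identify multilocus genotypes (clones)
#'
#' Partitions the samples of a genotype matrix into multilocus genotypes
#' (MLGs). Two missing-data policies are available:
#'
#' * `"strict"` (default): two samples share an MLG iff all normalized calls
#'   are equal, with missing matching only missing (an equivalence relation).
#' * `"missing_wildcard"`: two samples are linked if they agree at every
#'   locus where both are non-missing; MLGs are the connected components of
#'   the resulting link graph, so a sample with missing calls can bridge two
#'   otherwise distinct genotypes.
#'
#' @param g A [genotype_matrix()].
#' @param policy Missing-data matching policy.
#' @return An object of class `mlg_assignment`: list with `site_id`,
#'   `species`, `assignment` (named integer vector, MLG label per sample,
#'   labelled in order of first appearance), `G` (distinct MLGs), `N`
#'   (samples), and `policy`.
#' @export
identify_mlgs <- function(g, policy = c("strict", "missing_wildcard")) {
  stopifnot(inherits(g, "genotype_matrix"))
  policy <- match.arg(policy)
  n <- n_samples(g)
  if (policy == "strict") {
    key <- apply_genotype_key(g)
    assignment <- match(key, unique(key))
  } else {
    assignment <- wildcard_components(g)
  }
  names(assignment) <- g$sample_ids
  structure(
    list(site_id = g$site_id, species = g$species,
         assignment = assignment, G = length(unique(assignment)),
         N = n, policy = policy),
    class = "mlg_assignment")
}

apply_genotype_key <- function(g) {
  a1 <- g$allele1; a2 <- g$allele2
  a1[is.na(a1)] <- "\x01NA"
  a2[is.na(a2)] <- "\x01NA"
  apply(matrix(paste(a1, a2, sep = "/"), nrow(a1)), 1L, paste,
        collapse = "|")
}

# missing_wildcard: link samples agreeing at all mutually non-missing loci,
# then take connected components of the link graph
wildcard_components <- function(g) {
  n <- n_samples(g)
  if (n == 1L) return(1L)
  edges <- matrix(integer(0), ncol = 2L)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      both <- !is.na(g$allele1[i, ]) & !is.na(g$allele1[j, ])
      ok <- all(g$allele1[i, both] == g$allele1[j, both] &
                  g$allele2[i, both] == g$allele2[j, both])
      if (ok) edges <- rbind(edges, c(i, j))
    }
  }
  gr <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0L)
    gr <- igraph::add_edges(gr, t(edges))
  comp <- igraph::components(gr)$membership
  # relabel in order of first appearance for stable output
  match(comp, unique(comp))
}

#' @export
print.mlg_assignment <- function(x, ...) {
  cat("MLG assignment: site ", x$site_id, " -- G = ", x$G, " of N = ", x$N,
      " samples (policy: ", x$policy, ")\n", sep = "")
  invisible(x)
}

#' Clonal richness R = (G - 1)/(N - 1)
#'
#' The standard clonal-richness statistic: 0 when the site is monoclonal
#' (G = 1), 1 when every sample is a distinct genet (G = N). Undefined for
#' fewer than two samples.
#'
#' @param a An `mlg_assignment` from [identify_mlgs()].
#' @return A one-row data frame of class `richness_record` with columns
#'   `site_id`, `species`, `N`, `G`, `R`.
#' @examples
#' g <- genotype_matrix("S1", "sp", c("r1", "r2", "r3"), "L1",
#'                      matrix(c("A", "A", "B")), matrix(c("A", "A", "B")))
#' clonal_richness(identify_mlgs(g))  # G = 2, N = 3, R = 0.5
#' @export
clonal_richness <- function(a) {
  stopifnot(inherits(a, "mlg_assignment"))
  if (a$N < 2L)
    stop("clonal richness undefined for N < 2 (site ", a$site_id, ")")
  out <- data.frame(site_id = a$site_id, species = a$species,
                    N = a$N, G = a$G, R = (a$G - 1) / (a$N - 1),
                    stringsAsFactors = FALSE)
  class(out) <- c("richness_record", "data.frame")
  out
}

#' Probability of identity profile over increasing locus combinations
#'
#' For each locus, the probability that two individuals drawn at random
#' under Hardy-Weinberg equilibrium share a genotype is
#' `P_ID = sum_i p_i^4 + sum_{i<j} (2 p_i p_j)^2`. Assuming independent
#' loci, the cumulative P_ID after k loci is the product of the first k
#' per-locus values under the chosen locus order. The expected number of
#' duplicate sample pairs at a site of `n` samples is
#' `choose(n, 2) * P_ID` over all loci.
#'
#' @param f An [allele_frequencies()] table.
#' @param locus_order `"most_informative_first"` (default; ascending
#'   per-locus P_ID, i.e. most discriminating loci first, ties broken by
#'   locus id) or `"given"` (order of appearance in `f`).
#' @param n Number of samples used for the expected-duplicates figure
#'   (optional).
#' @return A data frame of class `pid_profile` with columns `locus`,
#'   `pid_locus`, `pid_cumulative` (non-increasing), plus attributes `n` and
#'   `expected_duplicates` when `n` is given.
#' @examples
#' g <- genotype_matrix("S1", "sp", c("r1", "r2"), "L1",
#'                      matrix(c("A", "B")), matrix(c("B", "A")))
#' probability_of_identity(allele_frequencies(g))  # p = q = 0.5: 0.375
#' @export
probability_of_identity <- function(f,
                                    locus_order = c("most_informative_first",
                                                    "given"),
                                    n = NULL) {
  stopifnot(inherits(f, "data.frame"), nrow(f) > 0L)
  locus_order <- match.arg(locus_order)
  loci <- unique(f$locus)
  per_locus <- vapply(loci, function(lc) {
    p <- f$freq[f$locus == lc]
    if (abs(sum(p) - 1) > 1e-9)
      stop("allele frequencies at locus '", lc, "' do not sum to 1")
    pid_single_locus(p)
  }, numeric(1))
  ord <- switch(locus_order,
                given = seq_along(loci),
                most_informative_first = order(per_locus, loci))
  out <- data.frame(locus = loci[ord], pid_locus = per_locus[ord],
                    pid_cumulative = cumprod(per_locus[ord]),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("pid_profile", "data.frame")
  attr(out, "locus_order") <- locus_order
  if (!is.null(n)) {
    attr(out, "n") <- as.integer(n)
    attr(out, "expected_duplicates") <-
      expected_duplicates(out$pid_cumulative[nrow(out)], n)
  }
  out
}

# single-locus P_ID under HWE from allele frequencies
pid_single_locus <- function(p) {
  sum(p^4) + sum((2 * outer(p, p))[upper.tri(diag(length(p)))]^2)
}

#' Expected number of duplicate genotype pairs
#'
#' `choose(n, 2) * pid`: with `n` samples there are `choose(n, 2)` pairs,
#' each sharing a full multilocus genotype by chance with probability `pid`
#' (the cumulative probability of identity).
#'
#' @param pid Cumulative probability of identity, in (0, 1].
#' @param n Number of samples, at least 2.
#' @return Expected duplicate-pair count (non-negative scalar).
#' @export
expected_duplicates <- function(pid, n) {
  if (n < 2) stop("expected duplicates needs n >= 2")
  if (pid <= 0 || pid > 1) stop("pid must lie in (0, 1]")
  choose(n, 2) * pid
}
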