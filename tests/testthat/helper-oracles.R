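# Shared fixtures and independent oracles used across the suite.

# tiny genotype matrix from character vectors like "A/B", NA for missing
gm_from_calls <- function(calls, site_id = "S1", species = "sp") {
  # calls: list of per-sample character vectors (one element per locus)
  n <- length(calls)
  l <- length(calls[[1L]])
  a1 <- matrix(NA_character_, n, l)
  a2 <- matrix(NA_character_, n, l)
  for (i in seq_len(n)) {
    for (j in seq_len(l)) {
      cl <- calls[[i]][j]
      if (!is.na(cl)) {
        parts <- strsplit(cl, "/", fixed = TRUE)[[1L]]
        a1[i, j] <- parts[1L]
        a2[i, j] <- parts[2L]
      }
    }
  }
  genotype_matrix(site_id, species, sprintf("r%02d", seq_len(n)),
                  sprintf("L%02d", seq_len(l)), a1, a2)
}

# oracle: exhaustive all-pairs strict MLG partition (equality of the full
# normalized genotype vector, missing matching only missing)
oracle_strict_mlg <- function(g) {
  n <- length(g$sample_ids)
  key <- vapply(seq_len(n), function(i) {
    paste(ifelse(is.na(g$allele1[i, ]), ".", g$allele1[i, ]),
          ifelse(is.na(g$allele2[i, ]), ".", g$allele2[i, ]),
          sep = "/", collapse = "|")
  }, character(1))
  match(key, unique(key))
}

# oracle: cumulative P_ID by enumerating all unordered genotypes per locus
# with their HWE probabilities and summing squared probabilities
oracle_pid <- function(freq_list) {
  per_locus <- vapply(freq_list, function(p) {
    k <- length(p)
    tot <- 0
    for (i in seq_len(k)) {
      for (j in i:k) {
        prob <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
        tot <- tot + prob^2
      }
    }
    tot
  }, numeric(1))
  prod(per_locus)
}

# random allele-frequency list: n_loci loci with up to max_alleles alleles
random_freqs <- function(n_loci, max_alleles) {
  lapply(seq_len(n_loci), function(i) {
    k <- sample(2:max_alleles, 1L)
    p <- rgamma(k, 1)
    p <- p / sum(p)
    names(p) <- LETTERS[seq_len(k)]
    p
  })
}

# allele_freq_table data frame from a frequency list
freq_table_from_list <- function(freq_list) {
  out <- do.call(rbind, lapply(seq_along(freq_list), function(i) {
    p <- freq_list[[i]]
    data.frame(locus = sprintf("L%02d", i), allele = names(p),
               freq = as.numeric(p), n_used = 50L,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("allele_freq_table", "data.frame")
  out
}
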