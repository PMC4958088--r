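# Brute-force Hardy-Weinberg oracle for the probability of identity:
# enumerate every unordered diploid genotype, P(match) = sum over genotypes
# of P(genotype)^2. Independent of the closed form used by pid().
hw_match_oracle <- function(p) {
  k <- length(p)
  total <- 0
  for (i in seq_len(k)) for (j in i:k) {
    prob <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    total <- total + prob^2
  }
  unname(total)
}

# small genotype table built directly from genotype strings (one marker per
# column of `cells`, a named list of character vectors)
toy_table <- function(cells) {
  calls <- do.call(cbind, cells)
  colnames(calls) <- names(cells)
  genotype_table(calls)
}

# random frequency vector over `k` alleles (named by synthetic sizes)
random_freqs <- function(k, sizes = 100 + 4 * seq_len(k)) {
  p <- stats::rgamma(k, shape = 1)
  stats::setNames(p / sum(p), sizes)
}

# random small population spec for property tests
random_loci <- function(n_loci, max_alleles = 4) {
  loci <- lapply(seq_len(n_loci), function(i)
    random_freqs(sample(2:max_alleles, 1)))
  stats::setNames(loci, paste0("L", seq_len(n_loci)))
}

# recursive check that child cultivar sets partition the parent set at
# every internal node of a CID
expect_cid_partition <- function(node, expected_codes) {
  if (is.null(node$branches)) {
    expect_setequal(node$cultivars, expected_codes)
    return(invisible(NULL))
  }
  child_sets <- lapply(node$branches, collect_codes)
  all_children <- unlist(child_sets)
  expect_false(anyDuplicated(all_children) > 0)
  expect_setequal(all_children, expected_codes)
  for (i in seq_along(node$branches))
    expect_cid_partition(node$branches[[i]], child_sets[[i]])
}

collect_codes <- function(node) {
  if (is.null(node$branches)) return(node$cultivars)
  unlist(lapply(node$branches, collect_codes), use.names = FALSE)
}
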