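#' Simulate a genotype table from known allele frequencies
#'
#' Draws a random-mating (Hardy-Weinberg) population: each individual
#' receives, at every locus independently, two alleles sampled from the
#' locus's frequency vector — or three with probability
#' `triploid_fraction`, mirroring the rare triploid cultivars found in
#' clonal germplasm panels. Loci are simulated independently, the same
#' assumption under which per-locus probabilities of identity multiply
#' into a panel probability. Simulated tables exercise every stage of the
#' package against known truth: allele-frequency recovery, agreement of
#' the analytic PID with empirical genotype-match rates, and the
#' identification-diagram invariants.
#'
#' @param n number of individuals (>= 1).
#' @param loci named list; each element a named numeric vector of allele
#'   frequencies (names = allele sizes in bp, values summing to 1).
#' @param triploid_fraction probability in \[0, 1) that an individual's
#'   call at a locus is triploid. Triploids draw three independent alleles
#'   from the same frequency vector.
#' @param seed optional integer; when given, the RNG state is set locally
#'   (and restored on exit) so the table is reproducible.
#' @return a [genotype_table()] with individuals coded `1:n`; the
#'   simulation recipe is attached as attribute `"spec"`.
#' @examples
#' gt <- simulate_genotypes(50, list(L1 = c(`100` = 0.5, `104` = 0.5)),
#'                          seed = 1)
#' summarize_markers(gt)
#' @export
simulate_genotypes <- function(n, loci, triploid_fraction = 0, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            triploid_fraction >= 0, triploid_fraction < 1)
  n <- as.integer(n)
  if (!is.list(loci) || length(loci) == 0L || is.null(names(loci)) ||
      anyDuplicated(names(loci)))
    stop("'loci' must be a non-empty named list of frequency vectors",
         call. = FALSE)
  for (m in names(loci)) {
    p <- loci[[m]]
    if (is.null(names(p)) || any(p <= 0) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf(
        "locus '%s': frequencies must be named, positive and sum to 1", m),
        call. = FALSE)
    if (any(!grepl("^[0-9]+$", names(p))))
      stop(sprintf("locus '%s': allele names must be integer sizes", m),
           call. = FALSE)
  }
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(as.integer(seed))
  }
  calls <- matrix("", nrow = n, ncol = length(loci),
                  dimnames = list(NULL, names(loci)))
  for (m in names(loci)) {
    p <- loci[[m]]
    ploidy <- 2L + stats::rbinom(n, 1L, triploid_fraction)
    draws <- as.integer(names(p))[sample.int(length(p), sum(ploidy),
                                             replace = TRUE, prob = p)]
    idx <- rep(seq_len(n), ploidy)
    calls[, m] <- vapply(split(draws, idx), format_genotype, character(1))
  }
  out <- genotype_table(calls,
                        data.frame(code = seq_len(n),
                                   name = paste0("sim", seq_len(n)),
                                   stringsAsFactors = FALSE))
  attr(out, "spec") <- list(n = n, loci = loci,
                            triploid_fraction = triploid_fraction,
                            seed = seed)
  out
}

#' Empirical genotype-match probability
#'
#' The fraction of unordered pairs of individuals sharing identical
#' canonical genotypes at all the named loci — the direct empirical
#' estimator of the (combined) probability of identity, and the
#' simulation-based oracle for the analytic [pid()] formula. Counting is
#' done by tabulating multilocus genotype keys, which yields exactly the
#' number of matching pairs an exhaustive pairwise scan would find.
#'
#' @param x a [genotype_table()] with at least two individuals.
#' @param loci marker names to match on; default all markers of `x`.
#' @return fraction in \[0, 1\].
#' @examples
#' # no two tea cultivars share all six core-marker genotypes
#' empirical_match_probability(tea_genotypes())
#' @export
empirical_match_probability <- function(x, loci = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  if (is.null(loci)) loci <- x$markers
  unknown <- setdiff(loci, x$markers)
  if (length(unknown) > 0L)
    stop("unknown loci: ", paste(unknown, collapse = ", "), call. = FALSE)
  n <- n_cultivars(x)
  if (n < 2L) stop("need at least two individuals", call. = FALSE)
  keys <- apply(x$calls[, loci, drop = FALSE], 1L, paste, collapse = "|")
  counts <- table(keys)
  sum(choose(counts, 2)) / choose(n, 2)
}
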