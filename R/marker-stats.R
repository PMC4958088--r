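#' Allele frequency spectrum of a marker
#'
#' Counts every allele of every call: a diploid call contributes two
#' observations and a triploid call three, so the denominator is the total
#' number of allele copies scored at the locus. This is the only counting
#' rule that uses all observations in a mixed-ploidy table.
#'
#' @param x a [genotype_table()].
#' @param marker marker name.
#' @return object of class `allele_spectrum`: list with `marker`, `freqs`
#'   (named numeric vector of frequencies, names = allele sizes, ascending)
#'   and `n` (number of allele observations).
#' @examples
#' gt <- tea_genotypes()
#' allele_freqs(gt, "TM442")
#' @export
allele_freqs <- function(x, marker) {
  calls <- allele_calls(x, marker)
  if (length(calls) == 0L) stop("empty genotype table", call. = FALSE)
  sizes <- unlist(calls, use.names = FALSE)
  counts <- table(sizes)
  freqs <- as.numeric(counts) / length(sizes)
  names(freqs) <- names(counts)
  structure(list(marker = marker, freqs = freqs, n = length(sizes)),
            class = "allele_spectrum")
}

#' @export
print.allele_spectrum <- function(x, digits = 3, ...) {
  cat(sprintf("Allele spectrum of %s (%d observations):\n", x$marker, x$n))
  print(round(x$freqs, digits))
  invisible(x)
}

# accept an allele_spectrum or bare frequency vector; validate
spectrum_freqs <- function(x) {
  p <- if (inherits(x, "allele_spectrum")) x$freqs else as.numeric(x)
  if (length(p) == 0L || any(p <= 0))
    stop("allele frequencies must be positive", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("allele frequencies must sum to 1", call. = FALSE)
  p
}

#' Probability of identity of a locus
#'
#' The probability that two individuals drawn at random from a
#' Hardy-Weinberg population share the same genotype at the locus,
#' \deqn{PID = 2\left(\sum_i p_i^2\right)^2 - \sum_i p_i^4,}
#' where \eqn{p_i} is the frequency of the i-th allele. Low PID means high
#' discriminating power; a monomorphic locus has PID 1.
#'
#' @param x an [allele_freqs()] spectrum, or a bare numeric vector of
#'   allele frequencies summing to 1.
#' @return PID, a number in (0, 1].
#' @examples
#' pid(c(0.5, 0.5))          # 0.375
#' pid(rep(0.25, 4))         # 0.109375
#' @export
pid <- function(x) {
  p <- spectrum_freqs(x)
  s2 <- sum(p^2)
  2 * s2^2 - sum(p^4)
}

#' Polymorphism information content of a locus
#'
#' Informativeness of a co-dominant marker, in the classical form used by
#' PowerMarker-style software:
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2.}
#'
#' @inheritParams pid
#' @return PIC, a number in \[0, 1).
#' @examples
#' pic(c(0.5, 0.5))   # 0.375
#' pic(rep(0.25, 4))  # 0.703125
#' @export
pic <- function(x) {
  p <- spectrum_freqs(x)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  # sum_{i<j} 2 p_i^2 p_j^2 == (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - s4)
}

#' Observed heterozygosity at a marker
#'
#' Fraction of cultivars whose call carries at least two distinct alleles;
#' triploid calls count as heterozygous whenever their three alleles are
#' not all identical.
#'
#' @inheritParams allele_freqs
#' @return fraction in \[0, 1\].
#' @export
observed_heterozygosity <- function(x, marker) {
  calls <- allele_calls(x, marker)
  mean(vapply(calls, function(a) length(unique(a)) > 1L, logical(1)))
}

#' Genotype classes at a marker
#'
#' Partitions the cultivars by canonical genotype identity (multiset
#' equality of allele sizes) at one marker — the grouping step that drives
#' construction of the identification diagram.
#'
#' @inheritParams allele_freqs
#' @return named list: canonical genotype string -> integer vector of
#'   cultivar codes, ordered by genotype string.
#' @examples
#' cls <- genotype_classes(tea_genotypes(), "TM442")
#' length(cls)       # 9 genotype groups
#' cls[["292/292"]]  # cultivar 15 alone
#' @export
genotype_classes <- function(x, marker) {
  stopifnot(inherits(x, "genotype_table"))
  if (!marker %in% x$markers)
    stop(sprintf("unknown marker '%s'", marker), call. = FALSE)
  g <- x$calls[, marker]
  codes <- as.integer(rownames(x$calls))
  cls <- split(codes, g)
  cls[order(names(cls))]
}

#' Per-marker summary statistics of a genotype table
#'
#' Computes, for every marker, the major allele frequency (MAF), the number
#' of distinct genotypes (NG) and alleles (NA), observed heterozygosity
#' (Ho), polymorphism information content (PIC) and probability of identity
#' (PID).
#'
#' @param x a [genotype_table()].
#' @return data frame of class `marker_stats` with one row per marker and
#'   columns `marker`, `maf`, `ng`, `na`, `ho`, `pic`, `pid`.
#' @examples
#' summarize_markers(tea_genotypes())
#' @export
summarize_markers <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  if (n_cultivars(x) == 0L || length(x$markers) == 0L)
    stop("empty genotype table", call. = FALSE)
  rows <- lapply(x$markers, function(m) {
    sp <- allele_freqs(x, m)
    data.frame(marker = m,
               maf = max(sp$freqs),
               ng = length(genotype_classes(x, m)),
               na = length(sp$freqs),
               ho = observed_heterozygosity(x, m),
               pic = pic(sp),
               pid = pid(sp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("marker_stats", "data.frame")
  out
}

#' @export
print.marker_stats <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  shown <- df
  shown[num] <- lapply(df[num], function(v) signif(v, digits))
  print(shown, row.names = FALSE)
  cat(sprintf("Mean: NA %.1f, NG %.1f, Ho %.3f, PIC %.3f, PID %.3g\n",
              mean(df$na), mean(df$ng), mean(df$ho), mean(df$pic),
              mean(df$pid)))
  invisible(x)
}

#' Write a marker statistics table as CSV
#'
#' Mirrors the column layout of published marker-summary tables
#' (marker, MAF, NG, NA, Ho, PIC, PID) and appends a `Mean` row.
#'
#' @param stats a `marker_stats` data frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_marker_stats <- function(stats, file) {
  df <- as.data.frame(stats)[, c("marker", "maf", "ng", "na", "ho", "pic", "pid")]
  mean_row <- data.frame(marker = "Mean", maf = mean(df$maf), ng = mean(df$ng),
                         na = mean(df$na), ho = mean(df$ho),
                         pic = mean(df$pic), pid = mean(df$pid))
  utils::write.csv(rbind(df, mean_row), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Combined probability of identity of a marker panel
#'
#' Under the assumption that loci segregate independently, the probability
#' that two random individuals share genotypes at every locus of a panel is
#' the product of the per-locus PIDs.
#'
#' @param pids numeric vector of per-locus PID values, each in (0, 1].
#' @return the product, in (0, 1].
#' @examples
#' combined_pid(c(0.192, 0.185, 0.183, 0.180, 0.165, 0.115))  # ~2.22e-5
#' @export
combined_pid <- function(pids) {
  pids <- as.numeric(pids)
  if (length(pids) == 0L)
    stop("at least one per-locus PID is required", call. = FALSE)
  if (any(!is.finite(pids)) || any(pids <= 0) || any(pids > 1))
    stop("per-locus PID values must lie in (0, 1]", call. = FALSE)
  prod(pids)
}

#' Compare computed marker statistics with a published table
#'
#' Recomputing per-locus statistics from a printed genotype table need not
#' reproduce a study's printed statistics exactly (published values may
#' stem from a larger or differently filtered data set). This diagnostic
#' aligns the two tables by marker and reports the differences rather than
#' hiding them.
#'
#' @param computed,reference `marker_stats` data frames (e.g.
#'   [summarize_markers()] output and [tea_marker_stats()]).
#' @param columns statistics to compare.
#' @return data frame with, per marker and statistic, the computed value,
#'   the reference value, and their difference.
#' @examples
#' cmp <- compare_marker_stats(summarize_markers(tea_genotypes()),
#'                             tea_marker_stats())
#' subset(cmp, marker == "TM442")
#' @export
compare_marker_stats <- function(computed, reference,
                                 columns = c("maf", "ng", "na", "ho",
                                             "pic", "pid")) {
  computed <- as.data.frame(computed)
  reference <- as.data.frame(reference)
  shared <- intersect(computed$marker, reference$marker)
  if (length(shared) == 0L)
    stop("no shared markers to compare", call. = FALSE)
  out <- do.call(rbind, lapply(shared, function(m) {
    a <- computed[computed$marker == m, ]
    b <- reference[reference$marker == m, ]
    data.frame(marker = m, statistic = columns,
               computed = as.numeric(a[1, columns]),
               reference = as.numeric(b[1, columns]),
               difference = as.numeric(a[1, columns]) -
                 as.numeric(b[1, columns]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
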