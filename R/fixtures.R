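#' Packaged tea-cultivar study tables
#'
#' Plain-text tables transcribed from a published fingerprinting study of 66
#' elite clonal tea (*Camellia sinensis*) cultivars typed at long-core-motif
#' SSR loci, shipped under `inst/extdata/`:
#'
#' * `tea_cultivars()` — the 66 cultivars: `code` (1-66), `name`, `origin`
#'   (province), and `cpp`, the cultivar processing-property (`O` oolong,
#'   `G` green, `B` black tea; slash-separated when a cultivar suits
#'   several).
#' * `tea_markers()` — the 33-marker screening panel: marker name, linkage
#'   group (LG01-LG15), repeat motif, primer sequences, annealing
#'   temperature (degrees C), fluorescent dye, and a `core` flag marking the
#'   six markers retained for fingerprinting.
#' * `tea_marker_stats()` — published per-locus statistics of the 33
#'   markers: major allele frequency (`maf`), genotype count (`ng`), allele
#'   count (`na`), observed heterozygosity (`ho`), polymorphism information
#'   content (`pic`) and probability of identity (`pid`), preserved exactly
#'   as printed (including the anomalous TM369 `pid` of 8.58e-7, which the
#'   published 33-locus combined probability requires).
#' * `tea_genotypes()` — the 66 x 6 genotype table at the core markers
#'   TM442, TM324, TM351, TM569, TM581 and TM461. Two cultivars (codes 4
#'   and 18) carry three-allele (triploid) calls.
#'
#' Each loader validates the shape of the file (row counts, core-marker
#' count, complete calls) and fails loudly on any mismatch, so silent
#' transcription corruption cannot propagate into analyses.
#'
#' @return `tea_genotypes()` a [genotype_table()]; the others data frames.
#' @examples
#' gt <- tea_genotypes()
#' dim(gt)
#' head(tea_marker_stats())
#' @name tea_fixtures
NULL

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "ssrCID", mustWork = FALSE)
  if (p == "") stop("packaged table '", name, "' not found", call. = FALSE)
  p
}

#' @rdname tea_fixtures
#' @export
tea_cultivars <- function() {
  df <- utils::read.csv(fixture_path("tea_cultivars.csv"),
                        stringsAsFactors = FALSE)
  if (nrow(df) != 66L || !identical(df$code, 1:66))
    stop("cultivar table corrupt: expected codes 1-66", call. = FALSE)
  if (any(df$cpp == "")) stop("cultivar table corrupt: empty processing property",
                              call. = FALSE)
  df
}

#' @rdname tea_fixtures
#' @export
tea_markers <- function() {
  df <- utils::read.csv(fixture_path("tea_markers.csv"),
                        stringsAsFactors = FALSE)
  if (nrow(df) != 33L || anyDuplicated(df$marker))
    stop("marker table corrupt: expected 33 unique markers", call. = FALSE)
  if (sum(df$core) != 6L)
    stop("marker table corrupt: expected 6 core markers", call. = FALSE)
  df
}

#' @rdname tea_fixtures
#' @export
tea_marker_stats <- function() {
  df <- utils::read.csv(fixture_path("tea_marker_stats.csv"),
                        stringsAsFactors = FALSE)
  if (nrow(df) != 33L || anyDuplicated(df$marker))
    stop("marker statistics table corrupt: expected 33 unique rows",
         call. = FALSE)
  needed <- c("marker", "maf", "ng", "na", "ho", "pic", "pid")
  if (!all(needed %in% names(df)))
    stop("marker statistics table corrupt: missing columns", call. = FALSE)
  class(df) <- c("marker_stats", "data.frame")
  df
}

#' @rdname tea_fixtures
#' @export
tea_genotypes <- function() {
  gt <- read_genotype_table(fixture_path("tea_genotypes.csv"))
  if (n_cultivars(gt) != 66L || length(marker_names(gt)) != 6L)
    stop("genotype table corrupt: expected 66 cultivars x 6 markers",
         call. = FALSE)
  tri <- apply(gt$calls, 1, function(r) any(grepl("/[0-9]+/", r)))
  if (!identical(sort(as.integer(names(which(tri)))), c(4L, 18L)))
    stop("genotype table corrupt: triploid calls expected for cultivars 4 and 18",
         call. = FALSE)
  meta <- tea_cultivars()
  gt$cultivars <- merge(gt$cultivars[, "code", drop = FALSE], meta,
                        by = "code", sort = TRUE)
  gt
}
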