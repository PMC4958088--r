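#' Parse a slash-delimited genotype string
#'
#' Fragment-size genotype calls at a co-dominant SSR locus are written as
#' two or three allele sizes (base pairs) joined by `/`, e.g. `"268/292"`
#' for a diploid heterozygote or `"171/177/183"` for a triploid call.
#' Parsing canonicalizes the call: alleles are returned sorted ascending,
#' so `"292/268"` and `"268/292"` denote the same genotype.
#'
#' @param text a single genotype string.
#' @return integer vector of 2 or 3 allele sizes, sorted ascending.
#' @seealso [format_genotype()], the inverse operation.
#' @examples
#' parse_genotype("292/268")      # 268 292
#' parse_genotype("171/177/183")  # triploid call
#' @export
parse_genotype <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("genotype must be a single character string", call. = FALSE)
  tokens <- strsplit(trimws(text), "/", fixed = TRUE)[[1L]]
  if (length(tokens) < 2L || length(tokens) > 3L)
    stop(sprintf("genotype '%s' must contain 2 or 3 alleles, found %d",
                 text, length(tokens)), call. = FALSE)
  if (!all(grepl("^[0-9]+$", tokens)))
    stop(sprintf("genotype '%s' contains a non-integer allele size", text),
         call. = FALSE)
  sizes <- as.integer(tokens)
  if (any(sizes <= 0L))
    stop(sprintf("genotype '%s' contains a non-positive allele size", text),
         call. = FALSE)
  sort(sizes)
}

#' Format an allele-size vector as a genotype string
#'
#' @param alleles integer vector of 2 or 3 positive allele sizes.
#' @return canonical string `"a/b"` or `"a/b/c"` with sizes ascending.
#' @examples
#' format_genotype(c(292, 268))  # "268/292"
#' @export
format_genotype <- function(alleles) {
  alleles <- as.integer(alleles)
  if (length(alleles) < 2L || length(alleles) > 3L || any(is.na(alleles)) ||
      any(alleles <= 0L))
    stop("a genotype holds 2 or 3 positive allele sizes", call. = FALSE)
  paste(sort(alleles), collapse = "/")
}

# canonicalize one cell, reporting its table position on failure
canonical_call <- function(text, cultivar, marker) {
  tryCatch(format_genotype(parse_genotype(text)),
           error = function(e) stop(sprintf(
             "invalid genotype for cultivar %s at marker %s: %s",
             cultivar, marker, conditionMessage(e)), call. = FALSE))
}

#' Construct a genotype table
#'
#' A genotype table is the central data container: a cultivars x markers
#' matrix of canonical genotype calls plus cultivar metadata. Every cell
#' must hold a valid 2- or 3-allele call; missing data is an error, not a
#' state, so transcription gaps surface immediately.
#'
#' @param calls character matrix of genotype strings; one row per cultivar,
#'   one column per marker (column names are marker names).
#' @param cultivars data frame with at least columns `code` (unique integer
#'   identifiers) and `name`; one row per row of `calls`. Defaults to codes
#'   `1:nrow(calls)` with empty names.
#' @return an object of class `genotype_table`: a list with elements
#'   `calls` (canonical call matrix, rownames = cultivar codes),
#'   `cultivars` (metadata data frame) and `markers` (character vector).
#' @examples
#' gt <- genotype_table(
#'   matrix(c("268/292", "286/286"), ncol = 1,
#'          dimnames = list(NULL, "TM442")),
#'   data.frame(code = 1:2, name = c("a", "b")))
#' gt
#' @export
genotype_table <- function(calls, cultivars = NULL) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("'calls' must be a character matrix", call. = FALSE)
  markers <- colnames(calls)
  if (is.null(markers) || anyDuplicated(markers) || any(markers == ""))
    stop("'calls' needs unique, non-empty marker column names", call. = FALSE)
  if (is.null(cultivars))
    cultivars <- data.frame(code = seq_len(nrow(calls)),
                            name = rep("", nrow(calls)))
  if (!is.data.frame(cultivars) || !all(c("code", "name") %in% names(cultivars)))
    stop("'cultivars' must be a data frame with 'code' and 'name' columns",
         call. = FALSE)
  if (nrow(cultivars) != nrow(calls))
    stop("'cultivars' and 'calls' disagree on the number of cultivars",
         call. = FALSE)
  codes <- cultivars$code
  if (anyDuplicated(codes))
    stop("duplicate cultivar codes: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  if (nrow(calls) > 0L) {
    for (j in seq_along(markers))
      for (i in seq_len(nrow(calls)))
        calls[i, j] <- canonical_call(calls[i, j], codes[i], markers[j])
  }
  rownames(calls) <- as.character(codes)
  rownames(cultivars) <- NULL
  structure(list(calls = calls, cultivars = cultivars, markers = markers),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d cultivars x %d markers\n",
              nrow(x$calls), length(x$markers)))
  cat("Markers:", paste(x$markers, collapse = ", "), "\n")
  n_tri <- sum(grepl("^[0-9]+/[0-9]+/[0-9]+$", x$calls))
  if (n_tri > 0) cat(sprintf("Triploid calls: %d\n", n_tri))
  n_show <- min(6L, nrow(x$calls))
  if (n_show > 0) {
    df <- as.data.frame(x)
    print(utils::head(df, n_show))
    if (nrow(df) > n_show) cat("... with", nrow(df) - n_show, "more cultivars\n")
  }
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

#' @export
as.data.frame.genotype_table <- function(x, ...) {
  cbind(x$cultivars[, c("code", "name")],
        as.data.frame(x$calls, stringsAsFactors = FALSE),
        row.names = NULL)
}

#' Number of cultivars / marker names of a genotype table
#'
#' @param x a `genotype_table`.
#' @return `n_cultivars()` the number of cultivars; `marker_names()` the
#'   marker names in column order.
#' @export
n_cultivars <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  nrow(x$calls)
}

#' @rdname n_cultivars
#' @export
marker_names <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  x$markers
}

# allele vectors (sorted integer) for one marker, named by cultivar code
allele_calls <- function(x, marker) {
  stopifnot(inherits(x, "genotype_table"))
  if (!marker %in% x$markers)
    stop(sprintf("unknown marker '%s'", marker), call. = FALSE)
  lapply(stats::setNames(x$calls[, marker], rownames(x$calls)),
         function(g) as.integer(strsplit(g, "/", fixed = TRUE)[[1L]]))
}

#' Read a genotype table from a delimited file
#'
#' Expects the wide layout used throughout the package: a header row with
#' `code`, `name` and then one column per marker; one row per cultivar with
#' genotype cells `"a/b"` or `"a/b/c"` (allele sizes in bp). Reading is the
#' inverse of [write_genotype_table()].
#'
#' @param file path to a CSV/TSV file (or a connection).
#' @param sep field separator, default `","`.
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(file, sep = ",") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("code", "name")))
    stop("genotype file must start with 'code' and 'name' columns followed ",
         "by at least one marker column", call. = FALSE)
  markers <- names(df)[-(1:2)]
  if (anyDuplicated(markers))
    stop("duplicate marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  if (any(!grepl("^[0-9]+$", df$code)))
    stop("cultivar codes must be integers", call. = FALSE)
  calls <- as.matrix(df[, markers, drop = FALSE])
  if (any(is.na(calls) | trimws(calls) == "")) {
    bad <- which(is.na(calls) | trimws(calls) == "", arr.ind = TRUE)[1, ]
    stop(sprintf("empty genotype cell for cultivar %s at marker %s",
                 df$code[bad[1]], markers[bad[2]]), call. = FALSE)
  }
  genotype_table(calls,
                 data.frame(code = as.integer(df$code), name = df$name,
                            stringsAsFactors = FALSE))
}

#' Write a genotype table to a delimited file
#'
#' @param x a `genotype_table`.
#' @param file output path (or connection).
#' @param sep field separator, default `","`.
#' @return `file`, invisibly. `read_genotype_table()` on the written file
#'   reproduces `x` exactly.
#' @export
write_genotype_table <- function(x, file, sep = ",") {
  stopifnot(inherits(x, "genotype_table"))
  df <- as.data.frame(x)
  utils::write.table(df, file, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}
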