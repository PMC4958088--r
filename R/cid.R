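#' Fit a cultivar identification diagram
#'
#' A cultivar identification diagram (CID) is a decision tree that
#' fingerprints clonal cultivars with as few markers as possible. The
#' markers are consumed in a fixed global order (conventionally descending
#' probability of identity, so that genotyping starts with the assay most
#' panels would run first): the root partitions all cultivars by their
#' genotype at the first marker; any group still containing several
#' cultivars is split again by the next marker, and so on. A cultivar whose
#' genotype is unique at some prefix of the marker order becomes a resolved
#' singleton leaf at that depth; a group that shares genotypes at every
#' marker ends as a flagged *unresolved* leaf (more markers would be needed
#' — see [add_cultivar()] for how such collisions appear when panels grow).
#'
#' @param x a [genotype_table()].
#' @param markers marker order for the diagram. Defaults to all markers of
#'   `x` sorted by descending PID (computed via [summarize_markers()] when
#'   `stats` is not given), ties broken by marker name.
#' @param stats optional `marker_stats` table supplying the `pid` column
#'   used to order the markers (e.g. a published table); ignored when
#'   `markers` is given.
#' @return an object of class `cid`: list with elements `root` (the
#'   recursive node structure), `markers` (the order used), `calls`
#'   (canonical call matrix), `cultivars` (metadata). Nodes are lists with
#'   `marker` and `branches` (internal; branches named by canonical
#'   genotype string, ascending) or `cultivars` (leaf; integer codes).
#' @seealso [predict.cid()] to identify samples, [summary.cid()] for
#'   per-cultivar paths, [add_cultivar()], [cid_to_json()], [cid_to_dot()].
#' @examples
#' fit <- cid(tea_genotypes())
#' fit
#' predict(fit, c(TM442 = "268/286", TM324 = "171/171"))
#' @export
cid <- function(x, markers = NULL, stats = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  if (n_cultivars(x) == 0L) stop("empty genotype table", call. = FALSE)
  if (is.null(markers)) {
    if (is.null(stats)) stats <- summarize_markers(x)
    df <- as.data.frame(stats)
    df <- df[df$marker %in% x$markers, ]
    markers <- df$marker[order(-df$pid, df$marker)]
  }
  markers <- as.character(markers)
  if (length(markers) == 0L) stop("empty marker order", call. = FALSE)
  missing <- setdiff(markers, x$markers)
  if (length(missing) > 0L)
    stop("markers absent from the genotype table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  codes <- as.integer(rownames(x$calls))
  root <- build_cid_node(x$calls, codes, markers, 1L)
  structure(list(root = root, markers = markers,
                 calls = x$calls[, markers, drop = FALSE],
                 cultivars = x$cultivars),
            class = "cid")
}

# recursive splitter: partition `codes` by genotype at markers[idx];
# singleton groups -> resolved leaves, exhausted groups -> unresolved leaves
build_cid_node <- function(calls, codes, markers, idx) {
  # a cultivar is "identified" only after at least one marker is read, so
  # singleton leaves appear from depth 1 onward
  if (idx > length(markers) || (length(codes) == 1L && idx > 1L))
    return(list(cultivars = sort(codes)))
  m <- markers[idx]
  groups <- split(codes, calls[as.character(codes), m])
  groups <- groups[order(names(groups))]
  branches <- lapply(groups, function(g)
    build_cid_node(calls, g, markers, idx + 1L))
  list(marker = m, branches = branches)
}

is_leaf <- function(node) is.null(node$branches)

# flat data frame of leaves: code, depth, resolved
walk_leaves <- function(node, depth = 0L) {
  if (is_leaf(node))
    return(data.frame(code = node$cultivars, depth = depth,
                      resolved = length(node$cultivars) == 1L))
  do.call(rbind, lapply(node$branches, walk_leaves, depth = depth + 1L))
}

#' @export
print.cid <- function(x, ...) {
  leaves <- walk_leaves(x$root)
  cat("Cultivar identification diagram\n")
  cat(sprintf("  %d cultivars, marker order: %s\n", nrow(x$calls),
              paste(x$markers, collapse = " > ")))
  cat(sprintf("  root genotype groups: %d\n", length(x$root$branches)))
  cat(sprintf("  resolved: %d cultivars; unresolved: %d cultivars in %d groups\n",
              sum(leaves$resolved), sum(!leaves$resolved),
              length(unresolved_groups(x$root))))
  cat(sprintf("  markers needed per cultivar: %d-%d (mean %.2f)\n",
              min(leaves$depth), max(leaves$depth), mean(leaves$depth)))
  invisible(x)
}

#' Summarize a cultivar identification diagram
#'
#' Tabulates, per cultivar, the depth at which it resolves (= number of
#' markers that must be genotyped) and the markers on its path, and
#' collects any unresolved groups.
#'
#' @param object a [cid()] fit.
#' @param ... unused.
#' @return object of class `summary.cid`: list with `paths` (data frame:
#'   `code`, `name`, `depth`, `markers`, `resolved`), `unresolved` (list of
#'   code vectors sharing all marker genotypes), `markers`, and
#'   `n_root_groups`.
#' @export
summary.cid <- function(object, ...) {
  leaves <- collect_paths(object$root, character(0))
  leaves <- leaves[order(leaves$code), ]
  leaves$name <- object$cultivars$name[match(leaves$code,
                                             object$cultivars$code)]
  leaves <- leaves[, c("code", "name", "depth", "markers", "resolved")]
  rownames(leaves) <- NULL
  unresolved <- unresolved_groups(object$root)
  structure(list(paths = leaves, unresolved = unresolved,
                 markers = object$markers,
                 n_root_groups = length(object$root$branches)),
            class = "summary.cid")
}

collect_paths <- function(node, path) {
  if (is_leaf(node))
    return(data.frame(code = node$cultivars, depth = length(path),
                      markers = paste(path, collapse = ","),
                      resolved = length(node$cultivars) == 1L,
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(node$branches, collect_paths,
                        path = c(path, node$marker)))
}

unresolved_groups <- function(node) {
  if (is_leaf(node)) {
    if (length(node$cultivars) > 1L) return(list(node$cultivars))
    return(list())
  }
  do.call(c, lapply(node$branches, unresolved_groups))
}

#' @export
print.summary.cid <- function(x, ...) {
  cat(sprintf("CID over %d cultivars, marker order %s\n",
              nrow(x$paths), paste(x$markers, collapse = " > ")))
  cat(sprintf("Root splits into %d genotype groups\n", x$n_root_groups))
  by_depth <- table(x$paths$depth)
  cat("Cultivars resolving per depth:\n")
  print(by_depth)
  if (length(x$unresolved) > 0L) {
    cat("Unresolved groups (share genotypes at all markers):\n")
    for (g in x$unresolved) cat(" ", paste(g, collapse = ", "), "\n")
  } else cat("All cultivars uniquely resolved.\n")
  invisible(x)
}

canonicalize_sample <- function(genotypes) {
  if (is.list(genotypes))
    genotypes <- vapply(genotypes, function(g)
      if (is.character(g)) g else format_genotype(g), character(1))
  if (!is.character(genotypes) || is.null(names(genotypes)))
    stop("'genotypes' must be a named character vector or list ",
         "(marker -> genotype)", call. = FALSE)
  vapply(names(genotypes), function(m)
    canonical_call(genotypes[[m]], "sample", m), character(1))
}

#' Identify a sample with a cultivar identification diagram
#'
#' Routes a sample's genotypes down the diagram. Traversal is lazy: only
#' the markers actually on the path need to be supplied, so a sample
#' resolving at depth 2 is identified from two genotypes. The outcome is
#' `"unique"` (a single cultivar), `"ambiguous"` (an unresolved leaf was
#' reached; all its cultivars are returned as candidates) or `"no_match"`
#' (the sample's genotype at some marker matches no branch — the sample is
#' not in the diagram).
#'
#' @param object a [cid()] fit.
#' @param genotypes named character vector or list mapping marker name to
#'   genotype (string `"a/b"` or allele-size vector). A missing genotype
#'   for a marker on the path is an error naming that marker.
#' @param ... unused.
#' @return object of class `cid_identification`: list with `outcome`,
#'   `cultivar` (code, for unique outcomes), `name`, `candidates` (codes),
#'   and `path` (data frame of consumed `marker`/`genotype` pairs).
#' @examples
#' fit <- cid(tea_genotypes())
#' predict(fit, c(TM442 = "268/286", TM324 = "171/171"))  # Yin Shuang
#' @export
predict.cid <- function(object, genotypes, ...) {
  sample <- canonicalize_sample(genotypes)
  node <- object$root
  path_markers <- character(0)
  path_genotypes <- character(0)
  while (!is_leaf(node)) {
    m <- node$marker
    if (!m %in% names(sample))
      stop(sprintf("genotype for marker %s is required at this step", m),
           call. = FALSE)
    g <- sample[[m]]
    path_markers <- c(path_markers, m)
    path_genotypes <- c(path_genotypes, g)
    nxt <- node$branches[[g]]
    if (is.null(nxt)) {
      return(structure(list(outcome = "no_match", cultivar = NA_integer_,
                            name = NA_character_, candidates = integer(0),
                            path = data.frame(marker = path_markers,
                                              genotype = path_genotypes)),
                       class = "cid_identification"))
    }
    node <- nxt
  }
  codes <- node$cultivars
  unique_hit <- length(codes) == 1L
  structure(list(
    outcome = if (unique_hit) "unique" else "ambiguous",
    cultivar = if (unique_hit) codes else NA_integer_,
    name = if (unique_hit)
      object$cultivars$name[match(codes, object$cultivars$code)]
    else NA_character_,
    candidates = codes,
    path = data.frame(marker = path_markers, genotype = path_genotypes)),
    class = "cid_identification")
}

#' @export
print.cid_identification <- function(x, ...) {
  switch(x$outcome,
    unique = cat(sprintf("Unique match: cultivar %d (%s)\n", x$cultivar,
                         x$name)),
    ambiguous = cat("Ambiguous: candidates", paste(x$candidates,
                                                   collapse = ", "), "\n"),
    no_match = cat("No match: sample is not in the diagram\n"))
  if (nrow(x$path) > 0)
    cat("Path:", paste(sprintf("%s=%s", x$path$marker, x$path$genotype),
                       collapse = " -> "), "\n")
  invisible(x)
}

#' Insert a new cultivar into an existing identification diagram
#'
#' New clonal releases are genotyped at the same core markers and routed
#' down the diagram. A genotype unseen at some node simply becomes a new
#' branch; colliding with a resolved leaf turns that leaf into an internal
#' node split by the next unused marker; if the newcomer shares every
#' marker genotype with an existing cultivar the leaf becomes (or remains)
#' an unresolved group — the signal that the panel needs another marker.
#'
#' @param object a [cid()] fit.
#' @param code new, unused cultivar code.
#' @param genotypes named vector/list with a genotype for **every** marker
#'   of the diagram.
#' @param name optional cultivar name.
#' @return the updated `cid` object. Identical to refitting [cid()] on the
#'   extended genotype table with the same marker order.
#' @export
add_cultivar <- function(object, code, genotypes, name = "") {
  stopifnot(inherits(object, "cid"))
  code <- as.integer(code)
  if (code %in% object$cultivars$code)
    stop(sprintf("cultivar code %d already present", code), call. = FALSE)
  sample <- canonicalize_sample(genotypes)
  missing <- setdiff(object$markers, names(sample))
  if (length(missing) > 0L)
    stop("genotypes required for all diagram markers; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  calls <- rbind(object$calls, sample[object$markers])
  rownames(calls) <- c(rownames(object$calls), as.character(code))
  object$calls <- calls
  object$cultivars <- rbind(
    object$cultivars[, c("code", "name")],
    data.frame(code = code, name = name, stringsAsFactors = FALSE))
  object$root <- insert_code(object$root, calls, code, object$markers, 1L)
  object
}

insert_code <- function(node, calls, code, markers, idx) {
  if (is_leaf(node)) {
    # collision: re-split this leaf (plus the newcomer) on the remaining
    # markers; with all markers consumed this yields an unresolved leaf
    return(build_cid_node(calls, c(node$cultivars, code), markers, idx))
  }
  g <- calls[as.character(code), node$marker]
  if (is.null(node$branches[[g]])) {
    node$branches[[g]] <- list(cultivars = code)
    node$branches <- node$branches[order(names(node$branches))]
  } else {
    node$branches[[g]] <- insert_code(node$branches[[g]], calls, code,
                                      markers, idx + 1L)
  }
  node
}
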