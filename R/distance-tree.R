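#' Within-individual allele profile
#'
#' Expresses one cultivar's call at each marker as allele shares: 1/2 each
#' for a diploid heterozygote, 1 for a homozygote, 1/3 each for a triploid
#' call (duplicated alleles accumulate). These profiles bridge individual
#' genotypes to allele-frequency-based genetic distances.
#'
#' @param x a [genotype_table()].
#' @param code cultivar code present in `x`.
#' @return named list, one element per marker: named numeric vector of
#'   allele shares summing to 1.
#' @export
allele_profile <- function(x, code) {
  stopifnot(inherits(x, "genotype_table"))
  key <- as.character(code)
  if (!key %in% rownames(x$calls))
    stop(sprintf("unknown cultivar code '%s'", code), call. = FALSE)
  out <- lapply(x$markers, function(m) {
    a <- as.integer(strsplit(x$calls[key, m], "/", fixed = TRUE)[[1L]])
    tab <- table(a)
    stats::setNames(as.numeric(tab) / length(a), names(tab))
  })
  stats::setNames(out, x$markers)
}

# profiles as a dense individuals x (marker:allele) share matrix
profile_matrix <- function(x) {
  cols <- unlist(lapply(x$markers, function(m) {
    sizes <- sort(unique(unlist(allele_calls(x, m), use.names = FALSE)))
    paste0(m, ":", sizes)
  }))
  mat <- matrix(0, nrow = nrow(x$calls), ncol = length(cols),
                dimnames = list(rownames(x$calls), cols))
  for (i in seq_len(nrow(x$calls))) {
    prof <- allele_profile(x, rownames(x$calls)[i])
    for (m in x$markers)
      mat[i, paste0(m, ":", names(prof[[m]]))] <- prof[[m]]
  }
  mat
}

#' Pairwise genetic distances between cultivars
#'
#' Computes a distance matrix over the cultivars' allele profiles.
#' `method = "nei"` (default) is Nei's standard genetic distance with
#' allele shares pooled across loci,
#' \deqn{D = -\ln \frac{\sum_l \sum_a x_{la} y_{la}}
#'   {\sqrt{\sum_l \sum_a x_{la}^2 \; \sum_l \sum_a y_{la}^2}},}
#' applied to individuals rather than populations. `method = "share"` is
#' the allele-sharing distance `1 - mean per-locus shared proportion`,
#' where the shared proportion at a locus is \eqn{\sum_a \min(x_a, y_a)}.
#' Two cultivars with identical multilocus genotypes are at distance 0
#' under both; `"nei"` is infinite for a pair sharing no allele anywhere,
#' `"share"` reaches at most 1.
#'
#' @param x a [genotype_table()] with at least two cultivars.
#' @param method `"nei"` or `"share"`.
#' @return a [stats::dist] object labelled by cultivar code.
#' @examples
#' d <- nei_dist(tea_genotypes())
#' summary(as.vector(d))
#' @export
nei_dist <- function(x, method = c("nei", "share")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "genotype_table"))
  if (n_cultivars(x) < 2L)
    stop("need at least two cultivars", call. = FALSE)
  mat <- profile_matrix(x)
  if (method == "nei") {
    cross <- mat %*% t(mat)
    self <- diag(cross)
    sim <- cross / sqrt(outer(self, self))
    d <- -log(pmin(sim, 1))
  } else {
    n <- nrow(mat)
    d <- matrix(0, n, n, dimnames = dimnames(mat)[c(1, 1)])
    nloci <- length(x$markers)
    marker_of <- sub(":.*$", "", colnames(mat))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      shared <- sum(pmin(mat[i, ], mat[j, ])) / nloci
      d[i, j] <- d[j, i] <- 1 - shared
    }
  }
  stats::as.dist(d)
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering: the height of each merge is
#' the mean distance between the two clusters joined, so the result is
#' ultrametric. A thin wrapper over [stats::hclust()] that keeps the input
#' labels and tags the result for the package's tree utilities.
#'
#' @param d a [stats::dist] object (e.g. from [nei_dist()]).
#' @return an object of classes `upgma` and [stats::hclust].
#' @examples
#' hc <- upgma(nei_dist(tea_genotypes()))
#' length(cut_tree(hc, 0.25))
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) stop("'d' must be a 'dist' object", call. = FALSE)
  if (attr(d, "Size") < 2L) stop("need at least two taxa", call. = FALSE)
  hc <- stats::hclust(d, method = "average")
  class(hc) <- c("upgma", "hclust")
  hc
}

#' Cut an UPGMA dendrogram at a height
#'
#' @param tree an [upgma()] tree (or any `hclust`).
#' @param height non-negative cut height on the merge-distance scale.
#' @return list of character vectors of leaf labels; the clusters connected
#'   below the cut, together a partition of all leaves.
#' @export
cut_tree <- function(tree, height) {
  stopifnot(inherits(tree, "hclust"), height >= 0)
  grp <- stats::cutree(tree, h = height)
  unname(split(names(grp), grp))
}

#' Export an UPGMA tree as Newick text
#'
#' Branch lengths follow the ultrametric convention: each merge at height
#' `h` places its children at depth `h/2` from the node, so leaf-to-leaf
#' path lengths equal the merge heights.
#'
#' @param tree an [upgma()] tree (or any `hclust`).
#' @param file optional path; when given the Newick string is also written
#'   there.
#' @return Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
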