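#' Serialize a cultivar identification diagram
#'
#' `cid_to_json()` writes the complete fit (marker order, cultivar table,
#' calls and tree) as JSON; [cid_from_json()] restores an equivalent
#' object. `cid_to_dot()` renders the tree as a Graphviz DOT digraph with
#' genotype-labelled edges, internal nodes labelled by marker and leaves by
#' cultivar code (unresolved leaves are marked). `render_cid()` dispatches
#' between the text, DOT and JSON forms. Branch order is deterministic
#' (genotype string ascending), so serializations are byte-stable.
#'
#' @param object a [cid()] fit.
#' @param file optional output path; when given the text is written there.
#' @return a character string (JSON, DOT, or indented text), invisibly when
#'   `file` is given.
#' @examples
#' fit <- cid(tea_genotypes())
#' fit2 <- cid_from_json(cid_to_json(fit))
#' identical(fit$root, fit2$root)
#' @export
cid_to_json <- function(object, file = NULL) {
  stopifnot(inherits(object, "cid"))
  payload <- list(
    markers = object$markers,
    cultivars = object$cultivars[, c("code", "name")],
    calls = as.data.frame(object$calls, stringsAsFactors = FALSE),
    root = node_to_list(object$root))
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  txt <- as.character(txt)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

node_to_list <- function(node) {
  if (is_leaf(node))
    return(list(kind = "leaf", cultivars = node$cultivars,
                resolved = length(node$cultivars) == 1L))
  list(kind = "internal", marker = node$marker,
       branches = lapply(node$branches, node_to_list))
}

#' Restore a cultivar identification diagram from JSON
#'
#' @param json JSON text produced by [cid_to_json()], or a path to a file
#'   containing it.
#' @return a `cid` object.
#' @rdname cid_to_json
#' @export
cid_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  markers <- as.character(unlist(payload$markers))
  cultivars <- data.frame(
    code = vapply(payload$cultivars, function(r) as.integer(r$code),
                  integer(1)),
    name = vapply(payload$cultivars, function(r) as.character(r$name),
                  character(1)),
    stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(payload$calls, function(r)
    vapply(markers, function(m) as.character(r[[m]]), character(1))))
  rownames(calls) <- as.character(cultivars$code)
  structure(list(root = list_to_node(payload$root), markers = markers,
                 calls = calls, cultivars = cultivars),
            class = "cid")
}

list_to_node <- function(lst) {
  if (identical(lst$kind, "leaf"))
    return(list(cultivars = vapply(lst$cultivars, as.integer, integer(1))))
  list(marker = lst$marker, branches = lapply(lst$branches, list_to_node))
}

#' @rdname cid_to_json
#' @export
cid_to_dot <- function(object, file = NULL) {
  stopifnot(inherits(object, "cid"))
  lines <- c("digraph CID {", "  node [shape=box];")
  counter <- new.env()
  counter$i <- 0L
  emit <- function(node) {
    counter$i <- counter$i + 1L
    id <- sprintf("n%d", counter$i)
    if (is_leaf(node)) {
      label <- paste(node$cultivars, collapse = ", ")
      style <- if (length(node$cultivars) > 1L)
        ", style=filled, fillcolor=lightgrey" else ""
      lines <<- c(lines, sprintf("  %s [label=\"%s\"%s];", id, label, style))
    } else {
      lines <<- c(lines, sprintf("  %s [label=\"%s\"];", id, node$marker))
      for (g in names(node$branches)) {
        child <- emit(node$branches[[g]])
        lines <<- c(lines, sprintf("  %s -> %s [label=\"%s\"];", id, child, g))
      }
    }
    id
  }
  emit(object$root)
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @param format one of `"text"`, `"dot"`, `"json"`.
#' @rdname cid_to_json
#' @export
render_cid <- function(object, format = c("text", "dot", "json"),
                       file = NULL) {
  format <- match.arg(format)
  switch(format,
         text = cid_to_text(object, file),
         dot = cid_to_dot(object, file),
         json = cid_to_json(object, file))
}

cid_to_text <- function(object, file = NULL) {
  lines <- character(0)
  walk <- function(node, prefix) {
    if (is_leaf(node)) {
      tag <- if (length(node$cultivars) > 1L) " [unresolved]" else ""
      lines <<- c(lines, sprintf("%s-> cultivar(s) %s%s", prefix,
                                 paste(node$cultivars, collapse = ", "), tag))
    } else {
      for (g in names(node$branches)) {
        lines <<- c(lines, sprintf("%s%s = %s", prefix, node$marker, g))
        walk(node$branches[[g]], paste0(prefix, "  "))
      }
    }
  }
  walk(object$root, "")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Plot a cultivar identification diagram
#'
#' Draws the decision tree with base graphics: internal nodes show the
#' splitting marker, edges the genotype, leaves the cultivar code(s).
#' Intended for small diagrams or subtrees; for the full 66-cultivar tea
#' diagram the DOT export ([cid_to_dot()]) scales better.
#'
#' @param x a [cid()] fit.
#' @param cex text size.
#' @param ... further arguments passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.cid <- function(x, cex = 0.7, ...) {
  nodes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      label = character(0), leaf = logical(0))
  edges <- data.frame(from = integer(0), to = integer(0),
                      label = character(0))
  counter <- new.env(); counter$i <- 0L; counter$leaf_x <- 0
  layout <- function(node, depth) {
    counter$i <- counter$i + 1L
    id <- counter$i
    if (is_leaf(node)) {
      counter$leaf_x <- counter$leaf_x + 1
      nodes[nrow(nodes) + 1L, ] <<- list(id, counter$leaf_x, -depth,
                                         paste(node$cultivars,
                                               collapse = ","), TRUE)
    } else {
      kids <- integer(0)
      for (g in names(node$branches)) {
        kid <- layout(node$branches[[g]], depth + 1)
        edges[nrow(edges) + 1L, ] <<- list(id, kid, g)
        kids <- c(kids, kid)
      }
      xs <- nodes$x[match(kids, nodes$id)]
      nodes[nrow(nodes) + 1L, ] <<- list(id, mean(xs), -depth,
                                         node$marker, FALSE)
    }
    id
  }
  layout(x$root, 0)
  graphics::plot(nodes$x, nodes$y, type = "n", axes = FALSE, xlab = "",
                 ylab = "", ...)
  for (k in seq_len(nrow(edges))) {
    a <- nodes[match(edges$from[k], nodes$id), ]
    b <- nodes[match(edges$to[k], nodes$id), ]
    graphics::segments(a$x, a$y, b$x, b$y, col = "grey50")
    graphics::text((a$x + b$x) / 2, (a$y + b$y) / 2, edges$label[k],
                   cex = cex * 0.85, col = "grey30")
  }
  graphics::text(nodes$x, nodes$y, nodes$label, cex = cex,
                 font = ifelse(nodes$leaf, 1, 2))
  invisible(x)
}
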