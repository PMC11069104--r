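# The glycan graph container and its canonical serialization.
#
# A glycan_graph is a rooted tree over 2k-1 nodes for k monosaccharides:
# monosaccharide and linkage nodes strictly alternate, every linkage node
# has exactly one child (the donor residue) and one parent (the acceptor
# residue), and the root is the reducing-end residue. Node indices are
# 1-based and equal the token position in the canonical string, so the i-th
# token of to_string(g) is node i.

# --- canonical ordering ------------------------------------------------------

# residue depth of a subtree (monosaccharides on the longest path)
res_depth <- function(node) {
  if (length(node$children) == 0L) return(1L)
  1L + max(vapply(node$children, function(ch) res_depth(ch$child), integer(1L)))
}

# At each branch point the main chain (serialized outside parentheses) is
# the longest branch; ties broken by lowest acceptor carbon, then by residue
# token. This convention is this package's own: IUPAC-condensed does not fix
# a branch order, and a deterministic one is needed for round-tripping.
canonical_order <- function(node) {
  if (length(node$children) == 0L) return(node)
  node$children <- lapply(node$children, function(ch) {
    ch$child <- canonical_order(ch$child)
    ch
  })
  depth <- vapply(node$children, function(ch) res_depth(ch$child), integer(1L))
  cto <- vapply(node$children, function(ch) {
    ct <- ch$link$c_to
    if (all(is.na(ct))) 99L else min(ct, na.rm = TRUE)
  }, integer(1L))
  lab <- vapply(node$children, function(ch) ch$child$label, character(1L))
  node$children <- node$children[order(-depth, cto, lab)]
  node
}

# --- graph construction ------------------------------------------------------

# Emit tokens of a canonically ordered tree depth-first in string order
# (main chain, then each further branch parenthesized, then the residue),
# assigning node indices as tokens are emitted.
build_glycan_graph <- function(tree) {
  acc <- new.env(parent = emptyenv())
  acc$label <- character()
  acc$type <- character()
  acc$linkage <- list()
  acc$parent <- integer()
  acc$orig <- integer()
  acc$str <- character()

  push <- function(label, type, linkage, orig) {
    i <- length(acc$label) + 1L
    acc$label[i] <- label
    acc$type[i] <- type
    acc$linkage[[i]] <- if (is.null(linkage)) list(NULL) else linkage
    acc$parent[i] <- NA_integer_
    acc$orig[i] <- orig
    acc$str[length(acc$str) + 1L] <- label
    i
  }
  punct <- function(ch) acc$str[length(acc$str) + 1L] <- ch

  emit_node <- function(node) {
    link_idx <- integer()
    k <- length(node$children)
    if (k >= 1L) {
      ch <- node$children[[1L]]
      ci <- emit_node(ch$child)
      li <- push(format_linkage(ch$link), "link", ch$link,
                 if (is.null(ch$link_orig)) NA_integer_ else ch$link_orig)
      acc$parent[ci] <- li
      link_idx <- c(link_idx, li)
      if (k >= 2L) {
        for (j in 2:k) {
          ch <- node$children[[j]]
          punct("(")
          cj <- emit_node(ch$child)
          lj <- push(format_linkage(ch$link), "link", ch$link,
                     if (is.null(ch$link_orig)) NA_integer_ else ch$link_orig)
          acc$parent[cj] <- lj
          punct(")")
          link_idx <- c(link_idx, lj)
        }
      }
    }
    ri <- push(node$label, "mono", NULL,
               if (is.null(node$orig)) NA_integer_ else node$orig)
    if (length(link_idx)) acc$parent[link_idx] <- ri
    ri
  }

  root <- emit_node(tree)
  n <- length(acc$label)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer()
  for (i in seq_len(n)) {
    p <- acc$parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  linkage <- lapply(seq_len(n), function(i) {
    if (acc$type[i] == "link") acc$linkage[[i]] else NULL
  })
  structure(list(
    label = acc$label,
    type = acc$type,
    linkage = linkage,
    parent = acc$parent,
    children = children,
    root = root,
    n_mono = sum(acc$type == "mono"),
    string = paste(acc$str, collapse = ""),
    index_map = acc$orig
  ), class = "glycan_graph")
}

#' @export
print.glycan_graph <- function(x, ...) {
  cat("<glycan_graph> ", x$string, "\n", sep = "")
  cat("  ", x$n_mono, " monosaccharides, ", length(x$label), " nodes, root = ",
      x$root, " (", x$label[x$root], ")\n", sep = "")
  invisible(x)
}

# monosaccharide children of a residue (skipping the intervening link nodes)
mono_children <- function(g, i) {
  links <- g$children[[i]]
  if (length(links) == 0L) return(integer())
  vapply(links, function(l) g$children[[l]][1L], integer(1L))
}

# depth of every node from the root (root = 0)
node_depths <- function(g) {
  d <- integer(length(g$label))
  for (i in seq_along(d)) {
    j <- i
    k <- 0L
    while (!is.na(g$parent[j])) {
      j <- g$parent[j]
      k <- k + 1L
    }
    d[i] <- k
  }
  d
}

#' Assert every structural invariant of a glycan graph
#'
#' Checks the single-root, alternation, linkage-degree, node-count and
#' connectivity invariants, and that the graph round-trips through its
#' serialized form. Errors on the first violation.
#'
#' @param g A `glycan_graph`.
#' @return `TRUE` invisibly.
#' @export
validate_glycan_graph <- function(g) {
  n <- length(g$label)
  stopifnot(inherits(g, "glycan_graph"),
            length(g$type) == n, length(g$parent) == n,
            sum(is.na(g$parent)) == 1L,
            is.na(g$parent[g$root]),
            g$type[g$root] == "mono",
            n == 2L * g$n_mono - 1L)
  for (i in seq_len(n)) {
    p <- g$parent[i]
    if (!is.na(p)) stopifnot(g$type[i] != g$type[p])  # alternation
    if (g$type[i] == "link") {
      stopifnot(length(g$children[[i]]) == 1L, !is.na(p))
    }
  }
  # connectivity: every node reaches the root
  for (i in seq_len(n)) {
    j <- i
    steps <- 0L
    while (!is.na(g$parent[j])) {
      j <- g$parent[j]
      steps <- steps + 1L
      stopifnot(steps <= n)
    }
    stopifnot(j == g$root)
  }
  # round trip through the serialized form
  stopifnot(identical(to_string(parse_iupac(g$string)), g$string))
  invisible(TRUE)
}

# --- subset serialization ----------------------------------------------------

# Rebuild the nested tree induced by `nodes`, recording original indices.
# Boundary rule: a linkage node whose parent residue is outside the subset
# is dropped from the serialization (sub-glycans must start and end on
# monosaccharides); a linkage whose child residue is missing is an error.
subset_tree <- function(g, nodes) {
  nodes <- sort(unique(as.integer(nodes)))
  n <- length(g$label)
  if (length(nodes) == 0L) stop("empty node subset", call. = FALSE)
  if (any(is.na(nodes)) || any(nodes < 1L) || any(nodes > n)) {
    stop("node indices out of range", call. = FALSE)
  }
  inset <- logical(n)
  inset[nodes] <- TRUE
  for (i in nodes) {
    if (g$type[i] == "link") {
      child <- g$children[[i]][1L]
      if (!inset[child]) {
        stop("subset separates linkage node ", i, " from its child residue",
             call. = FALSE)
      }
    }
  }
  # roots of the induced forest: residues not attached within the subset
  attached <- function(i) {
    p <- g$parent[i]
    !is.na(p) && inset[p] && !is.na(g$parent[p]) && inset[g$parent[p]]
  }
  mono_nodes <- nodes[g$type[nodes] == "mono"]
  roots <- mono_nodes[!vapply(mono_nodes, attached, logical(1L))]
  if (length(roots) != 1L) {
    stop("node subset does not induce a connected sub-glycan", call. = FALSE)
  }
  build <- function(i) {
    kids <- list()
    for (l in g$children[[i]]) {
      if (!inset[l]) next
      ch <- g$children[[l]][1L]
      kids <- c(kids, list(list(link = g$linkage[[l]], link_orig = l,
                                child = build(ch))))
    }
    list(label = g$label[i], children = kids, orig = i)
  }
  build(roots)
}

#' Serialize a glycan graph (or a connected subset) to IUPAC-condensed text
#'
#' Produces the canonical string: at every branch point the longest branch
#' is the main chain (written outside parentheses), ties broken by lowest
#' acceptor carbon then residue token. Serialization is idempotent:
#' `to_string(parse_iupac(x))` re-serializes to itself.
#'
#' With `nodes`, only the induced sub-glycan is serialized. The subset must
#' be connected; a linkage node at the rootward boundary (its acceptor
#' residue outside the subset) is dropped so that the output starts and ends
#' on monosaccharides and is itself valid IUPAC-condensed.
#'
#' @param graph A `glycan_graph`.
#' @param nodes Optional integer vector of node indices.
#' @param dialect "ascii" (default) or "unicode" (alpha/beta in linkages).
#' @return A single glycan string.
#' @examples
#' g <- parse_iupac("Neu5Aca2-3Galb1-4(Fuca1-3)GlcNAc")
#' to_string(g)
#' to_string(g, nodes = c(5, 6, 7))   # "Fuca1-3GlcNAc"
#' @export
to_string <- function(graph, nodes = NULL, dialect = c("ascii", "unicode")) {
  stopifnot(inherits(graph, "glycan_graph"))
  dialect <- match.arg(dialect)
  s <- if (is.null(nodes)) {
    graph$string
  } else {
    build_glycan_graph(canonical_order(subset_tree(graph, nodes)))$string
  }
  if (dialect == "unicode") {
    # residue tokens never contain hyphens, so "[ab][12?]-" can only start a
    # linkage token; convert just those anomer letters
    s <- gsub("a([12?]-)", "\u03b1\\1", s)
    s <- gsub("b([12?]-)", "\u03b2\\1", s)
  }
  s
}

#' Extract a connected sub-glycan as a new glycan graph
#'
#' Re-indexes the induced subtree canonically; the mapping from new to
#' original node indices is kept in the `index_map` field of the result.
#' Linkage nodes at the rootward boundary are dropped (see [to_string()]).
#'
#' @param graph A `glycan_graph`.
#' @param nodes Integer vector of node indices inducing a connected subtree.
#' @return A new `glycan_graph`; `$index_map[i]` is the original index of
#'   node `i` (NA for linkage nodes, which are re-derived).
#' @export
glycan_subgraph <- function(graph, nodes) {
  stopifnot(inherits(graph, "glycan_graph"))
  build_glycan_graph(canonical_order(subset_tree(graph, nodes)))
}
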