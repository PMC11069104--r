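# The matching engine.
#
# A parsed pattern is compiled into a chain of steps read non-reducing ->
# reducing. Each residue step owns its monosaccharide node and, when the
# step specifies a linkage or is followed by another step, the linkage node
# joining it to its acceptor. Branch groups hang off the residue step they
# precede; quantified elements become repeat steps whose admitted counts
# are materialized against the glycan's residue count and expanded into
# plain chains. Matching then traces each plain chain through the glycan
# from the reducing end of the pattern leafward, so every reported match is
# a connected subtree by construction. Lookaround steps must be present in
# the glycan but their node indices are excluded from reported matches.

# --- compilation -------------------------------------------------------------

new_step <- function(kind, spec = NULL, linkage = NULL, branches = list(),
                     quant = c(1, 1), lazy = FALSE, look = "none", unit = NULL) {
  list(kind = kind, spec = spec, linkage = linkage, branches = branches,
       quant = quant, lazy = lazy, look = look, unit = unit)
}

flag_chain <- function(steps, side) {
  lapply(steps, function(st) {
    st$look <- side
    st$branches <- lapply(st$branches, flag_chain, side = side)
    if (!is.null(st$unit)) st$unit <- flag_chain(st$unit, side)
    st
  })
}

# elements -> chain of steps; pending branch groups attach to the next
# residue (or repeat) step
compile_elements <- function(els) {
  steps <- list()
  pending <- list()
  for (e in els) {
    if (e$kind == "residue") {
      spec <- list(tokens = e$tokens, negated = e$negated, wildcard = e$wildcard)
      st <- new_step("residue", spec = spec, linkage = e$linkage,
                     branches = pending)
      pending <- list()
      if (e$quantified && !(e$quant[1L] == 1 && e$quant[2L] == 1)) {
        st2 <- st
        st2$branches <- list()
        unit <- list(st2)
        unit[[1L]]$branches <- st$branches
        st <- new_step("repeat", quant = e$quant, lazy = e$lazy, unit = unit)
      }
      steps[[length(steps) + 1L]] <- st
    } else if (e$look == "none" && !e$quantified) {
      # plain branch group
      pending <- c(pending, list(compile_elements(e$children[[1L]])))
    } else if (e$look == "none") {
      if (length(pending) > 0L) {
        glyre_parse_error("a branch group must precede a residue", e$pos)
      }
      steps[[length(steps) + 1L]] <-
        new_step("repeat", quant = e$quant, lazy = e$lazy,
                 unit = compile_elements(e$children[[1L]]))
    } else {
      # lookaround: splice the flagged sub-chain in place
      if (length(pending) > 0L) {
        glyre_parse_error("a branch group must precede a residue", e$pos)
      }
      sub <- flag_chain(compile_elements(e$children[[1L]]), e$look)
      steps <- c(steps, sub)
    }
  }
  if (length(pending) > 0L) {
    glyre_parse_error("a branch group must precede a residue", NA_integer_)
  }
  steps
}

compile_pattern <- function(ast) {
  stopifnot(inherits(ast, "glyre_pattern"))
  compile_elements(ast$elements)
}

# --- count expansion ---------------------------------------------------------

# cartesian product of variant lists: list of list-of-chains -> list of
# concatenated chains
cross_concat <- function(parts, cap = 50000L) {
  out <- list(list())
  for (p in parts) {
    nxt <- vector("list", length(out) * length(p))
    k <- 0L
    for (a in out) {
      for (b in p) {
        k <- k + 1L
        nxt[[k]] <- c(a, b)
      }
    }
    out <- nxt
    if (length(out) > cap) stop("pattern expansion too large", call. = FALSE)
  }
  out
}

# chain with repeat steps -> list of plain chains (counts materialized
# against `ceiling`, branches expanded recursively)
expand_chain <- function(steps, ceiling) {
  parts <- lapply(steps, function(st) {
    if (st$kind == "residue") {
      if (length(st$branches) == 0L) return(list(list(st)))
      branch_vars <- lapply(st$branches, expand_chain, ceiling = ceiling)
      combos <- cross_list(branch_vars)
      lapply(combos, function(bs) {
        st$branches <- bs
        list(st)
      })
    } else {
      unit_vars <- expand_chain(st$unit, ceiling)
      lo <- st$quant[1L]
      hi <- min(st$quant[2L], ceiling)
      out <- list()
      c_ <- lo
      while (c_ <= hi) {
        if (c_ == 0) {
          out[[length(out) + 1L]] <- list()
        } else {
          reps <- cross_concat(rep(list(unit_vars), c_))
          out <- c(out, reps)
        }
        c_ <- c_ + 1
      }
      out
    }
  })
  cross_concat(parts)
}

# cartesian product keeping elements separate (for branch sets)
cross_list <- function(parts) {
  out <- list(list())
  for (p in parts) {
    nxt <- vector("list", length(out) * length(p))
    k <- 0L
    for (a in out) {
      for (b in p) {
        k <- k + 1L
        nxt[[k]] <- c(a, list(b))
      }
    }
    out <- nxt
  }
  out
}

# --- plain-chain matching ----------------------------------------------------

label_matches <- function(spec, label) {
  if (spec$wildcard) return(TRUE)
  if (spec$negated) return(!(label %in% spec$tokens))
  label %in% spec$tokens
}

# All embeddings of a plain chain. Steps are processed from the reducing
# (rootward) end: the last step's residue is anchored either freely or as a
# child of `attach_parent`; earlier steps descend leafward. `blocked` lists
# residues under `attach_parent` already claimed by sibling branches.
# Each embedding: list(nodes, excl, entry = residue matched by the last step).
match_plain <- function(g, steps, attach_parent = NA_integer_, blocked = integer()) {
  if (length(steps) == 0L) {
    return(list(list(nodes = integer(), excl = integer(), entry = NA_integer_)))
  }
  st <- steps[[length(steps)]]
  rest <- steps[-length(steps)]
  out <- list()
  cand <- if (is.na(attach_parent)) {
    which(g$type == "mono")
  } else {
    setdiff(mono_children(g, attach_parent), blocked)
  }
  for (r in cand) {
    if (!label_matches(st$spec, g$label[r])) next
    l <- g$parent[r]
    consumed <- r
    if (!is.na(attach_parent)) {
      if (!link_matches(st$linkage, g$linkage[[l]])) next
      consumed <- c(r, l)
    } else if (!is.null(st$linkage)) {
      if (is.na(l)) next
      if (!link_matches(st$linkage, g$linkage[[l]])) next
      consumed <- c(r, l)
    }
    excl0 <- if (st$look != "none") consumed else integer()
    for (bc in match_branch_sets(g, st$branches, r)) {
      for (e in match_plain(g, rest, attach_parent = r, blocked = bc$used)) {
        out[[length(out) + 1L]] <-
          list(nodes = c(consumed, bc$nodes, e$nodes),
               excl = c(excl0, bc$excl, e$excl),
               entry = r)
      }
    }
  }
  out
}

# all ways to place every branch chain under residue r on distinct children
match_branch_sets <- function(g, branches, r, used = integer()) {
  if (length(branches) == 0L) {
    return(list(list(nodes = integer(), excl = integer(), used = used)))
  }
  first <- branches[[1L]]
  rest <- branches[-1L]
  out <- list()
  for (e in match_plain(g, first, attach_parent = r, blocked = used)) {
    for (tailc in match_branch_sets(g, rest, r, used = c(used, e$entry))) {
      out[[length(out) + 1L]] <-
        list(nodes = c(e$nodes, tailc$nodes),
             excl = c(e$excl, tailc$excl),
             used = tailc$used)
    }
  }
  out
}

# --- result selection --------------------------------------------------------

set_key <- function(x) paste(x, collapse = ",")

dedupe_sets <- function(sets) {
  if (length(sets) == 0L) return(sets)
  sets[!duplicated(vapply(sets, set_key, ""))]
}

# greedy keeps node sets that are not strict subsets of another result
# (count-maximal: no valid extension exists); lazy keeps sets that do not
# strictly contain another (count-minimal)
filter_policy <- function(sets, lazy_mode) {
  if (length(sets) <= 1L) return(sets)
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i == j) next
      si <- sets[[i]]
      sj <- sets[[j]]
      if (length(si) >= length(sj)) next
      if (all(si %in% sj)) {
        if (lazy_mode) keep[j] <- FALSE else keep[i] <- FALSE
      }
    }
  }
  sets[keep]
}

sort_sets <- function(sets) {
  if (length(sets) == 0L) return(sets)
  lo <- vapply(sets, min, integer(1L))
  sz <- vapply(sets, length, integer(1L))
  sets[order(lo, -sz)]
}

# --- public operations -------------------------------------------------------

as_glycan_graph <- function(glycan) {
  if (inherits(glycan, "glycan_graph")) glycan else parse_iupac(glycan)
}

as_pattern <- function(pattern) {
  if (inherits(pattern, "glyre_pattern")) pattern else parse_pattern(pattern)
}

#' Trace a pattern through a glycan graph
#'
#' The core matching operation: materializes quantifier counts, matches
#' every plain chain by recursive attachment descent, and returns all
#' distinct matches under the selection policy. Every returned node list is
#' sorted, induces a connected subtree, satisfies each element's count
#' constraint, and includes the linkage nodes between stitched residues;
#' lookaround nodes must be present in the glycan but are excluded from the
#' lists. Under the greedy policy each match is count-maximal (no valid
#' extension exists); under lazy, count-minimal. A lazy quantifier glyph
#' ("+?") in the pattern switches the whole match selection to lazy.
#'
#' @param graph A `glycan_graph` (or a glycan string).
#' @param pattern A `glyre_pattern` (or a pattern string).
#' @param policy "greedy" (default) or "lazy".
#' @return A list of sorted integer node-index vectors, ordered by lowest
#'   node index, ties broken by larger match first. Empty list = no match.
#' @export
trace_match <- function(graph, pattern, policy = c("greedy", "lazy")) {
  policy <- match.arg(policy)
  g <- as_glycan_graph(graph)
  ast <- as_pattern(pattern)
  chain <- compile_pattern(ast)
  variants <- expand_chain(chain, ceiling = g$n_mono)
  reported <- list()
  for (v in variants) {
    for (e in match_plain(g, v)) {
      ns <- sort(setdiff(e$nodes, e$excl))
      if (length(ns) > 0L) reported[[length(reported) + 1L]] <- ns
    }
  }
  reported <- dedupe_sets(reported)
  lazy_mode <- policy == "lazy" || has_lazy_quantifier(ast$elements)
  sort_sets(filter_policy(reported, lazy_mode))
}

#' Match a glyco-regex pattern against a glycan
#'
#' The main entry point: parses both inputs, traces the pattern through the
#' glycan graph, and serializes each match. No match is an empty result,
#' not an error.
#'
#' @param pattern Pattern string (or `glyre_pattern`).
#' @param glycan IUPAC-condensed glycan string (or `glycan_graph`).
#' @param policy "greedy" (default) or "lazy".
#' @return A `glyre_match` object: `glycan` (canonical string), `matches`
#'   (list of sorted 1-based node-index vectors) and `match_strings` (the
#'   serialized sub-glycans, rootward boundary linkages dropped).
#' @examples
#' m <- get_match("Fuca3GlcNAc", "Neu5Acα2-3Galβ1-4(Fucα1-3)GlcNAc")
#' m$matches        # one match: nodes 5,6,7
#' m$match_strings  # "Fuca1-3GlcNAc"
#' @export
get_match <- function(pattern, glycan, policy = c("greedy", "lazy")) {
  policy <- match.arg(policy)
  ast <- tryCatch(as_pattern(pattern), error = function(e) {
    stop("in pattern '", if (is.character(pattern)) pattern else "?", "': ",
         conditionMessage(e), call. = FALSE)
  })
  g <- tryCatch(as_glycan_graph(glycan), error = function(e) {
    stop("in glycan '", if (is.character(glycan)) glycan else "?", "': ",
         conditionMessage(e), call. = FALSE)
  })
  matches <- trace_match(g, ast, policy)
  strings <- vapply(matches, function(ns) to_string(g, ns), character(1L))
  structure(list(glycan = g$string, matches = matches,
                 match_strings = strings),
            class = "glyre_match")
}

#' @export
print.glyre_match <- function(x, ...) {
  cat("<glyre_match> ", x$glycan, "\n", sep = "")
  if (length(x$matches) == 0L) {
    cat("  no matches\n")
  } else {
    for (i in seq_along(x$matches)) {
      cat(sprintf("  [%d] nodes {%s}  %s\n", i,
                  paste(x$matches[[i]], collapse = ","), x$match_strings[i]))
    }
  }
  invisible(x)
}

#' All embeddings of a plain pattern segment
#'
#' A plain segment is a run of unquantified elements (exact, ambiguous,
#' wildcard or negated specs); its occurrences are located by subgraph
#' matching against the glycan, returning every embedding, overlapping ones
#' included.
#'
#' @param graph A `glycan_graph` (or glycan string).
#' @param segment A pattern string or parsed pattern whose elements all
#'   carry the default quantifier and no lookaround.
#' @return A list of segment matches: each has `node_set` (sorted indices)
#'   and `attachment`, the (leafward residue, rootward residue) pair used
#'   when stitching segments.
#' @export
segment_matches <- function(graph, segment) {
  g <- as_glycan_graph(graph)
  ast <- as_pattern(segment)
  if (any(vapply(ast$elements, function(e) e$quantified || e$look != "none",
                 logical(1L)))) {
    stop("segment must be a plain run: no quantifiers or lookaround", call. = FALSE)
  }
  chain <- compile_pattern(ast)
  depth <- node_depths(g)
  out <- list()
  for (e in match_plain(g, chain)) {
    ns <- sort(e$nodes)
    monos <- ns[g$type[ns] == "mono"]
    leafward <- monos[which.max(depth[monos])]
    out[[length(out) + 1L]] <-
      list(node_set = ns, attachment = c(leafward = leafward, rootward = e$entry))
  }
  out
}

#' Enumerate repeat-unit chains satisfying a count constraint
#'
#' For a constraint produced by [expand_quantified()], finds every chain of
#' `c` consecutive, non-overlapping embeddings of the repeat unit for each
#' admitted count `c`, optionally required to attach below a given anchor
#' residue. A count of zero yields the empty node set.
#'
#' @param graph A `glycan_graph` (or glycan string).
#' @param constraint A `glyre_count_constraint`.
#' @param anchor Optional residue node index the chain must attach to
#'   (i.e. the rootward acceptor of the repeat chain).
#' @return A list of list(node_set, count).
#' @export
check_counts <- function(graph, constraint, anchor = NULL) {
  stopifnot(inherits(constraint, "glyre_count_constraint"))
  g <- as_glycan_graph(graph)
  out <- list()
  for (c_ in constraint$allowed_counts) {
    if (c_ == 0L) {
      out[[length(out) + 1L]] <- list(node_set = integer(), count = 0L)
      next
    }
    chain <- do.call(c, rep(list(constraint$unit_chain), c_))
    embs <- match_plain(g, chain,
                        attach_parent = if (is.null(anchor)) NA_integer_ else anchor)
    for (e in embs) {
      out[[length(out) + 1L]] <- list(node_set = sort(e$nodes), count = c_)
    }
  }
  # distinct node sets per count
  keys <- vapply(out, function(x) paste(x$count, set_key(x$node_set)), "")
  out[!duplicated(keys)]
}
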