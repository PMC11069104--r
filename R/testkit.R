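# Synthetic glycans and the brute-force matching oracle.
#
# The generator draws random valid glycan trees for property-based testing;
# it stands in for real glycomes (no biosynthetic pathway constraints). The
# oracle re-decides pattern matches by explicit assignment enumeration over
# pattern-node tables and shares only the two parsers with the engine, so
# agreement between the two is meaningful evidence of correctness.

# --- RNG scoping -------------------------------------------------------------

# run expr under set.seed(seed) without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

pick1 <- function(x) x[[sample.int(length(x), 1L)]]

# --- synthetic glycan generator ----------------------------------------------

#' Specification for the synthetic glycan generator
#'
#' Bundles the parameters of [generate_glycans()]. Defaults reflect common
#' mammalian-type building blocks and linkages; they produce compact,
#' moderately branched glycans suitable for exercising every feature of the
#' matcher, not frequency-matched mimics of any real glycome.
#'
#' @param alphabet Monosaccharide tokens to draw from.
#' @param linkage_pool Data frame of candidate linkages with columns
#'   `anomer` and `c_to` (the acceptor carbon); the donor carbon always
#'   follows the C1/C2 rule for the drawn residue.
#' @param max_residues Maximum monosaccharide count; sizes are drawn
#'   uniformly from 1..max_residues.
#' @param branch_prob Per-attachment probability that a new residue starts
#'   or extends a branch (attaches to an internal node) rather than
#'   elongating the current chain tip.
#' @param unknown_linkage_prob Probability that an emitted linkage is the
#'   fully unknown "?1-?".
#' @param seed Integer seed; the same spec and seed reproduce the same
#'   glycans bit-exactly.
#' @return A `synthetic_glycan_spec` list.
#' @export
synthetic_glycan_spec <- function(alphabet = c("Gal", "Glc", "Man", "GlcNAc",
                                               "GalNAc", "Fuc", "Neu5Ac",
                                               "Neu5Gc", "Xyl"),
                                  linkage_pool = default_linkage_pool(),
                                  max_residues = 10L,
                                  branch_prob = 0.2,
                                  unknown_linkage_prob = 0.05,
                                  seed = NULL) {
  stopifnot(max_residues >= 1L, branch_prob >= 0, branch_prob <= 1,
            unknown_linkage_prob >= 0, unknown_linkage_prob <= 1)
  structure(list(alphabet = alphabet, linkage_pool = linkage_pool,
                 max_residues = as.integer(max_residues),
                 branch_prob = branch_prob,
                 unknown_linkage_prob = unknown_linkage_prob,
                 seed = seed),
            class = "synthetic_glycan_spec")
}

#' @rdname synthetic_glycan_spec
#' @export
default_linkage_pool <- function() {
  expand.grid(anomer = c("a", "b"), c_to = c(2L, 3L, 4L, 6L),
              stringsAsFactors = FALSE)
}

# one random glycan tree under the current RNG stream
random_glycan_tree <- function(spec) {
  n_res <- sample.int(spec$max_residues, 1L)
  label <- character(n_res)
  parent <- rep(NA_integer_, n_res)
  link <- vector("list", n_res)
  nkids <- integer(n_res)
  used_cto <- vector("list", n_res)
  label[1L] <- pick1(spec$alphabet)
  tip <- 1L
  if (n_res >= 2L) {
    for (i in 2:n_res) {
      host <- tip
      if (i >= 3L && stats::runif(1L) < spec$branch_prob) {
        # branch: attach as an extra child of an internal node
        prev <- seq_len(i - 1L)
        elig <- prev[nkids[prev] >= 1L & nkids[prev] < 3L &
                       vapply(prev, function(j) {
                         length(setdiff(spec$linkage_pool$c_to, used_cto[[j]])) > 0L
                       }, logical(1L))]
        if (length(elig) > 0L) host <- pick1(elig)
      }
      label[i] <- pick1(spec$alphabet)
      if (stats::runif(1L) < spec$unknown_linkage_prob) {
        lk <- new_linkage("?", NA, NA)
      } else {
        free <- setdiff(spec$linkage_pool$c_to, used_cto[[host]])
        ct <- pick1(free)
        rows <- which(spec$linkage_pool$c_to == ct)
        anomer <- spec$linkage_pool$anomer[pick1(rows)]
        lk <- new_linkage(anomer, donor_carbon(label[i]), ct)
        used_cto[[host]] <- c(used_cto[[host]], ct)
      }
      parent[i] <- host
      link[[i]] <- lk
      nkids[host] <- nkids[host] + 1L
      tip <- i
    }
  }
  # nested-tree form
  build <- function(j) {
    kids <- which(parent == j)
    list(label = label[j],
         children = lapply(kids, function(k) list(link = link[[k]], child = build(k))),
         orig = NA_integer_)
  }
  build(1L)
}

#' Generate random valid IUPAC-condensed glycans
#'
#' Draws rooted glycan trees under a [synthetic_glycan_spec()] and
#' serializes them canonically. Every generated string parses and satisfies
#' the glycan-graph invariants; C2-linking residues (sialic acids and
#' relatives) always donate from C2.
#'
#' @param spec A `synthetic_glycan_spec`.
#' @param n Number of glycans to draw.
#' @return Character vector of glycan strings.
#' @examples
#' generate_glycans(synthetic_glycan_spec(seed = 42), n = 3)
#' @export
generate_glycans <- function(spec = synthetic_glycan_spec(), n = 1L) {
  stopifnot(inherits(spec, "synthetic_glycan_spec"))
  with_local_seed(spec$seed, {
    vapply(seq_len(n), function(i) {
      build_glycan_graph(canonical_order(random_glycan_tree(spec)))$string
    }, character(1L))
  })
}

#' @rdname generate_glycans
#' @export
generate_glycan <- function(spec = synthetic_glycan_spec()) {
  generate_glycans(spec, 1L)
}

# --- brute-force oracle ------------------------------------------------------

# Expand a pattern AST into explicit pattern-node tables. A table is a list
# of pnodes list(spec, link, parent, look); `parent` points rootward within
# the table and is always created before its children, so assignment can
# proceed in table order. One table per combination of quantifier counts
# (and per branch variant).
oracle_tables <- function(els, ceiling) {
  # a variant is list(nodes, attach, head): `attach` = id the next leafward
  # chain element hangs below; `head` = leafmost chain node so far
  start <- list(list(nodes = list(), attach = NA_integer_, head = NA_integer_))

  add_pnode <- function(v, spec, link, parent, look) {
    id <- length(v$nodes) + 1L
    v$nodes[[id]] <- list(spec = spec, link = link, parent = parent, look = look)
    v$id <- id
    v
  }
  # splice a sub-variant's nodes into v, re-offsetting parent ids;
  # the sub chain's root (tail) is re-parented onto `onto`
  splice <- function(v, sub, onto) {
    off <- length(v$nodes)
    for (k in seq_along(sub$nodes)) {
      pn <- sub$nodes[[k]]
      if (!is.na(pn$parent)) pn$parent <- pn$parent + off
      v$nodes[[off + k]] <- pn
    }
    # sub's rootmost node had parent NA; attach it
    for (k in seq_along(sub$nodes)) {
      if (k == sub$tailpos && !is.na(onto)) {
        pn <- v$nodes[[off + k]]
        pn$parent <- onto
        v$nodes[[off + k]] <- pn
      }
    }
    v$subhead <- sub$headpos + off
    v$subtail <- sub$tailpos + off
    v
  }

  seq_variants <- function(elements, look) {
    vars <- list(list(nodes = list(), attach = NA_integer_,
                      head = NA_integer_, tailpos = NA_integer_, headpos = NA_integer_))
    for (e in rev(elements)) {
      nxt <- list()
      for (v in vars) {
        if (e$kind == "residue" && !e$quantified) {
          spec <- list(tokens = e$tokens, negated = e$negated, wildcard = e$wildcard)
          v2 <- add_pnode(v, spec, e$linkage, v$attach, look_of(e, look))
          v2$attach <- v2$id
          v2$head <- v2$id
          if (is.na(v2$tailpos)) v2$tailpos <- v2$id
          v2$headpos <- v2$id
          nxt[[length(nxt) + 1L]] <- v2
        } else if (e$kind == "residue") {
          # quantified residue: repeat of a one-element unit
          unit <- e
          unit$quantified <- FALSE
          unit$quant <- c(1, 1)
          nxt <- c(nxt, repeat_variants(v, list(unit), e$quant, look_of(e, look)))
        } else if (e$look == "none" && !e$quantified) {
          # branch group: hang the sub-chain below the current attach point
          if (is.na(v$attach)) next  # branch with no anchor: no valid table
          for (sub in seq_variants(e$children[[1L]], look)) {
            if (length(sub$nodes) == 0L) next
            v2 <- splice(v, sub, onto = v$attach)
            nxt[[length(nxt) + 1L]] <- v2
          }
        } else if (e$look == "none") {
          nxt <- c(nxt, repeat_variants(v, e$children[[1L]], e$quant, look))
        } else {
          # lookaround: a flagged stretch of the chain
          for (sub in seq_variants(e$children[[1L]], e$look)) {
            if (length(sub$nodes) == 0L) next
            v2 <- splice(v, sub, onto = v$attach)
            v2$attach <- v2$subhead
            v2$head <- v2$subhead
            if (is.na(v2$tailpos)) v2$tailpos <- v2$subtail
            v2$headpos <- v2$subhead
            nxt[[length(nxt) + 1L]] <- v2
          }
        }
      }
      vars <- nxt
      if (length(vars) > 20000L) stop("oracle expansion too large", call. = FALSE)
    }
    vars
  }

  look_of <- function(e, outer) if (outer != "none") outer else "none"

  repeat_variants <- function(v, unit_elements, quant, look) {
    lo <- quant[1L]
    hi <- min(quant[2L], ceiling)
    out <- list()
    c_ <- lo
    while (c_ <= hi) {
      stack <- list(v)
      ok <- TRUE
      if (c_ > 0) {
        for (inst in seq_len(c_)) {
          nstack <- list()
          for (w in stack) {
            for (sub in seq_variants(unit_elements, look)) {
              if (length(sub$nodes) == 0L) next
              w2 <- splice(w, sub, onto = w$attach)
              w2$attach <- w2$subhead
              w2$head <- w2$subhead
              if (is.na(w2$tailpos)) w2$tailpos <- w2$subtail
              w2$headpos <- w2$subhead
              nstack[[length(nstack) + 1L]] <- w2
            }
          }
          stack <- nstack
          if (length(stack) == 0L) { ok <- FALSE; break }
        }
      }
      if (ok) out <- c(out, stack)
      c_ <- c_ + 1
    }
    out
  }

  vars <- seq_variants(els, "none")
  lapply(vars, function(v) v$nodes)
}

# Enumerate all injective assignments of pattern nodes to glycan residues
# satisfying label, adjacency and linkage constraints.
oracle_assignments <- function(g, tab) {
  n <- length(tab)
  monos <- which(g$type == "mono")
  results <- list()
  rec <- function(i, map) {
    if (i > n) {
      results[[length(results) + 1L]] <<- map
      return(invisible(NULL))
    }
    pn <- tab[[i]]
    for (r in monos) {
      if (r %in% map) next
      if (!label_matches(pn$spec, g$label[r])) next
      l <- g$parent[r]
      if (!is.na(pn$parent)) {
        pr <- map[pn$parent]
        if (is.na(l) || g$parent[l] != pr) next
        if (!link_matches(pn$link, g$linkage[[l]])) next
      } else if (!is.null(pn$link)) {
        if (is.na(l)) next
        if (!link_matches(pn$link, g$linkage[[l]])) next
      }
      map[i] <- r
      rec(i + 1L, map)
      map[i] <- NA_integer_
    }
  }
  rec(1L, rep(NA_integer_, n))
  results
}

#' Brute-force matching oracle
#'
#' Independently recomputes the matches of a pattern against a glycan by
#' materializing quantifier counts into explicit pattern-node tables and
#' enumerating every injective assignment of pattern nodes to glycan
#' residues, checking the label, adjacency and linkage constraints by
#' direct definition. Exponential; refuses glycans above 14 residues. Its
#' output is the ground truth the engine is tested against.
#'
#' @param pattern Pattern string.
#' @param glycan Glycan string.
#' @param policy "greedy" or "lazy".
#' @return A list of sorted node-index vectors, same contract as
#'   [trace_match()].
#' @export
brute_force_match <- function(pattern, glycan, policy = c("greedy", "lazy")) {
  policy <- match.arg(policy)
  g <- as_glycan_graph(glycan)
  if (g$n_mono > 14L) {
    stop("oracle refuses glycans above 14 residues (exponential enumeration)",
         call. = FALSE)
  }
  ast <- as_pattern(pattern)
  tabs <- oracle_tables(ast$elements, ceiling = g$n_mono)
  sets <- list()
  seen <- character()
  for (tab in tabs) {
    if (length(tab) == 0L) next
    for (map in oracle_assignments(g, tab)) {
      consumed <- integer()
      dropped <- integer()
      for (i in seq_along(tab)) {
        pn <- tab[[i]]
        r <- map[i]
        take <- r
        if (!is.na(pn$parent) || !is.null(pn$link)) take <- c(take, g$parent[r])
        consumed <- c(consumed, take)
        if (pn$look != "none") dropped <- c(dropped, take)
      }
      rep_set <- sort(setdiff(consumed, dropped))
      if (length(rep_set) == 0L) next
      key <- paste(rep_set, collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        sets[[length(sets) + 1L]] <- rep_set
      }
    }
  }
  lazy_mode <- policy == "lazy" || has_lazy_quantifier(ast$elements)
  # minimality/maximality by pairwise strict inclusion
  if (length(sets) > 1L) {
    drop <- logical(length(sets))
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i == j || length(sets[[i]]) >= length(sets[[j]])) next
        if (all(sets[[i]] %in% sets[[j]])) {
          if (lazy_mode) drop[j] <- TRUE else drop[i] <- TRUE
        }
      }
    }
    sets <- sets[!drop]
  }
  if (length(sets) == 0L) return(sets)
  sets[order(vapply(sets, min, integer(1L)),
             -vapply(sets, length, integer(1L)))]
}

# --- pattern corpus for engine-vs-oracle testing -----------------------------

#' Grammar features covered by the test corpus
#' @return Character vector of feature names accepted by [sample_pattern()].
#' @export
pattern_features <- function() {
  c("plain", "wildcard", "linkage_alternation", "negation",
    "quant_optional", "quant_star", "quant_plus",
    "quant_exact", "quant_range", "quant_min",
    "lazy", "branch", "lookahead", "lookbehind")
}

# pieces of a random rootward path through g: list of (token, link_text)
random_path_pieces <- function(g, max_len = 3L) {
  monos <- which(g$type == "mono")
  r <- pick1(monos)
  pieces <- list()
  len <- sample.int(max_len, 1L)
  while (length(pieces) < len) {
    l <- g$parent[r]
    link_text <- if (!is.na(l)) g$label[l] else NULL
    pieces[[length(pieces) + 1L]] <- list(token = g$label[r], link = link_text)
    if (is.na(l)) break
    r <- g$parent[l]
  }
  pieces
}

piece_str <- function(p, with_link = TRUE) {
  paste0(p$token, if (with_link && !is.null(p$link)) p$link else "")
}

#' Draw a random pattern exercising one grammar feature
#'
#' Builds a pattern from a random rootward path through the glycan (so that
#' matches are frequent), then rewrites it to exercise the requested
#' feature; with some probability a token is mutated to another residue to
#' produce non-matching cases. Uses the current RNG stream.
#'
#' @param graph A `glycan_graph`.
#' @param feature One of [pattern_features()].
#' @param alphabet Tokens used for mutations.
#' @return A pattern string.
#' @export
sample_pattern <- function(graph, feature = "plain",
                           alphabet = c("Gal", "Glc", "Man", "GlcNAc",
                                        "GalNAc", "Fuc", "Neu5Ac", "Neu5Gc",
                                        "Xyl")) {
  stopifnot(feature %in% pattern_features())
  g <- graph
  pieces <- random_path_pieces(g)
  np <- length(pieces)
  # occasional mutation for negative cases
  if (stats::runif(1L) < 0.3) {
    k <- sample.int(np, 1L)
    pieces[[k]]$token <- pick1(alphabet)
  }
  strs <- vapply(seq_along(pieces), function(i) {
    piece_str(pieces[[i]], with_link = i < np || !is.null(pieces[[i]]$link) &&
                stats::runif(1L) < 0.3)
  }, character(1L))
  # drop any trailing link on the last piece half of the time is handled
  # above; assemble per feature
  wrap_first <- function(glyph) {
    paste0("(", piece_str(pieces[[1L]], with_link = np > 1L), ")", glyph,
           paste(strs[-1L], collapse = ""))
  }
  out <- switch(
    feature,
    plain = paste(strs, collapse = ""),
    wildcard = {
      k <- sample.int(np, 1L)
      pieces[[k]]$token <- if (stats::runif(1L) < 0.5) "." else "Monosaccharide"
      paste(vapply(seq_along(pieces), function(i)
        piece_str(pieces[[i]], with_link = i < np), character(1L)), collapse = "")
    },
    linkage_alternation = {
      k <- if (np > 1L) sample.int(np - 1L, 1L) else 1L
      lk <- pieces[[k]]$link
      base <- if (!is.null(lk) && grepl("^[ab][12]-[1-9]$", lk)) lk else "a1-3"
      extra <- pick1(setdiff(c("2", "3", "4", "6"), substr(base, 4L, 4L)))
      pieces[[k]]$link <- paste0(base, "/", extra)
      paste(vapply(seq_along(pieces), function(i)
        piece_str(pieces[[i]], with_link = i < np), character(1L)), collapse = "")
    },
    negation = {
      k <- sample.int(np, 1L)
      tok <- if (stats::runif(1L) < 0.5) pieces[[k]]$token else pick1(alphabet)
      pieces[[k]]$token <- paste0("!", tok)
      paste(vapply(seq_along(pieces), function(i)
        piece_str(pieces[[i]], with_link = i < np), character(1L)), collapse = "")
    },
    quant_optional = wrap_first("?"),
    quant_star = wrap_first("*"),
    quant_plus = wrap_first("+"),
    quant_exact = wrap_first(paste0("{", sample(1:2, 1L), "}")),
    quant_range = wrap_first("{1,2}"),
    quant_min = wrap_first("{1,}"),
    lazy = wrap_first(pick1(c("+?", "*?", "??"))),
    branch = {
      bp <- branch_point_pattern(g, alphabet)
      if (!is.null(bp)) bp else {
        paste0("(", pick1(alphabet), "a1-3)", piece_str(pieces[[np]], with_link = FALSE))
      }
    },
    lookahead = {
      if (np < 2L) {
        paste0(strs[1L], collapse = "")
      } else {
        k <- sample.int(np - 1L, 1L)
        paste0(paste(strs[seq_len(k)], collapse = ""),
               "(?=", paste(strs[(k + 1L):np], collapse = ""), ")")
      }
    },
    lookbehind = {
      if (np < 2L) {
        strs[1L]
      } else {
        k <- sample.int(np - 1L, 1L)
        paste0("(?<=", paste(strs[seq_len(k)], collapse = ""), ")",
               paste(strs[(k + 1L):np], collapse = ""))
      }
    }
  )
  out
}

# pattern around an actual branch point of g, if one exists
branch_point_pattern <- function(g, alphabet) {
  monos <- which(g$type == "mono")
  bps <- monos[vapply(monos, function(m) length(mono_children(g, m)) >= 2L,
                      logical(1L))]
  if (length(bps) == 0L) return(NULL)
  b <- pick1(bps)
  kids <- mono_children(g, b)
  k1 <- kids[1L]
  k2 <- kids[2L]
  main <- paste0(g$label[k1], g$label[g$parent[k1]])
  side <- paste0(g$label[k2], g$label[g$parent[k2]])
  if (stats::runif(1L) < 0.3) side <- paste0(pick1(alphabet), g$label[g$parent[k2]])
  paste0(main, "(", side, ")", g$label[b])
}
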