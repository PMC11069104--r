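# The glyco-regex pattern dialect.
#
# Patterns read non-reducing -> reducing, like IUPAC-condensed strings.
# Grammar (whitespace insignificant):
#
#   pattern    := lookbehind? element+ lookahead?
#   lookbehind := "(?<=" element+ ")"
#   lookahead  := "(?=" element+ ")"
#   element    := residue | group quantifier? | residue quantifier
#   group      := "(" element+ ")"
#   residue    := "!"? tokenalt linkage?
#   tokenalt   := token ("|" token)*          token := residue name, "." or
#                                             "Monosaccharide" (wildcards)
#   linkage    := [ab?][1-9]("/"[1-9])*       donor carbon inferred (C1/C2)
#              |  [ab?][12?]"-"[1-9?]("/"[1-9])*   explicit full form
#   quantifier := ("?" | "*" | "+" | "{n}" | "{n,m}" | "{n,}") "?"?
#                                             trailing "?" = lazy
#
# A "(...)" group directly before a residue is a glycan branch attached to
# that residue; a "(...)" group carrying a quantifier is a repeat unit along
# the chain. Lookbehind is only legal at the non-reducing (left) end,
# lookahead at the reducing (right) end.

.SHORT_LINK_RE <- "[ab?][1-9](/[1-9])*"

# --- tokenizer ---------------------------------------------------------------

tokenize_pattern <- function(s) {
  toks <- list()
  pos <- 1L
  n <- nchar(s)
  push <- function(kind, text, p) {
    toks[[length(toks) + 1L]] <<- list(kind = kind, text = text, pos = p)
  }
  # full form first so "a2-3" is not split into shorthand "a2" + "-3"
  boundary_re <- paste0("(", .LINK_RE, ")|(", .SHORT_LINK_RE, ")|[().!{}*+?|]")
  while (pos <= n) {
    rest <- substr(s, pos, n)
    if (startsWith(rest, "(?<=")) { push("lbehind", "(?<=", pos); pos <- pos + 4L; next }
    if (startsWith(rest, "(?=")) { push("lahead", "(?=", pos); pos <- pos + 3L; next }
    ch <- substr(s, pos, pos)
    if (ch %in% c("(", ")", "!", "|", ".")) {
      push(switch(ch, "(" = "(", ")" = ")", "!" = "bang", "|" = "pipe", "." = "dot"),
           ch, pos)
      pos <- pos + 1L
      next
    }
    if (ch == "{") {
      m <- regexpr("^\\{[0-9]*(,[0-9]*)?\\}", rest)
      if (m == -1L) glyre_parse_error("malformed {n,m} quantifier", pos)
      len <- attr(m, "match.length")
      push("quant", substr(rest, 1L, len), pos)
      pos <- pos + len
      next
    }
    # a linkage token beats the "?"/residue readings where both are possible
    m <- regexpr(paste0("^((", .LINK_RE, ")|(", .SHORT_LINK_RE, "))"), rest)
    if (m == 1L) {
      len <- attr(m, "match.length")
      push("link", substr(rest, 1L, len), pos)
      pos <- pos + len
      next
    }
    if (ch %in% c("*", "+", "?")) {
      push("quant", ch, pos)
      pos <- pos + 1L
      next
    }
    mb <- regexpr(boundary_re, rest)
    end <- if (mb == -1L) nchar(rest) else as.integer(mb) - 1L
    if (end < 1L) glyre_parse_error(paste0("unexpected character '", ch, "'"), pos)
    txt <- substr(rest, 1L, end)
    if (!grepl("^[A-Za-z0-9?'_]+$", txt)) {
      glyre_parse_error(paste0("invalid residue token '", txt, "'"), pos)
    }
    if (txt != "Monosaccharide" && is_residue_concat(txt)) {
      glyre_parse_error(
        paste0("two adjacent residue tokens with no linkage: '", txt, "'"), pos)
    }
    push("res", txt, pos)
    pos <- pos + end
  }
  toks
}

# --- parser ------------------------------------------------------------------

parse_quantifier <- function(text, pos) {
  if (text == "?") return(c(0, 1))
  if (text == "*") return(c(0, Inf))
  if (text == "+") return(c(1, Inf))
  m <- regmatches(text, regexec("^\\{([0-9]+)(,([0-9]*))?\\}$", text))[[1L]]
  if (length(m) == 0L) glyre_parse_error("malformed {n,m} quantifier", pos)
  lo <- as.numeric(m[2L])
  hi <- if (m[3L] == "") lo else if (m[4L] == "") Inf else as.numeric(m[4L])
  if (hi < lo) glyre_parse_error("quantifier with min > max", pos)
  c(lo, hi)
}

default_quant <- function() c(1, 1)

# residue element constructor; linkage resolved through infer_linkage so the
# donor carbon follows the C1/C2 rule for each token
make_residue_element <- function(tokens, negated, wildcard, link_text, pos) {
  linkage <- NULL
  if (!is.null(link_text)) {
    if (wildcard || negated || length(tokens) > 1L) {
      # donor carbon cannot be pinned to one residue: leave it open
      linkage <- infer_wild_linkage(link_text, pos)
    } else {
      linkage <- infer_linkage(tokens, link_text)
    }
  }
  list(kind = "residue", tokens = tokens, negated = negated,
       wildcard = wildcard, linkage = linkage,
       quant = default_quant(), quantified = FALSE, lazy = FALSE,
       look = "none", pos = pos)
}

# linkage shorthand next to a wildcard/negated/alternation spec: donor
# carbon unknown (matches both C1 and C2 donors)
infer_wild_linkage <- function(link_text, pos) {
  if (grepl("-", link_text, fixed = TRUE)) {
    return(split_linkage(parse_linkage_token(link_text, pos)))
  }
  m <- regmatches(link_text, regexec("^([ab?])([1-9?])((/[1-9])*)$", link_text))[[1L]]
  if (length(m) == 0L) glyre_parse_error("malformed linkage shorthand", pos)
  ct1 <- if (m[3L] == "?") NA_integer_ else as.integer(m[3L])
  extra <- if (nzchar(m[4L])) as.integer(strsplit(sub("^/", "", m[4L]), "/")[[1L]]) else integer()
  lapply(c(ct1, extra), function(ct) new_linkage(m[2L], NA, ct))
}

parse_elements <- function(st, top, opener_pos) {
  els <- list()
  last_quantifiable <- function() {
    length(els) > 0L && els[[length(els)]]$look == "none"
  }
  repeat {
    t <- if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
    if (is.null(t)) {
      if (top) return(els)
      glyre_parse_error("unbalanced parentheses", opener_pos)
    }
    if (t$kind == ")") {
      if (top) glyre_parse_error("unbalanced parentheses", t$pos)
      return(els)
    }
    if (length(els) > 0L && els[[length(els)]]$look == "ahead") {
      glyre_parse_error("lookahead must sit at the reducing end of the pattern",
                        t$pos)
    }
    if (t$kind %in% c("res", "dot", "bang")) {
      negated <- FALSE
      pos0 <- t$pos
      if (t$kind == "bang") {
        negated <- TRUE
        st$i <- st$i + 1L
        t <- if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
        if (is.null(t) || !t$kind %in% c("res")) {
          glyre_parse_error("'!' must be followed by a residue name", pos0)
        }
      }
      tokens <- character()
      wildcard <- FALSE
      repeat {
        if (t$kind == "dot" || (t$kind == "res" && t$text == "Monosaccharide")) {
          wildcard <- TRUE
        } else {
          tokens <- c(tokens, t$text)
        }
        st$i <- st$i + 1L
        nxt <- if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
        if (!is.null(nxt) && nxt$kind == "pipe") {
          st$i <- st$i + 1L
          t <- if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
          if (is.null(t) || !t$kind %in% c("res", "dot")) {
            glyre_parse_error("'|' must join residue names", nxt$pos)
          }
          next
        }
        break
      }
      if (wildcard && (negated || length(tokens) > 0L)) {
        glyre_parse_error("wildcard cannot be negated or joined by '|'", pos0)
      }
      link_text <- NULL
      nxt <- if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
      if (!is.null(nxt) && nxt$kind == "link") {
        link_text <- nxt$text
        st$i <- st$i + 1L
      }
      els[[length(els) + 1L]] <-
        make_residue_element(tokens, negated, wildcard, link_text, pos0)
    } else if (t$kind == "(") {
      st$i <- st$i + 1L
      children <- parse_elements(st, top = FALSE, opener_pos = t$pos)
      expect_rparen(st, t$pos)
      if (length(children) == 0L) glyre_parse_error("empty group", t$pos)
      els[[length(els) + 1L]] <-
        list(kind = "group", children = list(children),
             quant = default_quant(), quantified = FALSE, lazy = FALSE,
             look = "none", pos = t$pos)
    } else if (t$kind %in% c("lbehind", "lahead")) {
      if (!top) glyre_parse_error("lookaround groups must be at the top level", t$pos)
      side <- if (t$kind == "lbehind") "behind" else "ahead"
      if (side == "behind" && length(els) > 0L) {
        glyre_parse_error("lookbehind must sit at the non-reducing end of the pattern",
                          t$pos)
      }
      st$i <- st$i + 1L
      children <- parse_elements(st, top = FALSE, opener_pos = t$pos)
      expect_rparen(st, t$pos)
      if (length(children) == 0L) glyre_parse_error("empty lookaround group", t$pos)
      els[[length(els) + 1L]] <-
        list(kind = "group", children = list(children),
             quant = default_quant(), quantified = FALSE, lazy = FALSE,
             look = side, pos = t$pos)
    } else if (t$kind == "quant") {
      if (!last_quantifiable()) {
        glyre_parse_error("quantifier with nothing to bind to", t$pos)
      }
      le <- els[[length(els)]]
      if (le$quantified) glyre_parse_error("element already carries a quantifier", t$pos)
      q <- parse_quantifier(t$text, t$pos)
      st$i <- st$i + 1L
      lazy <- FALSE
      nxt <- if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
      if (!is.null(nxt) && nxt$kind == "quant" && nxt$text == "?") {
        lazy <- TRUE
        st$i <- st$i + 1L
      }
      le$quant <- q
      le$quantified <- TRUE
      le$lazy <- lazy
      els[[length(els)]] <- le
    } else if (t$kind == "link") {
      glyre_parse_error("linkage must follow a residue (write it inside the quantified group)",
                        t$pos)
    } else if (t$kind == "pipe") {
      glyre_parse_error("'|' must join residue names", t$pos)
    } else {
      glyre_parse_error(paste0("unexpected token '", t$text, "'"), t$pos)
    }
  }
}

expect_rparen <- function(st, opener_pos) {
  t <- if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
  if (is.null(t) || t$kind != ")") {
    glyre_parse_error("unbalanced parentheses", opener_pos)
  }
  st$i <- st$i + 1L
}

#' Parse a glyco-regex pattern
#'
#' Tokenizes and parses a pattern string into an abstract syntax tree of
#' residue elements and groups. See the package vignette for the full
#' grammar. Shorthand linkages ("Mana6") resolve their donor carbon through
#' [infer_linkage()]; "." and "Monosaccharide" are interchangeable
#' wildcards; "!Fuc" (whitespace-tolerant "! Fuc") negates a single residue
#' position.
#'
#' @param pattern A single pattern string.
#' @return A `glyre_pattern` object with an `elements` list.
#' @examples
#' parse_pattern("Mana6")
#' parse_pattern("Galb3/4")
#' parse_pattern("(?<=Neu5Aca3)Galb4(Fuca3)GlcNAc")
#' @export
parse_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern)) {
    stop("pattern must be a single character string", call. = FALSE)
  }
  s <- normalize_glycan_string(pattern)
  if (!nzchar(s)) glyre_parse_error("empty pattern", 1L)
  st <- new.env(parent = emptyenv())
  st$toks <- tokenize_pattern(s)
  st$i <- 1L
  els <- parse_elements(st, top = TRUE, opener_pos = 1L)
  if (st$i <= length(st$toks)) {
    glyre_parse_error("unexpected trailing token", st$toks[[st$i]]$pos)
  }
  main <- Filter(function(e) e$look == "none", els)
  if (length(main) == 0L) {
    glyre_parse_error("pattern needs at least one element outside lookaround groups", 1L)
  }
  structure(list(elements = els, source = s), class = "glyre_pattern")
}

#' @export
print.glyre_pattern <- function(x, ...) {
  cat("<glyre_pattern> ", x$source, "\n", sep = "")
  describe <- function(els, indent) {
    pad <- strrep("  ", indent)
    for (e in els) {
      if (e$kind == "residue") {
        lab <- if (e$wildcard) "." else paste(e$tokens, collapse = "|")
        if (e$negated) lab <- paste0("!", lab)
        lk <- if (is.null(e$linkage)) "" else
          paste0(" [", paste(vapply(e$linkage, format_linkage, ""), collapse = ", "), "]")
        cat(pad, "residue ", lab, lk, quant_str(e), look_str(e), "\n", sep = "")
      } else {
        cat(pad, "group", quant_str(e), look_str(e), "\n", sep = "")
        describe(e$children[[1L]], indent + 1L)
      }
    }
  }
  describe(x$elements, 1L)
  invisible(x)
}

quant_str <- function(e) {
  if (!e$quantified) return("")
  hi <- if (is.infinite(e$quant[2L])) "Inf" else e$quant[2L]
  paste0(" {", e$quant[1L], ",", hi, "}", if (e$lazy) " lazy" else "")
}

look_str <- function(e) {
  switch(e$look, none = "", behind = " (lookbehind)", ahead = " (lookahead)")
}

# any lazy quantifier glyph anywhere in the AST?
has_lazy_quantifier <- function(els) {
  for (e in els) {
    if (isTRUE(e$lazy)) return(TRUE)
    if (e$kind == "group" && has_lazy_quantifier(e$children[[1L]])) return(TRUE)
  }
  FALSE
}

# --- count constraints -------------------------------------------------------

#' Expand a quantified pattern element into a count constraint
#'
#' Segments carrying a quantifier are handled as (substructure : allowed
#' counts) pairs: the repeat unit together with the set of repeat counts the
#' quantifier admits. Unbounded quantifiers are materialized against
#' `ceiling`, which callers set to the glycan's residue count (no repeat
#' unit can occur more often).
#'
#' @param element A quantified element from a parsed pattern (or a pattern
#'   string containing exactly one element).
#' @param ceiling Upper bound used to materialize unbounded quantifiers.
#' @return A `glyre_count_constraint`: list(substructure, allowed_counts,
#'   unit_chain). The substructure is a `glycan_graph` of one repeat unit
#'   (wildcards appear as the token "Monosaccharide"); `unit_chain` is the
#'   compiled form the engine consumes.
#' @examples
#' p <- parse_pattern("(Galb4GlcNAcb3){1,3}")
#' cc <- expand_quantified(p$elements[[1]], ceiling = 10)
#' cc$allowed_counts
#' @export
expand_quantified <- function(element, ceiling = 12L) {
  if (inherits(element, "glyre_pattern")) {
    if (length(element$elements) != 1L) {
      stop("pass a single pattern element", call. = FALSE)
    }
    element <- element$elements[[1L]]
  }
  unit_els <- if (element$kind == "group") element$children[[1L]] else {
    e <- element
    e$quant <- default_quant()
    e$quantified <- FALSE
    list(e)
  }
  chain <- compile_elements(unit_els)
  lo <- element$quant[1L]
  hi <- min(element$quant[2L], ceiling)
  counts <- if (hi < lo) integer() else as.integer(lo):as.integer(hi)
  structure(list(substructure = unit_as_graph(chain),
                 allowed_counts = counts,
                 unit_chain = chain),
            class = "glyre_count_constraint")
}

# Render a compiled unit chain as a glycan_graph (wildcards ->
# "Monosaccharide", negations keep their "!" prefix, open linkages -> "?").
unit_as_graph <- function(chain) {
  build <- function(steps) {
    node <- NULL
    lk_prev <- NULL
    for (i in seq_along(steps)) {
      st <- steps[[i]]
      if (st$kind != "residue") {
        stop("repeat units may not nest further quantifiers in the rendered substructure",
             call. = FALSE)
      }
      lab <- if (st$spec$wildcard) "Monosaccharide" else
        paste0(if (st$spec$negated) "!" else "", paste(st$spec$tokens, collapse = "|"))
      kids <- lapply(st$branches, function(b) list(link = tail_linkage(b), child = build(b)))
      if (!is.null(node)) {
        kids <- c(kids, list(list(link = lk_prev, child = node)))
      }
      # step i's linkage joins it to step i+1 (rootward); remember it for
      # the next iteration, where this node becomes the child
      node <- list(label = lab, children = kids, orig = NA_integer_)
      lk_prev <- if (is.null(st$linkage)) new_linkage("?", NA, NA) else st$linkage[[1L]]
    }
    node
  }
  tail_linkage <- function(steps) {
    st <- steps[[length(steps)]]
    if (is.null(st$linkage)) new_linkage("?", NA, NA) else st$linkage[[1L]]
  }
  build_glycan_graph(canonical_order(build(chain)))
}
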