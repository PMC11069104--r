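# IUPAC-condensed glycan parsing.
#
# Strings read non-reducing -> reducing end; branches in parentheses attach
# to the residue that follows them. Both the Unicode dialect
# ("Neu5Acα2-3Galβ1-4(Fucα1-3)GlcNAc") and the ASCII dialect
# ("Neu5Aca2-3Galb1-4(Fuca1-3)GlcNAc") are accepted; everything is
# normalized to ASCII before tokenization.

.LINK_RE <- "[ab?][12?]-[1-9?](/[1-9])*"

# Common residue vocabulary, used only to catch two adjacent residue tokens
# written with no linkage between them ("GalGlcNAc"), which are otherwise
# lexically indistinguishable from one unknown residue name.
.KNOWN_RESIDUES <- c(
  "Glc", "Gal", "Man", "GlcNAc", "GalNAc", "ManNAc", "Fuc", "Xyl", "Rha",
  "Ara", "Rib", "Neu5Ac", "Neu5Gc", "Neu", "Kdn", "Kdo", "GlcA", "IdoA",
  "GalA", "ManA", "GlcN", "GalN", "Qui", "All", "Api", "Fru", "Tal", "Ido",
  "Alt", "Sor", "Psi", "Tag", "Xul", "Abe", "Col", "Par", "Tyv", "Leg",
  "Pse", "Aci", "Bac", "Dha", "Mur", "MurNAc"
)

# TRUE when token is a concatenation of two or more known residue names
is_residue_concat <- function(token) {
  if (token %in% .KNOWN_RESIDUES) return(FALSE)
  splits_known <- function(t) {
    if (t %in% .KNOWN_RESIDUES) return(TRUE)
    for (k in seq_len(nchar(t) - 1L)) {
      left <- substr(t, 1L, k)
      if (left %in% .KNOWN_RESIDUES && splits_known(substr(t, k + 1L, nchar(t)))) {
        return(TRUE)
      }
    }
    FALSE
  }
  splits_known(token)
}

normalize_glycan_string <- function(x) {
  x <- gsub("\u03b1", "a", x)
  x <- gsub("\u03b2", "b", x)
  x <- gsub("[\u2010\u2011\u2012\u2013\u2014\u2212]", "-", x)
  gsub("[[:space:]]+", "", x)
}

check_parens <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) glyre_parse_error("unbalanced parentheses", i)
    }
  }
  if (depth != 0L) glyre_parse_error("unbalanced parentheses", nchar(s))
  invisible(TRUE)
}

# Token stream: list of list(kind = "res"|"link"|"("|")", text, pos).
tokenize_iupac <- function(s) {
  toks <- list()
  pos <- 1L
  n <- nchar(s)
  boundary_re <- paste0("(", .LINK_RE, ")|[()]")
  while (pos <= n) {
    ch <- substr(s, pos, pos)
    if (ch == "(" || ch == ")") {
      toks[[length(toks) + 1L]] <- list(kind = ch, text = ch, pos = pos)
      pos <- pos + 1L
      next
    }
    rest <- substr(s, pos, n)
    m <- regexpr(boundary_re, rest)
    if (m == 1L) {
      len <- attr(m, "match.length")
      toks[[length(toks) + 1L]] <- list(kind = "link",
                                        text = substr(rest, 1L, len), pos = pos)
      pos <- pos + len
    } else {
      end <- if (m == -1L) nchar(rest) else as.integer(m) - 1L
      txt <- substr(rest, 1L, end)
      if (!grepl("^[A-Za-z0-9?'_]+$", txt)) {
        glyre_parse_error(paste0("invalid residue token '", txt, "'"), pos)
      }
      if (is_residue_concat(txt)) {
        glyre_parse_error(
          paste0("two adjacent residue tokens with no linkage: '", txt, "'"), pos)
      }
      toks[[length(toks) + 1L]] <- list(kind = "res", text = txt, pos = pos)
      pos <- pos + end
    }
  }
  toks
}

# Recursive-descent parse into a nested tree:
#   node := list(label = <token>, children = list(list(link, child)), orig = NA)
# Returns list(node, trailing): `trailing` is the linkage that follows the
# chain root (only legal inside a parenthesized branch).
parse_chain_env <- function(st) {
  pending <- list()
  repeat {
    t <- if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
    if (is.null(t)) glyre_parse_error("unexpected end of glycan string", st$len)
    if (t$kind == "(") {
      st$i <- st$i + 1L
      r <- parse_chain_env(st)
      t2 <- if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
      if (is.null(t2) || t2$kind != ")") {
        glyre_parse_error("unbalanced parentheses", t$pos)
      }
      st$i <- st$i + 1L
      if (is.null(r$trailing)) {
        glyre_parse_error("a branch must end with a linkage", t$pos)
      }
      pending <- c(pending, list(list(link = r$trailing, child = r$node)))
    } else if (t$kind == "res") {
      st$i <- st$i + 1L
      node <- list(label = t$text, children = pending, orig = NA_integer_)
      pending <- list()
      nxt <- if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
      if (!is.null(nxt) && nxt$kind == "link") {
        st$i <- st$i + 1L
        lk <- parse_linkage_token(nxt$text, nxt$pos)
        after <- if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
        if (is.null(after) || after$kind == ")") {
          return(list(node = node, trailing = lk))
        }
        if (after$kind == "link") {
          glyre_parse_error("two adjacent linkage tokens", after$pos)
        }
        pending <- list(list(link = lk, child = node))
      } else if (!is.null(nxt) && nxt$kind == "res") {
        glyre_parse_error("two adjacent residue tokens with no linkage", nxt$pos)
      } else if (!is.null(nxt) && nxt$kind == "(") {
        glyre_parse_error("residue must be joined to what follows by a linkage",
                          nxt$pos)
      } else {
        return(list(node = node, trailing = NULL))
      }
    } else if (t$kind == "link") {
      glyre_parse_error("linkage without a preceding residue", t$pos)
    } else {
      glyre_parse_error("empty branch", t$pos)
    }
  }
}

#' Parse an IUPAC-condensed glycan string into a glycan graph
#'
#' Builds the rooted tree with alternating monosaccharide and linkage nodes.
#' The reducing-end residue (rightmost token) is the root; every edge points
#' child -> parent toward the root. Node indices are 1-based and equal the
#' token position in the canonical serialized string (see [to_string()] for
#' the canonical branch order).
#'
#' Both Unicode (alpha/beta, en-dash) and ASCII (a/b, hyphen) dialects are
#' accepted and normalized to ASCII. Whitespace is ignored.
#'
#' @param glycan A single IUPAC-condensed glycan string.
#' @return A `glycan_graph` object.
#' @examples
#' g <- parse_iupac("Neu5Acα2-3Galβ1-4(Fucα1-3)GlcNAc")
#' g$n_mono       # 4 monosaccharides, 7 nodes total
#' to_string(g)   # canonical ASCII form
#' @export
parse_iupac <- function(glycan) {
  if (!is.character(glycan) || length(glycan) != 1L || is.na(glycan)) {
    stop("glycan must be a single character string", call. = FALSE)
  }
  s <- normalize_glycan_string(glycan)
  if (!nzchar(s)) glyre_parse_error("empty glycan string", 1L)
  check_parens(s)
  st <- new.env(parent = emptyenv())
  st$toks <- tokenize_iupac(s)
  st$i <- 1L
  st$len <- nchar(s)
  r <- parse_chain_env(st)
  if (!is.null(r$trailing)) {
    glyre_parse_error("dangling linkage at the reducing end", st$len)
  }
  if (st$i <= length(st$toks)) {
    glyre_parse_error("unexpected token after chain root", st$toks[[st$i]]$pos)
  }
  build_glycan_graph(canonical_order(r$node))
}
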