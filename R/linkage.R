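# Glycosidic linkage labels.
#
# A linkage is a list(anomer, c_from, c_to): anomer is "a", "b" or "?";
# c_from is the donor carbon (1L, 2L, or NA for unknown); c_to is an integer
# vector of acceptor carbons, length > 1 encoding in-string ambiguity such
# as b1-3/4, NA meaning unknown. The fully unknown linkage serializes as
# "?1-?" (the conventional token) and parses back to anomer "?", c_from NA,
# c_to NA, so that it matches anything in both directions.

new_linkage <- function(anomer = "?", c_from = NA, c_to = NA) {
  anomer <- as.character(anomer)
  if (!anomer %in% c("a", "b", "?")) {
    stop("invalid anomeric configuration: '", anomer, "'", call. = FALSE)
  }
  c_to <- suppressWarnings(as.integer(c_to))
  c_to <- if (all(is.na(c_to))) NA_integer_ else sort(unique(c_to[!is.na(c_to)]))
  list(anomer = anomer,
       c_from = suppressWarnings(as.integer(c_from))[1L],
       c_to = c_to)
}

is_unknown_linkage <- function(lk) {
  lk$anomer == "?" && is.na(lk$c_from) && all(is.na(lk$c_to))
}

format_linkage <- function(lk) {
  if (is_unknown_linkage(lk)) return("?1-?")
  cf <- if (is.na(lk$c_from)) "?" else as.character(lk$c_from)
  ct <- vapply(lk$c_to, function(x) if (is.na(x)) "?" else as.character(x), "")
  paste0(lk$anomer, cf, "-", paste(ct, collapse = "/"))
}

# "a2-3", "b1-3/4", "?1-?" -> linkage. `pos` is the character offset in the
# input string, used in error messages only.
parse_linkage_token <- function(tok, pos = NA_integer_) {
  m <- regmatches(tok, regexec("^([ab?])([12?])-([1-9?])((/[1-9])*)$", tok))[[1L]]
  if (length(m) == 0L) {
    glyre_parse_error(paste0("malformed linkage token '", tok, "'"), pos)
  }
  anomer <- m[2L]
  c_from <- if (m[3L] == "?") NA_integer_ else as.integer(m[3L])
  c_to1 <- if (m[4L] == "?") NA_integer_ else as.integer(m[4L])
  extra <- if (nzchar(m[5L])) as.integer(strsplit(sub("^/", "", m[5L]), "/")[[1L]]) else integer()
  if (anomer == "?" && identical(c_from, 1L) && is.na(c_to1) && length(extra) == 0L) {
    # conventional fully-unknown token "?1-?"
    return(new_linkage("?", NA, NA))
  }
  if (is.na(c_to1) && length(extra) > 0L) {
    glyre_parse_error("cannot mix '?' with explicit acceptor carbons", pos)
  }
  new_linkage(anomer, c_from, c(c_to1, extra))
}

#' Monosaccharides that donate from carbon 2
#'
#' Ulosonic acids (sialic acids such as Neu5Ac/Neu5Gc, Kdn, Kdo and
#' relatives) are ketoses whose glycosidic bond forms from C2 rather than
#' C1. The default list is matched by prefix against the residue token, so
#' modified forms ("Neu5Ac9Ac") are covered.
#'
#' @return A character vector of residue-token prefixes.
#' @export
c2_donor_prefixes <- function() {
  c("Neu", "Kdn", "Kdo", "Leg", "Pse", "Aci", "Sia", "Fru")
}

# Donor carbon for a residue token: 2L for ulosonic acids, else 1L.
donor_carbon <- function(token, c2_prefixes = c2_donor_prefixes()) {
  if (any(startsWith(token, c2_prefixes))) 2L else 1L
}

#' Infer a full linkage from a pattern shorthand
#'
#' Pattern dialect linkages omit the donor carbon ("Mana6", "Galb3/4"); the
#' donor is inferred from the monosaccharide: C2 for ulosonic acids (see
#' [c2_donor_prefixes()]), C1 otherwise. An empty shorthand yields the fully
#' unknown linkage under the same donor rule.
#'
#' @param mono Residue token (e.g. "Man", "Neu5Ac").
#' @param shorthand Anomer + acceptor carbon(s), e.g. "a6", "b3/4", "?4";
#'   the full form ("a1-6") is also accepted and parsed literally. Empty
#'   string for a fully unspecified linkage.
#' @param c2_prefixes Residue-token prefixes that donate from C2.
#' @return A list of linkage labels, one per listed acceptor carbon.
#' @examples
#' infer_linkage("Man", "a6")      # alpha1-6
#' infer_linkage("Gal", "b3/4")    # beta1-3 and beta1-4
#' infer_linkage("Neu5Ac", "a3")   # alpha2-3 (C2 donor)
#' @export
infer_linkage <- function(mono, shorthand = "", c2_prefixes = c2_donor_prefixes()) {
  cf <- donor_carbon(mono, c2_prefixes)
  if (!nzchar(shorthand)) {
    return(list(new_linkage("?", cf, NA)))
  }
  if (grepl("-", shorthand, fixed = TRUE)) {
    lk <- parse_linkage_token(shorthand)
    return(split_linkage(lk))
  }
  m <- regmatches(shorthand, regexec("^([ab?])([1-9?])((/[1-9])*)$", shorthand))[[1L]]
  if (length(m) == 0L) {
    glyre_parse_error(paste0("malformed linkage shorthand '", shorthand, "'"), NA_integer_)
  }
  ct1 <- if (m[3L] == "?") NA_integer_ else as.integer(m[3L])
  extra <- if (nzchar(m[4L])) as.integer(strsplit(sub("^/", "", m[4L]), "/")[[1L]]) else integer()
  lapply(c(ct1, extra), function(ct) new_linkage(m[2L], cf, ct))
}

# One linkage with an ambiguous c_to vector -> list of single-c_to linkages.
split_linkage <- function(lk) {
  lapply(lk$c_to, function(ct) new_linkage(lk$anomer, lk$c_from, ct))
}

# Does the glycan linkage `lk` satisfy any of the pattern linkage `specs`?
# NULL specs = no constraint. "?"/NA components are wildcards on both sides.
link_matches <- function(specs, lk) {
  if (is.null(specs)) return(TRUE)
  for (s in specs) {
    ano_ok <- s$anomer == "?" || lk$anomer == "?" || s$anomer == lk$anomer
    if (!ano_ok) next
    from_ok <- is.na(s$c_from) || is.na(lk$c_from) || s$c_from == lk$c_from
    if (!from_ok) next
    to_ok <- all(is.na(s$c_to)) || all(is.na(lk$c_to)) ||
      length(intersect(s$c_to, lk$c_to)) > 0L
    if (to_ok) return(TRUE)
  }
  FALSE
}

# Classed parse error carrying a character offset.
glyre_parse_error <- function(msg, pos = NA_integer_) {
  full <- if (is.na(pos)) msg else sprintf("%s (offset %d)", msg, pos)
  stop(structure(class = c("glyre_parse_error", "error", "condition"),
                 list(message = full, call = sys.call(-1L))))
}
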