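# Application utilities on top of the engine: branch extraction and
# motif-count matrices for downstream enrichment / differential analyses
# (the statistics themselves are out of scope; the count table is the
# hand-off point).

#' A labelled branch-extraction query
#'
#' Pairs a glyco-regex pattern with a human-readable label. Queries for
#' branch extraction typically end in a lookahead asserting the shared core
#' (e.g. the N-glycan trimannosyl chitobiose core), so that the core is
#' required but not captured.
#'
#' @param pattern A pattern string; must contain at least one element
#'   outside lookaround groups.
#' @param label A short label for tables and output columns.
#' @return A `branch_query` list.
#' @examples
#' arm16 <- branch_query("Neu5Aca6Galb4GlcNAcb2Mana6(?=Manb4GlcNAcb4GlcNAc)",
#'                       label = "alpha1-6 arm")
#' @export
branch_query <- function(pattern, label = pattern) {
  ast <- parse_pattern(pattern)  # validates
  structure(list(pattern = pattern, label = label, ast = ast),
            class = "branch_query")
}

#' Extract matching sub-glycans (e.g. the alpha1-6 branch of N-glycans)
#'
#' Runs a query against one glycan and returns the serialized sub-glycan of
#' every match. Lookaround context (such as a core asserted by a lookahead)
#' must be present but is excluded from the extracted strings; a linkage at
#' the rootward boundary of a match (e.g. the a1-6 joining an arm to the
#' core) is part of the match's node set but dropped from the serialization
#' so that every extracted string is itself valid IUPAC-condensed.
#'
#' @param glycan A glycan string (or `glycan_graph`).
#' @param query A `branch_query` or a pattern string.
#' @param policy "greedy" (default) or "lazy".
#' @return Character vector of sub-glycan strings (empty when the branch is
#'   absent).
#' @examples
#' bi <- paste0("Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6",
#'              "(Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-3)Manb1-4GlcNAcb1-4GlcNAc")
#' extract_branch(bi, "Neu5Aca6Galb4GlcNAcb2Mana6(?=Manb4GlcNAcb4GlcNAc)")
#' @export
extract_branch <- function(glycan, query, policy = c("greedy", "lazy")) {
  policy <- match.arg(policy)
  pattern <- if (inherits(query, "branch_query")) query$ast else query
  m <- get_match(pattern, glycan, policy)
  m$match_strings
}

#' Count pattern matches across glycans
#'
#' Builds the motif-count matrix handed to downstream enrichment or
#' differential-abundance analyses: one row per glycan, one column per
#' query, each cell the number of distinct matches of that pattern in that
#' glycan. Row and column order follow the input order. Glycans that fail
#' to parse are kept as all-NA rows and reported via the `failures`
#' attribute (and a warning), not silently dropped.
#'
#' @param glycans Character vector of glycan strings.
#' @param queries Character vector of pattern strings, or a list of
#'   `branch_query` objects.
#' @param labels Column labels; defaults to the query labels/patterns.
#' @return A data frame of counts with `glycan` as the first column and one
#'   integer column per query; attribute `failures` holds a data frame of
#'   unparseable glycans and their error messages.
#' @examples
#' count_matches("Neu5Aca2-3Galb1-4(Fuca1-3)GlcNAc", c("Fuca3GlcNAc", "Xyl"))
#' @export
count_matches <- function(glycans, queries, labels = NULL) {
  qlist <- lapply(queries, function(q) {
    if (inherits(q, "branch_query")) q else branch_query(q)
  })
  if (is.null(labels)) labels <- vapply(qlist, function(q) q$label, character(1L))
  stopifnot(length(labels) == length(qlist))
  fail_glycan <- character()
  fail_error <- character()
  counts <- matrix(NA_integer_, nrow = length(glycans), ncol = length(qlist))
  for (i in seq_along(glycans)) {
    g <- tryCatch(parse_iupac(glycans[i]), error = function(e) e)
    if (inherits(g, "error")) {
      fail_glycan <- c(fail_glycan, glycans[i])
      fail_error <- c(fail_error, conditionMessage(g))
      next
    }
    for (j in seq_along(qlist)) {
      counts[i, j] <- length(trace_match(g, qlist[[j]]$ast))
    }
  }
  out <- data.frame(glycan = glycans, counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("glycan", labels)
  if (length(fail_glycan) > 0L) {
    warning(length(fail_glycan), " glycan(s) failed to parse; see attr(x, 'failures')",
            call. = FALSE)
  }
  attr(out, "failures") <- data.frame(glycan = fail_glycan, error = fail_error,
                                      stringsAsFactors = FALSE)
  out
}

# --- file input/output -------------------------------------------------------

#' Read glycan strings from a file
#'
#' Plain-text files hold one glycan per line ("#" comments and blank lines
#' ignored); CSV/TSV files need a named glycan column.
#'
#' @param path File path.
#' @param column Column name for CSV/TSV input; required for those formats.
#' @return Character vector of glycan strings.
#' @export
read_glycans <- function(path, column = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv")) {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            comment.char = "#", quote = "\"")
    if (is.null(column)) {
      stop("CSV/TSV input needs a glycan column name (column=...)", call. = FALSE)
    }
    if (!column %in% names(df)) {
      stop("column '", column, "' not found in ", path, call. = FALSE)
    }
    return(as.character(df[[column]]))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Write match results to JSON or TSV
#'
#' One record/row per (glycan, match) with 1-based node indices and the
#' serialized sub-glycan.
#'
#' @param results A `glyre_match` or a list of them.
#' @param path Output path; "" writes TSV to stdout.
#' @param format "tsv" or "json".
#' @return Invisibly, the data frame that was written.
#' @export
write_matches <- function(results, path = "", format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(results, "glyre_match")) results <- list(results)
  rows <- do.call(rbind, lapply(results, function(m) {
    if (length(m$matches) == 0L) {
      return(NULL)
    }
    data.frame(glycan = m$glycan,
               match = seq_along(m$matches),
               nodes = vapply(m$matches, function(ns) paste(ns, collapse = ","),
                              character(1L)),
               match_string = m$match_strings,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(glycan = character(), match = integer(),
                       nodes = character(), match_string = character(),
                       stringsAsFactors = FALSE)
  }
  if (format == "json") {
    recs <- lapply(results, function(m) {
      list(glycan = m$glycan,
           matches = lapply(m$matches, as.integer),
           match_strings = as.list(m$match_strings))
    })
    json <- jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE)
    if (nzchar(path)) writeLines(json, path) else cat(json, "\n")
  } else {
    utils::write.table(rows, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(rows)
}
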