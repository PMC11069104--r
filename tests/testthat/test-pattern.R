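# Pattern tokenization, parsing, linkage inference and count expansion.

el1 <- function(p) parse_pattern(p)$elements[[1L]]

test_that("shorthand linkages resolve with the C1/C2 donor rule", {
  e <- el1("Mana6")
  expect_identical(e$tokens, "Man")
  expect_false(e$wildcard)
  expect_length(e$linkage, 1L)
  expect_identical(format_linkage_public(e$linkage[[1L]]), "a1-6")

  e <- el1("Galb3/4")
  expect_length(e$linkage, 2L)
  expect_identical(vapply(e$linkage, format_linkage_public, ""),
                   c("b1-3", "b1-4"))

  e <- el1("Neu5Aca3")
  expect_identical(format_linkage_public(e$linkage[[1L]]), "a2-3")
})

test_that("infer_linkage matches its documented contract", {
  expect_identical(vapply(infer_linkage("Man", "a6"), format_linkage_public, ""),
                   "a1-6")
  expect_identical(vapply(infer_linkage("Gal", "b3/4"), format_linkage_public, ""),
                   c("b1-3", "b1-4"))
  expect_identical(vapply(infer_linkage("Neu5Ac", "a3"), format_linkage_public, ""),
                   "a2-3")
  expect_identical(vapply(infer_linkage("Kdn", "a8"), format_linkage_public, ""),
                   "a2-8")
  # empty shorthand: fully unspecified acceptor under the same donor rule
  lk <- infer_linkage("Gal", "")[[1L]]
  expect_identical(lk$anomer, "?")
  expect_equal(lk$c_from, 1L)
  expect_true(all(is.na(lk$c_to)))
  expect_equal(infer_linkage("Neu5Gc", "")[[1L]]$c_from, 2L)
})

test_that("wildcards '.' and 'Monosaccharide' are interchangeable", {
  # compare ASTs with source text and character offsets stripped
  strip <- function(p) {
    p$source <- ""
    p$elements <- lapply(p$elements, function(e) { e$pos <- NULL; e })
    p
  }
  a <- parse_pattern(".")
  b <- parse_pattern("Monosaccharide")
  expect_true(a$elements[[1L]]$wildcard)
  expect_identical(strip(a), strip(b))
  expect_identical(strip(parse_pattern("Galb4.b3Man")),
                   strip(parse_pattern("Galb4Monosaccharideb3Man")))
})

test_that("negation parses and tolerates whitespace", {
  a <- el1("!Fuc")
  expect_true(a$negated)
  expect_identical(a$tokens, "Fuc")
  b <- parse_pattern("! Fuc")
  expect_identical(parse_pattern("!Fuc")$elements, b$elements)
  # negation with a linkage constraint
  c_ <- el1("!Fuca3")
  expect_true(c_$negated)
  expect_length(c_$linkage, 1L)
})

test_that("quantifier glyph algebra holds as ASTs", {
  strip_src <- function(p) { p$source <- ""; p }
  expect_identical(strip_src(parse_pattern("Gal?")),
                   strip_src(parse_pattern("Gal{0,1}")))
  expect_identical(strip_src(parse_pattern("(Galb4GlcNAcb3)+")),
                   strip_src(parse_pattern("(Galb4GlcNAcb3){1,}")))
  e <- el1("(Gala3)*")
  expect_equal(e$quant, c(0, Inf))
  e <- el1("(Gala3)+?")
  expect_true(e$lazy)
  expect_equal(e$quant, c(1, Inf))
  e <- el1("(Gala3){2,5}")
  expect_equal(e$quant, c(2, 5))
})

test_that("token alternation builds one element with a token set", {
  e <- el1("Gal|GalNAcb4")
  expect_setequal(e$tokens, c("Gal", "GalNAc"))
  expect_length(e$linkage, 1L)
})

test_that("malformed patterns fail with position-bearing parse errors", {
  expect_error(parse_pattern("*Gal"), class = "glyre_parse_error")
  expect_error(parse_pattern("Gal{3,1}"), regexp = "min > max",
               class = "glyre_parse_error")
  expect_error(parse_pattern("Gal(?<=Man)Glc"), regexp = "lookbehind",
               class = "glyre_parse_error")
  expect_error(parse_pattern("Gal(?=Man)Glc"), regexp = "lookahead",
               class = "glyre_parse_error")
  expect_error(parse_pattern("(Galb4"), class = "glyre_parse_error")
  expect_error(parse_pattern("()Gal"), class = "glyre_parse_error")
  expect_error(parse_pattern("(?=Gal)"), regexp = "outside lookaround",
               class = "glyre_parse_error")
  expect_error(parse_pattern("Man*a3Gal"), class = "glyre_parse_error")
  expect_error(parse_pattern(""), class = "glyre_parse_error")
})

test_that("pattern fuzzing never fails with anything but a parse error", {
  set.seed(424L)
  chars <- c(LETTERS, letters, 0:9, "(", ")", "{", "}", "*", "+", "?", "!",
             "|", "/", "-", ".", " ")
  for (i in 1:400) {
    s <- paste(sample(chars, sample(1:12, 1L), replace = TRUE), collapse = "")
    res <- tryCatch({
      parse_pattern(s)
      "ok"
    },
    glyre_parse_error = function(e) "parse_error",
    error = function(e) paste("unexpected:", conditionMessage(e)))
    expect_true(res %in% c("ok", "parse_error"), info = s)
  }
})

test_that("expand_quantified materializes (substructure : counts) pairs", {
  cc <- expand_quantified(parse_pattern("Fuca3?"), ceiling = 5L)
  expect_s3_class(cc, "glyre_count_constraint")
  expect_identical(cc$allowed_counts, 0:1)
  expect_identical(cc$substructure$string, "Fuc")

  cc <- expand_quantified(parse_pattern("(Galb4GlcNAcb3){1,3}"), ceiling = 10L)
  expect_identical(cc$allowed_counts, 1:3)
  expect_identical(cc$substructure$string, "Galb1-4GlcNAc")
  expect_equal(cc$substructure$n_mono, 2L)

  cc <- expand_quantified(parse_pattern("(Gal)*"), ceiling = 5L)
  expect_identical(cc$allowed_counts, 0:5)
})
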