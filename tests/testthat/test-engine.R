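# The matching engine: segment matching, count checking, path tracing and
# the get_match entry point.

test_that("segment matches enumerate every embedding of a plain run", {
  sm <- segment_matches(SLEX, "Fuca3GlcNAc")
  expect_length(sm, 1L)
  expect_identical(sm[[1L]]$node_set, c(5L, 6L, 7L))
  expect_identical(unname(sm[[1L]]$attachment), c(5L, 7L))

  # a wildcard matches each residue once
  expect_length(segment_matches(SLEX, "."), 4L)
  # absent token
  expect_length(segment_matches(SLEX, "Xyl"), 0L)
  # quantified input is rejected
  expect_error(segment_matches(SLEX, "Gal+"), regexp = "plain")
})

test_that("check_counts enumerates tandem repeat chains", {
  cc <- expand_quantified(parse_pattern("(Galb4GlcNAcb3){1,3}"), ceiling = 10L)
  hits <- check_counts(POLYLACNAC2, cc)
  counts <- vapply(hits, function(h) h$count, integer(1L))
  expect_setequal(counts, c(1L, 2L))
  expect_identical(sort(vapply(hits[counts == 2L], function(h)
    length(h$node_set), integer(1L))), 8L)

  cc01 <- expand_quantified(parse_pattern("(Xyla3)?"), ceiling = 5L)
  hits <- check_counts(POLYLACNAC2, cc01)
  expect_length(hits, 1L)
  expect_identical(hits[[1L]]$count, 0L)
  expect_length(hits[[1L]]$node_set, 0L)

  cc2 <- expand_quantified(parse_pattern("(Galb4GlcNAcb3){3}"), ceiling = 10L)
  hits <- check_counts(POLYLACNAC2, cc2)  # only 2 tandem units available
  expect_length(hits, 0L)
})

test_that("the sialyl Lewis x worked example matches as expected", {
  m <- get_match("Neu5Aca3Galb4(Fuca3)GlcNAc", SLEX_UNI)
  expect_length(m$matches, 1L)
  expect_identical(m$matches[[1L]], 1:7)
  expect_identical(m$match_strings, "Neu5Aca2-3Galb1-4(Fuca1-3)GlcNAc")

  m <- get_match("Fuca3GlcNAc", SLEX_UNI)
  expect_length(m$matches, 1L)
  expect_identical(m$matches[[1L]], c(5L, 6L, 7L))

  # lookbehind keeps the context requirement but drops its node indices
  m <- get_match("(?<=Neu5Aca3)Galb4(Fuca3)GlcNAc", SLEX_UNI)
  expect_length(m$matches, 1L)
  expect_identical(m$matches[[1L]], 3:7)
})

test_that("positional negation matches non-excluded residues only", {
  # on sialyl Lewis x no a?-3-linked residue on GlcNAc other than Fuc exists
  m <- get_match("!Fuca3GlcNAc", SLEX)
  expect_length(m$matches, 0L)
  # on a Gal-a1-3 variant the negation is satisfied
  m <- get_match("!Fuca3GlcNAc", "Gala1-3GlcNAc")
  expect_length(m$matches, 1L)
})

test_that("identity and trivial cases behave", {
  m <- get_match(".", "Gal")
  expect_length(m$matches, 1L)
  expect_identical(m$matches[[1L]], 1L)
  expect_identical(m$match_strings, "Gal")
  expect_length(get_match("Glc", "Gal")$matches, 0L)
})

test_that("greedy returns maximal repeat chains, lazy minimal ones", {
  greedy <- trace_match(POLYLACNAC3, "(Galb4GlcNAcb3)+")
  expect_length(greedy, 1L)
  expect_identical(greedy[[1L]], 1:12)

  lazy <- trace_match(POLYLACNAC3, "(Galb4GlcNAcb3)+?")
  expect_length(lazy, 3L)
  expect_identical(lazy, list(1:4, 5:8, 9:12))

  # policy argument forces lazy without the glyph
  lazy2 <- trace_match(POLYLACNAC3, "(Galb4GlcNAcb3)+", policy = "lazy")
  expect_identical(lazy2, lazy)
})

test_that("matches are connected, deduplicated and deterministically ordered", {
  glycans <- generate_glycans(
    synthetic_glycan_spec(seed = 77L, max_residues = 12L, branch_prob = 0.3), 20L)
  set.seed(78L)
  for (gstr in glycans) {
    g <- parse_iupac(gstr)
    for (feature in c("plain", "wildcard", "quant_plus", "branch")) {
      pat <- sample_pattern(g, feature)
      m1 <- trace_match(g, pat)
      m2 <- trace_match(g, pat)
      expect_identical(m1, m2)  # bit-identical across runs
      expect_connected_matches(g, m1)
      keys <- vapply(m1, paste, character(1L), collapse = ",")
      expect_identical(keys, unique(keys))
      if (length(m1) > 1L) {
        expect_true(!is.unsorted(vapply(m1, min, integer(1L))))
      }
    }
  }
})

test_that("every lazy match is contained in some greedy match", {
  glycans <- generate_glycans(
    synthetic_glycan_spec(seed = 79L, max_residues = 10L), 15L)
  set.seed(80L)
  for (gstr in glycans) {
    g <- parse_iupac(gstr)
    for (feature in c("quant_star", "quant_plus", "quant_range")) {
      pat <- sample_pattern(g, feature)
      greedy <- trace_match(g, pat, policy = "greedy")
      lazy <- trace_match(g, pat, policy = "lazy")
      for (lm in lazy) {
        expect_true(any(vapply(greedy, function(gm) all(lm %in% gm),
                               logical(1L))),
                    info = paste(gstr, pat))
      }
    }
  }
})

test_that("widening an exact spec to a wildcard never loses matches", {
  glycans <- generate_glycans(
    synthetic_glycan_spec(seed = 81L, max_residues = 10L), 15L)
  set.seed(82L)
  for (gstr in glycans) {
    g <- parse_iupac(gstr)
    pat <- sample_pattern(g, "plain")
    n_exact <- length(trace_match(g, pat))
    # replace the first residue token with the wildcard
    ast <- parse_pattern(pat)
    first_tok <- ast$elements[[1L]]$tokens[1L]
    if (is.null(first_tok) || is.na(first_tok)) next
    wpat <- sub(first_tok, ".", pat, fixed = TRUE)
    n_wild <- length(trace_match(g, wpat))
    expect_gte(n_wild, n_exact)
  }
})

test_that("lookaround matches equal plain matches minus the context nodes", {
  # construct plain/lookbehind pairs on the biantennary fixture
  plain <- trace_match(BIANT, "Neu5Aca6Galb4GlcNAcb2Mana6Manb4GlcNAcb4GlcNAc")
  looked <- trace_match(BIANT, ARM16_QUERY)
  expect_length(plain, 1L)
  expect_length(looked, 1L)
  core <- 17:21
  expect_identical(looked[[1L]], setdiff(plain[[1L]], core))

  lb_plain <- trace_match(SLEX, "Neu5Aca3Galb4(Fuca3)GlcNAc")
  lb <- trace_match(SLEX, "(?<=Neu5Aca3)Galb4(Fuca3)GlcNAc")
  expect_identical(lb[[1L]], setdiff(lb_plain[[1L]], c(1L, 2L)))
})

test_that("unknown linkages match in both directions", {
  g <- "Gal?1-?GlcNAc"
  expect_length(trace_match(g, "Galb4GlcNAc"), 1L)
  expect_length(trace_match("Galb1-4GlcNAc", "Gal?1-?GlcNAc"), 1L)
  expect_length(trace_match("Galb1-4GlcNAc", "Gal?4GlcNAc"), 1L)
  expect_length(trace_match("Galb1-4GlcNAc", "Gala4GlcNAc"), 0L)
})

test_that("get_match propagates parse errors with input identification", {
  expect_error(get_match("Gal{3,1}", SLEX), regexp = "pattern")
  expect_error(get_match("Gal", "GalGlc"), regexp = "glycan")
})
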