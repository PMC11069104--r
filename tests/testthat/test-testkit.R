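# Synthetic glycan generator and brute-force oracle.

test_that("generation is deterministic under a fixed seed", {
  spec <- synthetic_glycan_spec(seed = 42L)
  expect_identical(generate_glycan(spec), generate_glycan(spec))
  expect_identical(generate_glycans(spec, 10L), generate_glycans(spec, 10L))
  # the generator does not disturb the caller's RNG stream
  set.seed(1L)
  before <- stats::runif(1L)
  set.seed(1L)
  invisible(generate_glycans(spec, 3L))
  expect_identical(stats::runif(1L), before)
})

test_that("a single-residue budget yields a bare alphabet token", {
  spec <- synthetic_glycan_spec(max_residues = 1L, seed = 7L)
  s <- generate_glycan(spec)
  expect_true(s %in% spec$alphabet)
})

test_that("generated glycans always parse and satisfy graph invariants", {
  spec <- synthetic_glycan_spec(seed = 11L, max_residues = 12L,
                                branch_prob = 0.35,
                                unknown_linkage_prob = 0.15)
  for (s in generate_glycans(spec, 150L)) {
    g <- parse_iupac(s)
    expect_silent(validate_glycan_graph(g))
    # C2 donors only on ulosonic acids
    for (i in which(g$type == "link")) {
      lk <- g$linkage[[i]]
      if (!is.na(lk$c_from) && lk$c_from == 2L) {
        donor <- g$children[[i]][1L]
        expect_true(startsWith(g$label[donor], "Neu") ||
                      startsWith(g$label[donor], "Kd"))
      }
    }
  }
})

test_that("branching frequency tracks branch_prob within binomial bounds", {
  p <- 0.25
  spec <- synthetic_glycan_spec(seed = 13L, max_residues = 10L,
                                branch_prob = p, unknown_linkage_prob = 0)
  glycans <- generate_glycans(spec, 1000L)
  branch_events <- 0L
  trials <- 0L
  for (s in glycans) {
    g <- parse_iupac(s)
    monos <- which(g$type == "mono")
    kids <- vapply(monos, function(m) length(g$children[[m]]), integer(1L))
    branch_events <- branch_events + sum(pmax(kids - 1L, 0L))
    trials <- trials + max(g$n_mono - 2L, 0L)
  }
  expect_gt(trials, 1000L)
  sd3 <- 3 * sqrt(trials * p * (1 - p))
  # small downward slack: branching is skipped when no internal node has a
  # free acceptor carbon
  expect_lt(abs(branch_events - trials * p), sd3 + 0.02 * trials)
})

test_that("oracle reproduces the worked examples by direct enumeration", {
  expect_identical(brute_force_match(".", "Gal"), list(1L))
  expect_identical(brute_force_match("Neu5Aca3Galb4(Fuca3)GlcNAc", SLEX),
                   list(1:7))
  expect_identical(brute_force_match("Fuca3GlcNAc", SLEX), list(c(5L, 6L, 7L)))
  big <- generate_glycans(synthetic_glycan_spec(seed = 3L, max_residues = 30L,
                                                branch_prob = 0),
                          5L)
  big <- big[vapply(big, function(s) parse_iupac(s)$n_mono, integer(1L)) > 14L]
  if (length(big) > 0L) {
    expect_error(brute_force_match("Gal", big[[1L]]), regexp = "refuses")
  }
})

test_that("engine and oracle agree on a mixed-feature smoke corpus", {
  glycans <- generate_glycans(
    synthetic_glycan_spec(seed = 21L, max_residues = 12L, branch_prob = 0.3,
                          unknown_linkage_prob = 0.1), 25L)
  set.seed(22L)
  for (gstr in glycans) {
    g <- parse_iupac(gstr)
    for (feature in pattern_features()) {
      pat <- sample_pattern(g, feature)
      expect_same_matches(trace_match(g, pat), brute_force_match(pat, gstr))
    }
  }
})
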