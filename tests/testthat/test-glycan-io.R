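# Parsing, canonical serialization and subsetting of glycan graphs.

test_that("sialyl Lewis x parses to the expected alternating tree", {
  g <- parse_iupac(SLEX_UNI)
  expect_s3_class(g, "glycan_graph")
  expect_equal(g$n_mono, 4L)
  expect_length(g$label, 7L)
  expect_identical(g$label,
                   c("Neu5Ac", "a2-3", "Gal", "b1-4", "Fuc", "a1-3", "GlcNAc"))
  expect_identical(g$type, rep(c("mono", "link"), length.out = 7L))
  expect_equal(g$root, 7L)
  expect_identical(g$label[g$root], "GlcNAc")
  # Gal and Fuc both hang off GlcNAc through their linkage nodes
  expect_setequal(mono_children_public(g, 7L), c(3L, 5L))
  # Unicode and ASCII dialects build the same graph
  expect_identical(g$string, parse_iupac(SLEX)$string)
  expect_identical(g$parent, parse_iupac(SLEX)$parent)
})

test_that("degenerate and small glycans parse", {
  g <- parse_iupac("Gal")
  expect_equal(g$n_mono, 1L)
  expect_length(g$label, 1L)
  expect_equal(g$root, 1L)
  expect_true(all(is.na(g$parent)))
  expect_identical(to_string(g), "Gal")
})

test_that("node count is 2k-1 and serialization is idempotent", {
  for (s in c(SLEX, BIANT, POLYLACNAC3, "Gal", "Mana1-2Man")) {
    g <- parse_iupac(s)
    expect_length(g$label, 2L * g$n_mono - 1L)
    canon <- to_string(g)
    expect_identical(to_string(parse_iupac(canon)), canon)
  }
})

test_that("parse errors carry class and offset", {
  expect_error(parse_iupac(""), class = "glyre_parse_error")
  expect_error(parse_iupac("Galb1-4(Fuca1-3GlcNAc"), class = "glyre_parse_error")
  expect_error(parse_iupac("Galb1-4)Fuca1-3(GlcNAc"), class = "glyre_parse_error")
  expect_error(parse_iupac("GalGlcNAc"), regexp = "adjacent residue",
               class = "glyre_parse_error")
  expect_error(parse_iupac("b1-4GlcNAc"), class = "glyre_parse_error")
  expect_error(parse_iupac("Galb1-4"), regexp = "dangling",
               class = "glyre_parse_error")
  err <- tryCatch(parse_iupac("GalGlcNAc"), error = identity)
  expect_match(conditionMessage(err), "offset")
})

test_that("unicode dialect serialization round-trips", {
  g <- parse_iupac(SLEX)
  uni <- to_string(g, dialect = "unicode")
  expect_identical(uni, "Neu5Acα2-3Galβ1-4(Fucα1-3)GlcNAc")
  expect_identical(parse_iupac(uni)$string, g$string)
})

test_that("subset serialization cuts at monosaccharides", {
  g <- parse_iupac(SLEX)
  expect_identical(to_string(g, c(5L, 6L, 7L)), "Fuca1-3GlcNAc")
  expect_identical(to_string(g, 7L), "GlcNAc")
  # whole-graph subset reproduces the canonical string
  expect_identical(to_string(g, seq_along(g$label)), g$string)
  # disconnected subset: Neu5Ac and Fuc without the path between
  expect_error(to_string(g, c(1L, 5L)), regexp = "connected")
  # linkage node separated from its child residue
  expect_error(to_string(g, c(6L, 7L)), regexp = "linkage")
})

test_that("glycan_subgraph re-indexes canonically and keeps the index map", {
  g <- parse_iupac(BIANT)
  full <- glycan_subgraph(g, seq_along(g$label))
  expect_identical(full$string, g$string)
  expect_identical(full$index_map, seq_along(g$label))

  root_only <- glycan_subgraph(g, g$root)
  expect_equal(root_only$n_mono, 1L)
  expect_identical(root_only$string, "GlcNAc")

  # the a1-6 arm (its joining a1-6 linkage is a rootward boundary: kept in
  # the node set but cut from the serialization)
  arm <- glycan_subgraph(g, 9:16)
  expect_identical(arm$string, "Neu5Aca2-6Galb1-4GlcNAcb1-2Man")
  expect_identical(arm$index_map, c(9L, 10L, 11L, 12L, 13L, 14L, 15L))
  expect_identical(g$label[arm$index_map], arm$label)
})

test_that("round trip holds on seeded synthetic glycans", {
  glycans <- generate_glycans(
    synthetic_glycan_spec(seed = 101L, max_residues = 12L, branch_prob = 0.3),
    50L)
  for (s in glycans) {
    g <- parse_iupac(s)
    expect_identical(to_string(g), s)
    g2 <- parse_iupac(to_string(g))
    expect_identical(g2$label, g$label)
    expect_identical(g2$parent, g$parent)
  }
})

test_that("read_glycans handles plain text and delimited files", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header comment", SLEX, "", "Gal  # inline"), tmp)
  expect_identical(read_glycans(tmp), c(SLEX, "Gal"))

  tmpc <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = 1:2, glycan = c(SLEX, "Gal")), tmpc,
                   row.names = FALSE)
  expect_identical(read_glycans(tmpc, column = "glycan"), c(SLEX, "Gal"))
  expect_error(read_glycans(tmpc), regexp = "column")
})
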