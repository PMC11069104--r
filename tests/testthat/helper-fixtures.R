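# Shared fixtures: structures printed in the glycobiology literature plus
# constructed repeat/branch fixtures. All built in code at test time.

# sialyl Lewis x; canonical node order:
# 1 Neu5Ac, 2 a2-3, 3 Gal, 4 b1-4, 5 Fuc, 6 a1-3, 7 GlcNAc
SLEX_UNI <- "Neu5Acα2-3Galβ1-4(Fucα1-3)GlcNAc"
SLEX <- "Neu5Aca2-3Galb1-4(Fuca1-3)GlcNAc"

# disialylated biantennary N-glycan; 11 residues, 21 nodes. Canonical form
# puts the a1-3 arm outside parentheses (lowest acceptor carbon on a depth
# tie), so nodes 1-8 are the a1-3 arm (incl. its a1-3 linkage), 9-16 the
# a1-6 arm (incl. a1-6), 17-21 the trimannosyl-chitobiose remainder
# (Man b1-4 GlcNAc b1-4 GlcNAc).
BIANT <- paste0("Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6",
                "(Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-3)",
                "Manb1-4GlcNAcb1-4GlcNAc")

ARM16_QUERY <- "Neu5Aca6Galb4GlcNAcb2Mana6(?=Manb4GlcNAcb4GlcNAc)"
ARM13_QUERY <- "Neu5Aca6Galb4GlcNAcb2Mana3(?=Manb4GlcNAcb4GlcNAc)"

# three tandem LacNAc units on a reducing-end Gal; unit i occupies nodes
# 4i-3 .. 4i (Gal, b1-4, GlcNAc, b1-3), root Gal is node 13
POLYLACNAC3 <- "Galb1-4GlcNAcb1-3Galb1-4GlcNAcb1-3Galb1-4GlcNAcb1-3Gal"
POLYLACNAC2 <- "Galb1-4GlcNAcb1-3Galb1-4GlcNAcb1-3Gal"

# mucin-type core 1 O-glycan (no N-glycan core)
OGLYCAN <- "Galb1-3GalNAc"

node_set_list <- function(m) lapply(m, as.integer)

expect_same_matches <- function(engine, oracle) {
  expect_identical(node_set_list(engine), node_set_list(oracle))
}

# every match must induce a connected subgraph: serialization only succeeds
# for connected subsets, so reuse it as the connectivity check
expect_connected_matches <- function(g, matches) {
  for (ns in matches) {
    expect_silent(to_string(g, ns))
  }
}

# residue children of residue i, hopping over the intervening linkage node
mono_children_public <- function(g, i) {
  links <- g$children[[i]]
  vapply(links, function(l) g$children[[l]][1L], integer(1L))
}

format_linkage_public <- function(lk) glyre:::format_linkage(lk)
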