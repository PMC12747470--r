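# Versioned substructure-pattern library for linker featurization, matched
# by VF2 subgraph isomorphism (igraph) on element-colored graphs. Matching
# deliberately ignores bond orders: linkers recovered from crystal
# structures carry distance-perceived orders while training molecules carry
# explicit ones, and connectivity+element patterns are invariant to that.
# A pattern count is the number of distinct atom sets inducing the pattern
# (subset semantics: a CH3 carbon also contains CH2 matches).

.pattern_version <- "fragments-v1"

pat <- function(name, elements, bonds = NULL) {
  b <- if (is.null(bonds)) {
    data.frame(i = integer(), j = integer())
  } else {
    data.frame(i = bonds[c(TRUE, FALSE)], j = bonds[c(FALSE, TRUE)])
  }
  list(name = name, elements = elements, bonds = b)
}

ring6 <- function(members, extra_el = character(), extra_bonds = integer()) {
  pat_bonds <- c(rbind(1:6, c(2:6, 1)))
  pat(NULL, c(members, extra_el), c(pat_bonds, extra_bonds))
}

.substructure_patterns <- local({
  p <- list()
  add <- function(name, elements, bonds = NULL) {
    q <- pat(name, elements, bonds); q$name <- name
    p[[length(p) + 1L]] <<- q
  }
  addring <- function(name, members, extra_el = character(), extra_bonds = integer()) {
    q <- ring6(members, extra_el, extra_bonds); q$name <- name
    p[[length(p) + 1L]] <<- q
  }
  # single-atom element presence counts
  for (el in c("C", "N", "O", "F", "Cl", "Br", "I", "S", "P", "H")) {
    add(paste0("count_", el), el)
  }
  # bonded pairs
  add("pair_C_O", c("C", "O"), c(1, 2))
  add("pair_C_N", c("C", "N"), c(1, 2))
  add("pair_C_S", c("C", "S"), c(1, 2))
  add("pair_C_F", c("C", "F"), c(1, 2))
  add("pair_C_Cl", c("C", "Cl"), c(1, 2))
  add("pair_C_Br", c("C", "Br"), c(1, 2))
  add("pair_C_I", c("C", "I"), c(1, 2))
  add("hydroxyl", c("O", "H"), c(1, 2))
  add("thiol", c("S", "H"), c(1, 2))
  add("nh", c("N", "H"), c(1, 2))
  # small groups
  add("nh2", c("H", "N", "H"), c(1, 2, 2, 3))
  add("nitro", c("O", "N", "O"), c(1, 2, 2, 3))
  add("carboxylic_acid", c("H", "O", "C", "O"), c(1, 2, 2, 3, 3, 4))
  add("o_c_o", c("O", "C", "O"), c(1, 2, 2, 3))
  add("ether_c_o_c", c("C", "O", "C"), c(1, 2, 2, 3))
  add("sec_amine_c_n_c", c("C", "N", "C"), c(1, 2, 2, 3))
  add("ch2", c("H", "C", "H"), c(1, 2, 2, 3))
  add("ch3", c("H", "C", "H", "H"), c(1, 2, 2, 3, 2, 4))
  add("c_c_o", c("C", "C", "O"), c(1, 2, 2, 3))
  add("c_c_n", c("C", "C", "N"), c(1, 2, 2, 3))
  add("n_c_o", c("N", "C", "O"), c(1, 2, 2, 3))
  add("tert_amine", c("C", "N", "C", "C"), c(1, 2, 2, 3, 2, 4))
  # rings
  addring("benzene_ring", rep("C", 6))
  addring("pyridine_ring", c("N", rep("C", 5)))
  addring("diazine_ring", c("N", "C", "N", "C", "C", "C"))
  add("cyclopentyl_ring", rep("C", 5), c(1, 2, 2, 3, 3, 4, 4, 5, 5, 1))
  add("azole_ring", c("N", rep("C", 4)), c(1, 2, 2, 3, 3, 4, 4, 5, 5, 1))
  # ring substitutions (position 7+ hangs off ring atom 1)
  addring("aniline_n_on_ring", rep("C", 6), "N", c(1, 7))
  addring("phenol_o_on_ring", rep("C", 6), c("O", "H"), c(1, 7, 7, 8))
  addring("ring_methyl", rep("C", 6), c("C", "H", "H", "H"),
          c(1, 7, 7, 8, 7, 9, 7, 10))
  addring("ring_F", rep("C", 6), "F", c(1, 7))
  addring("ring_Cl", rep("C", 6), "Cl", c(1, 7))
  addring("ring_Br", rep("C", 6), "Br", c(1, 7))
  addring("ring_nitro", rep("C", 6), c("N", "O", "O"), c(1, 7, 7, 8, 7, 9))
  addring("ring_carboxyl", rep("C", 6), c("C", "O", "O", "H"),
          c(1, 7, 7, 8, 7, 9, 9, 10))
  addring("pyridine_nitro", c("N", rep("C", 5)), c("N", "O", "O"),
          c(2, 7, 7, 8, 7, 9))
  addring("pyridine_amine", c("N", rep("C", 5)), c("N", "H", "H"),
          c(2, 7, 7, 8, 7, 9))
  add("biphenyl_link", c("C", "C"), c(1, 2))  # placeholder pair kept distinct below
  p
})
# drop the duplicate placeholder (pair_C_C would double-count every bond set)
.substructure_patterns <- Filter(function(q) q$name != "biphenyl_link",
                                 .substructure_patterns)

pattern_names <- function() vapply(.substructure_patterns, `[[`, character(1), "name")

.element_color <- function(elements) {
  # shared small integer palette for vf2 vertex colors
  palette <- c("H", "C", "N", "O", "F", "Cl", "Br", "I", "S", "P", "B", "Si")
  col <- match(elements, palette)
  col[is.na(col)] <- length(palette) + 1L
  as.integer(col)
}

mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol)))
  )
}

# count distinct atom subsets of `mol` inducing `pattern`
count_pattern <- function(mol, pattern, g = NULL, el_counts = NULL) {
  pel <- table(pattern$elements)
  mel <- if (is.null(el_counts)) table(mol$atoms$element) else el_counts
  for (e in names(pel)) {
    if (is.na(mel[e]) || mel[e] < pel[[e]]) return(0L)
  }
  if (nrow(pattern$bonds) == 0L) {
    return(as.integer(sum(mol$atoms$element == pattern$elements[1])))
  }
  if (is.null(g)) g <- mol_igraph(mol)
  pg <- igraph::graph_from_data_frame(pattern$bonds, directed = FALSE,
                                      vertices = data.frame(name = seq_along(pattern$elements)))
  maps <- igraph::subgraph_isomorphisms(
    pattern = pg, target = g, method = "vf2",
    # color1 belongs to the first graph of the underlying vf2 call (the
    # target), color2 to the pattern
    vertex.color1 = .element_color(mol$atoms$element),
    vertex.color2 = .element_color(pattern$elements[as.integer(igraph::V(pg)$name)])
  )
  if (!length(maps)) return(0L)
  sets <- unique(vapply(maps, function(m) paste(sort(as.integer(m)), collapse = ","),
                        character(1)))
  length(sets)
}

count_all_patterns <- function(mol) {
  g <- mol_igraph(mol)
  el_counts <- table(mol$atoms$element)
  vapply(.substructure_patterns, function(q) {
    as.numeric(count_pattern(mol, q, g = g, el_counts = el_counts))
  }, numeric(1)) |> stats::setNames(pattern_names())
}
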