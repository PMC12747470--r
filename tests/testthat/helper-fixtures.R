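# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small training set + model for unit tests (the full n = 2000 benchmark
# lives in the acceptance suite)
fixture_dataset <- function() memo("dataset", make_toxicity_dataset(n = 800, seed = 11))
fixture_model <- function() {
  memo("model", train_toxicity_classifier(fixture_dataset(), seed = 11,
                                          num_trees = 300))
}
fixture_guests <- function() memo("guests", make_guest_models())
fixture_ff <- function() memo("ff", forcefield())

# apply an atom permutation to a molecule (relabelling its graph)
permute_molecule <- function(mol, perm) {
  inv <- match(seq_along(perm), perm)
  small_molecule(mol$atoms[perm, , drop = FALSE],
                 data.frame(i = inv[mol$bonds$i], j = inv[mol$bonds$j],
                            order = mol$bonds$order),
                 net_charge = mol$net_charge, name = mol$name)
}

# minimal CIF with a 2-fold + mirror symmetry listing producing 4 images
cif_with_symops <- function() {
  paste(c(
    "data_symtest",
    "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "  'x, y, z'",
    "  '-x, -y, z'",
    "  'x, -y, -z'",
    "  '-x, y, -z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "C1 C 0.15 0.20 0.25",
    ""), collapse = "\n")
}
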