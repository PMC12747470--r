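# Canonical graph signatures for linker deduplication. Uses iterative
# neighborhood refinement (Weisfeiler-Lehman style) on element / bond-order
# labelled graphs: atom labels are repeatedly replaced by a hash of the
# label plus the sorted multiset of (bond order, neighbor label) pairs until
# the partition stabilizes, then the signature is the sorted atom-label
# multiset plus the sorted edge-label list. Isomorphic molecules always map
# to the same key; the (theoretical) WL blind spot - distinct strongly
# regular graphs - does not arise for chemical fragments of this size.

#' Canonical signature of a molecular graph
#'
#' A text key identical for isomorphic element-and-bond-order labelled
#' graphs and stable across atom orderings; used to deduplicate linkers.
#'
#' @param mol A connected [small_molecule()].
#' @return A character scalar key.
#' @examples
#' # two atom orderings of the same molecule give the same key
#' @export
canonical_signature <- function(mol) {
  stopifnot(inherits(mol, "small_molecule"))
  n <- n_atoms(mol)
  if (n == 0L) stop("empty molecule", call. = FALSE)
  if (n > 1L && !is_connected_mol(mol)) {
    stop("canonical_signature requires a connected molecule", call. = FALSE)
  }
  lab <- mol$atoms$element
  if (nrow(mol$bonds)) {
    adj <- vector("list", n)
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[r]; j <- mol$bonds$j[r]; o <- mol$bonds$order[r]
      adj[[i]] <- c(adj[[i]], list(c(j, o)))
      adj[[j]] <- c(adj[[j]], list(c(i, o)))
    }
    prev_k <- 0L
    for (iter in seq_len(n)) {
      new <- vapply(seq_len(n), function(i) {
        nb <- vapply(adj[[i]], function(e) paste0(format(e[2]), ":", lab[e[1]]),
                     character(1))
        paste0(lab[i], "|", paste(sort(nb), collapse = ","))
      }, character(1))
      # compress to small ids to keep strings bounded
      ids <- match(new, sort(unique(new)))
      lab <- paste0(mol$atoms$element, ids)
      k <- length(unique(lab))
      if (k == prev_k) break
      prev_k <- k
    }
  }
  edge_lab <- if (nrow(mol$bonds)) {
    sort(vapply(seq_len(nrow(mol$bonds)), function(r) {
      ends <- sort(c(lab[mol$bonds$i[r]], lab[mol$bonds$j[r]]))
      paste0(ends[1], "~", format(mol$bonds$order[r]), "~", ends[2])
    }, character(1)))
  } else character()
  paste0("atoms[", paste(sort(lab), collapse = ";"), "]",
         "bonds[", paste(edge_lab, collapse = ";"), "]")
}

is_connected_mol <- function(mol) {
  n <- n_atoms(mol)
  if (n <= 1L) return(TRUE)
  comp <- mol_components(mol)
  length(unique(comp)) == 1L
}

# connected components of the bond graph; returns integer component id per atom
mol_components <- function(mol) {
  n <- n_atoms(mol)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      a <- find(mol$bonds$i[r]); b <- find(mol$bonds$j[r])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), function(i) as.integer(find(i)), integer(1))
  match(roots, unique(roots))
}
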