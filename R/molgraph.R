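# Molecular graph container: element/bond connectivity with formal charges
# and optional atom-map indices. Hydrogens are implicit here (per-atom
# counts); they become explicit atoms only in 3D structures.

#' Construct a molecular graph
#'
#' Low-level constructor; most users will call [parse_smiles()] instead.
#'
#' @param atoms Data frame with columns `element`, `charge`, `aromatic`,
#'   `map_index`, `parity`, `isotope`, `implicit_h` (missing optional columns
#'   are filled with defaults).
#' @param bonds Data frame with columns `i`, `j`, `order` (1, 2, 3 or 1.5 for
#'   aromatic) and optionally `geom`.
#' @param total_charge Integer total molecular charge in units of e.
#' @param smiles Optional source SMILES string kept for provenance.
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds = NULL, total_charge = NULL, smiles = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L, "element" %in% names(atoms))
  defaults <- list(charge = 0L, aromatic = FALSE, map_index = NA_integer_,
                   parity = NA_integer_, isotope = NA_integer_,
                   implicit_h = 0L)
  for (col in names(defaults)) {
    if (is.null(atoms[[col]])) atoms[[col]] <- defaults[[col]]
  }
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0),
                        geom = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(bonds$geom)) bonds$geom <- NA_character_
  if (is.null(total_charge)) total_charge <- sum(atoms$charge)
  g <- structure(list(atoms = atoms, bonds = bonds,
                      total_charge = as.integer(total_charge),
                      smiles = smiles),
                 class = "molgraph")
  validate_molgraph(g)
  g
}

#' Validate molgraph invariants
#'
#' Checks that the total charge equals the sum of formal charges, that bond
#' endpoints are distinct valid atom indices, that bond orders are 1, 2, 3 or
#' aromatic (1.5), and that atom-map indices are unique where present.
#'
#' @param g A [molgraph].
#' @return `g`, invisibly; errors on violation.
#' @export
validate_molgraph <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  na <- nrow(g$atoms)
  if (g$total_charge != sum(g$atoms$charge)) {
    stop("molgraph invariant violated: total_charge != sum of formal charges")
  }
  b <- g$bonds
  if (nrow(b) > 0) {
    if (any(b$i == b$j)) stop("molgraph invariant violated: bond endpoints must differ")
    if (any(b$i < 1L | b$i > na | b$j < 1L | b$j > na)) {
      stop("molgraph invariant violated: bond endpoint out of range")
    }
    if (!all(b$order %in% c(1, 1.5, 2, 3))) {
      stop("molgraph invariant violated: bond order must be 1, 2, 3 or aromatic")
    }
  }
  maps <- g$atoms$map_index[!is.na(g$atoms$map_index)]
  if (anyDuplicated(maps)) {
    stop("molgraph invariant violated: duplicate atom-map indices")
  }
  invisible(g)
}

#' @export
print.molgraph <- function(x, ...) {
  heavy <- sum(x$atoms$element != "H")
  cat(sprintf("<molgraph> %d heavy atoms, %d bonds, charge %+d%s\n",
              heavy, nrow(x$bonds), x$total_charge,
              if (!is.null(x$smiles)) paste0("  [", x$smiles, "]") else ""))
  invisible(x)
}

#' Number of atoms / heavy atoms in a molgraph
#' @param g A [molgraph].
#' @return Integer count.
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' @rdname n_atoms
#' @export
n_heavy_atoms <- function(g) sum(g$atoms$element != "H")

#' Total electron count of a molecule
#'
#' Sum of atomic numbers over all atoms (implicit hydrogens included) minus
#' the total molecular charge.
#'
#' @param g A [molgraph].
#' @return Integer electron count.
#' @export
electron_count <- function(g) {
  z <- sum(atomic_number(g$atoms$element)) + sum(g$atoms$implicit_h)
  as.integer(z - g$total_charge)
}

#' Guess the spin multiplicity of a molecule
#'
#' Electron-parity rule: an even electron count gives a singlet (1), an odd
#' count a doublet (2). This is the crude-but-fast limit of automatic spin
#' guessing; backends may override it via their own configuration.
#'
#' @param g A [molgraph].
#' @return A positive integer multiplicity (2S + 1).
#' @examples
#' guess_multiplicity(parse_smiles("Oc1ccccc1"))  # 50 electrons -> 1
#' guess_multiplicity(parse_smiles("[CH3]"))      # 9 electrons -> 2
#' @export
guess_multiplicity <- function(g) {
  if (electron_count(g) %% 2L == 0L) 1L else 2L
}

# Expand implicit hydrogens into explicit H atoms appended after the original
# atoms (original indices are preserved). Returns a molgraph.
molgraph_explicit_h <- function(g) {
  nh <- g$atoms$implicit_h
  if (sum(nh) == 0L) return(g)
  atoms <- g$atoms
  bonds <- g$bonds
  for (a in seq_len(nrow(g$atoms))) {
    for (k in seq_len(nh[a])) {
      atoms <- rbind(atoms, data.frame(
        element = "H", charge = 0L, aromatic = FALSE,
        map_index = NA_integer_, parity = NA_integer_,
        isotope = NA_integer_, implicit_h = 0L, stringsAsFactors = FALSE))
      bonds <- rbind(bonds, data.frame(i = a, j = nrow(atoms), order = 1,
                                       geom = NA_character_,
                                       stringsAsFactors = FALSE))
    }
  }
  atoms$implicit_h <- 0L
  molgraph(atoms = atoms, bonds = bonds, total_charge = g$total_charge,
           smiles = g$smiles)
}

# Hydrogen-suppressed view: drop simple explicit H atoms (degree one, no
# charge or isotope) into their neighbor's hydrogen count.
molgraph_suppress_h <- function(g) {
  is_h <- g$atoms$element == "H" & g$atoms$charge == 0L & is.na(g$atoms$isotope)
  if (!any(is_h)) return(g)
  deg <- tabulate(c(g$bonds$i, g$bonds$j), nbins = nrow(g$atoms))
  drop <- which(is_h & deg == 1L)
  if (length(drop) == 0L) return(g)
  keep <- setdiff(seq_len(nrow(g$atoms)), drop)
  # neighbors of dropped H atoms absorb a hydrogen
  atoms <- g$atoms
  for (h in drop) {
    nb <- c(g$bonds$j[g$bonds$i == h], g$bonds$i[g$bonds$j == h])
    atoms$implicit_h[nb] <- atoms$implicit_h[nb] + 1L
  }
  remap <- match(seq_len(nrow(atoms)), keep)
  b <- g$bonds[!(g$bonds$i %in% drop | g$bonds$j %in% drop), , drop = FALSE]
  b$i <- remap[b$i]
  b$j <- remap[b$j]
  molgraph(atoms = atoms[keep, , drop = FALSE], bonds = b,
           total_charge = g$total_charge, smiles = g$smiles)
}

#' Canonical connectivity key of a molecule
#'
#' An isomorphism-invariant text key for the hydrogen-suppressed molecular
#' graph with formal charges; structures sharing this key belong to the same
#' compound. Bond orders are honored by encoding every bond as an auxiliary
#' colored vertex before canonicalization (BLISS, via
#' [igraph::canonical_permutation()]). 3D information and stereo descriptors
#' are deliberately ignored: compound identity is connectivity-only.
#'
#' @param g A [molgraph].
#' @return A character scalar key.
#' @export
connectivity_key <- function(g) {
  hs <- molgraph_suppress_h(g)
  na <- nrow(hs$atoms)
  atom_lab <- paste0(hs$atoms$element,
                     ifelse(hs$atoms$charge != 0L,
                            sprintf("%+d", hs$atoms$charge), ""),
                     "H", hs$atoms$implicit_h)
  nb <- nrow(hs$bonds)
  if (nb == 0L) {
    return(paste0("v1|", paste(sort(atom_lab), collapse = ","), "|"))
  }
  bond_lab <- paste0("b", hs$bonds$order)
  labels <- c(atom_lab, bond_lab)
  # bond k becomes vertex na + k, wired to its two endpoints
  edges <- rbind(
    cbind(hs$bonds$i, na + seq_len(nb)),
    cbind(hs$bonds$j, na + seq_len(nb))
  )
  ig <- igraph::make_graph(t(edges), n = na + nb, directed = FALSE)
  colors <- as.integer(factor(labels, levels = sort(unique(labels))))
  perm <- igraph::canonical_permutation(ig, colors = colors)$labeling
  canon_lab <- character(na + nb)
  canon_lab[perm] <- labels
  el <- igraph::as_edgelist(igraph::permute(ig, perm), names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0("v1|", paste(canon_lab, collapse = ","), "|",
         paste(el[, 1], el[, 2], sep = "-", collapse = ";"))
}

#' Test whether two molecular graphs have the same connectivity
#'
#' @param a,b [molgraph] objects.
#' @return Logical scalar.
#' @export
same_connectivity <- function(a, b) {
  identical(connectivity_key(a), connectivity_key(b))
}
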