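# Atom-to-atom mapping: which atoms rearrange between the two sides of a
# reaction. Used to prune reactive-trial enumeration to the bonds that
# actually change.

#' Derive an atom mapping from a mapped reaction SMILES
#'
#' Pairs up identical map indices across the two sides, then computes
#' \itemize{
#'   \item `changed_atoms`: map indices whose incident bond multiset
#'     (neighbors by map index or element, bond order, and hydrogen count)
#'     differs between reactants and products;
#'   \item `formed_bonds`: mapped atom pairs bonded in the products but not
#'     in the reactants;
#'   \item `broken_bonds`: the reverse.
#' }
#' Comparison is connectivity-only, so conformational change (or an identity
#' reaction) yields an empty `changed_atoms` set, and deriving from the
#' reversed reaction yields the same set.
#'
#' @param rxn Either a mapped reaction SMILES string or the result of
#'   [parse_reaction_smiles()].
#' @return An object of class `atom_mapping` with fields `pairs` (data frame
#'   of shared map indices), `changed_atoms`, `formed_bonds`, `broken_bonds`.
#' @examples
#' m <- derive_mapping("[CH3:1][I:2].[OH2:3]>>[CH3:1][OH:3].[IH:2]")
#' m$changed_atoms  # 1, 2, 3: all three heavy atoms change bonding
#' @export
derive_mapping <- function(rxn) {
  if (is.character(rxn)) rxn <- parse_reaction_smiles(rxn)
  stopifnot(is.list(rxn), !is.null(rxn$reactants), !is.null(rxn$products))

  side_info <- function(graphs, side) {
    maps <- integer(0)
    for (g in graphs) maps <- c(maps, g$atoms$map_index[!is.na(g$atoms$map_index)])
    if (anyDuplicated(maps)) {
      stop("non-bijective atom mapping: duplicate map index on the ",
           side, " side")
    }
    maps
  }
  rmaps <- side_info(rxn$reactants, "reactant")
  pmaps <- side_info(rxn$products, "product")
  shared <- intersect(rmaps, pmaps)
  if (length(shared) == 0L) stop("no shared atom-map indices between sides")

  # incident bond multiset of every mapped atom on one side
  bond_env <- function(graphs) {
    out <- list()
    adj <- list()
    for (g in graphs) {
      maps <- g$atoms$map_index
      for (a in which(!is.na(maps))) {
        m <- as.character(maps[a])
        entries <- character(0)
        b <- g$bonds
        inc <- which(b$i == a | b$j == a)
        for (k in inc) {
          nb <- if (b$i[k] == a) b$j[k] else b$i[k]
          nb_key <- if (!is.na(maps[nb])) paste0("m", maps[nb])
                    else paste0("e", g$atoms$element[nb])
          entries <- c(entries, paste0(nb_key, "|", b$order[k]))
        }
        entries <- c(entries, rep("eH|1", g$atoms$implicit_h[a]))
        out[[m]] <- paste(sort(entries), collapse = ",")
        nb_maps <- integer(0)
        for (k in inc) {
          nb <- if (b$i[k] == a) b$j[k] else b$i[k]
          if (!is.na(maps[nb])) nb_maps <- c(nb_maps, maps[nb])
        }
        adj[[m]] <- sort(nb_maps)
      }
    }
    list(multisets = out, adj = adj)
  }
  re <- bond_env(rxn$reactants)
  pe <- bond_env(rxn$products)

  changed <- shared[vapply(shared, function(m) {
    !identical(re$multisets[[as.character(m)]], pe$multisets[[as.character(m)]])
  }, logical(1))]

  pair_set <- function(adj, within) {
    pairs <- matrix(integer(0), ncol = 2)
    for (m in within) {
      for (nb in adj[[as.character(m)]]) {
        if (nb %in% within && m < nb) pairs <- rbind(pairs, c(m, nb))
      }
    }
    pairs
  }
  rpairs <- pair_set(re$adj, shared)
  ppairs <- pair_set(pe$adj, shared)
  pk <- function(m) if (nrow(m) == 0) character(0) else paste(m[, 1], m[, 2])
  formed <- ppairs[!(pk(ppairs) %in% pk(rpairs)), , drop = FALSE]
  broken <- rpairs[!(pk(rpairs) %in% pk(ppairs)), , drop = FALSE]
  colnames(formed) <- colnames(broken) <- c("a", "b")

  structure(list(
    pairs = data.frame(reactant = sort(shared), product = sort(shared)),
    changed_atoms = sort(changed),
    formed_bonds = formed,
    broken_bonds = broken,
    reaction = rxn
  ), class = "atom_mapping")
}

#' @export
print.atom_mapping <- function(x, ...) {
  cat(sprintf("<atom_mapping> %d mapped atoms, %d changed, %d formed / %d broken bonds\n",
              nrow(x$pairs), length(x$changed_atoms),
              nrow(x$formed_bonds), nrow(x$broken_bonds)))
  invisible(x)
}
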