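# Stereoisomer enumeration for molecules whose SMILES left stereo elements
# unspecified. Every unspecified tetrahedral center and double-bond geometry
# is assigned both ways, so a molecule with k unspecified elements yields
# 2^k graphs (capped, see `max_elements`). Specified descriptors are never
# touched. Inputs whose stereochemistry cannot be expressed in SMILES at all
# (e.g. axial chirality) are beyond this representation; callers can flag
# such molecules as stereo-incomplete rather than guessing.

# Weisfeiler-Lehman style refinement labels on the graph with one atom
# removed; used to decide whether two substituents of a candidate center are
# distinguishable.
.wl_branch_signature <- function(g, root, exclude) {
  na <- nrow(g$atoms)
  keep <- setdiff(seq_len(na), exclude)
  lab <- paste(g$atoms$element, g$atoms$charge, g$atoms$implicit_h,
               g$atoms$aromatic)
  adj <- vector("list", na)
  b <- g$bonds
  for (k in seq_len(nrow(b))) {
    if (b$i[k] %in% keep && b$j[k] %in% keep) {
      adj[[b$i[k]]] <- rbind(adj[[b$i[k]]], c(b$j[k], b$order[k]))
      adj[[b$j[k]]] <- rbind(adj[[b$j[k]]], c(b$i[k], b$order[k]))
    }
  }
  iters <- min(na, 8L)
  for (it in seq_len(iters)) {
    new_lab <- lab
    for (v in keep) {
      nb <- adj[[v]]
      if (is.null(nb)) next
      entries <- sort(paste0(nb[, 2], ":", lab[nb[, 1]]))
      new_lab[v] <- paste0(lab[v], "{", paste(entries, collapse = ","), "}")
    }
    # re-compress to keep strings bounded
    new_lab <- as.character(match(new_lab, sort(unique(new_lab))))
    prefix <- paste(g$atoms$element, g$atoms$charge, g$atoms$implicit_h,
                    g$atoms$aromatic)
    lab <- paste0(prefix, "#", new_lab)
  }
  # reachable component from root (graph minus excluded atom)
  seen <- rep(FALSE, na)
  queue <- root
  seen[root] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- adj[[v]]
    if (!is.null(nb)) {
      for (w in nb[, 1]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  paste0(lab[root], "||", paste(sort(lab[seen]), collapse = ";"))
}

# Indices of atoms that are unspecified tetrahedral stereocenter candidates:
# four pairwise-distinguishable substituents (implicit hydrogens count, so at
# most one of them), parity not already set, not aromatic.
.unspecified_tetrahedral <- function(g) {
  out <- integer(0)
  b <- g$bonds
  deg <- tabulate(c(b$i, b$j), nbins = nrow(g$atoms))
  for (a in seq_len(nrow(g$atoms))) {
    if (g$atoms$aromatic[a] || !is.na(g$atoms$parity[a])) next
    nh <- g$atoms$implicit_h[a]
    if (deg[a] + nh != 4L || nh > 1L) next
    inc <- which(b$i == a | b$j == a)
    if (any(b$order[inc] != 1)) next
    nbs <- ifelse(b$i[inc] == a, b$j[inc], b$i[inc])
    sigs <- vapply(nbs, function(v) .wl_branch_signature(g, v, a), character(1))
    if (nh == 1L) sigs <- c(sigs, "implicitH")
    if (anyDuplicated(sigs) == 0L) out <- c(out, a)
  }
  out
}

# Bond table rows that are unspecified double-bond geometry candidates: a
# non-ring C=C (or C=N) whose two ends each carry distinguishable
# substituents.
.unspecified_double_bonds <- function(g) {
  b <- g$bonds
  nb <- nrow(b)
  if (nb == 0L) return(integer(0))
  in_ring <- rep(FALSE, nb)
  if (nb > 0) {
    ig <- igraph::make_graph(t(cbind(b$i, b$j)), n = nrow(g$atoms),
                             directed = FALSE)
    in_ring <- !(seq_len(nb) %in% as.integer(igraph::bridges(ig)))
  }
  out <- integer(0)
  for (k in which(b$order == 2 & is.na(b$geom) & !in_ring)) {
    ends <- c(b$i[k], b$j[k])
    ok <- TRUE
    for (e in seq_along(ends)) {
      a <- ends[e]
      other <- ends[3 - e]
      inc <- which((b$i == a | b$j == a) & seq_len(nb) != k)
      nbs <- ifelse(b$i[inc] == a, b$j[inc], b$i[inc])
      nh <- g$atoms$implicit_h[a]
      sigs <- vapply(nbs, function(v) .wl_branch_signature(g, v, a), character(1))
      sigs <- c(sigs, rep("implicitH", nh))
      if (length(sigs) != 2L || anyDuplicated(sigs) > 0L) {
        ok <- FALSE
        break
      }
    }
    if (ok) out <- c(out, k)
  }
  out
}

#' Enumerate stereoisomers of a molecular graph
#'
#' Returns one graph per assignment of every *unspecified* stereo element
#' (tetrahedral centers get parity `@`/`@@`, double bonds get `E`/`Z`);
#' elements already specified in the input are untouched. A molecule with k
#' unspecified elements yields `2^k` graphs; enumeration is capped at
#' `2^max_elements` (further elements are left unspecified and a warning is
#' emitted) to bound the downstream exploration.
#'
#' @param g A [molgraph].
#' @param max_elements Cap on the number of enumerated stereo elements
#'   (default 6, i.e. at most 64 isomers).
#' @return A list of [molgraph] objects (length `2^k`, at least 1).
#' @examples
#' length(enumerate_stereoisomers(parse_smiles("CCI")))      # 1
#' length(enumerate_stereoisomers(parse_smiles("CC(F)Cl")))  # 2
#' length(enumerate_stereoisomers(parse_smiles("FC=CF")))    # 2 (E and Z)
#' @export
enumerate_stereoisomers <- function(g, max_elements = 6L) {
  centers <- .unspecified_tetrahedral(g)
  dbonds <- .unspecified_double_bonds(g)
  n_el <- length(centers) + length(dbonds)
  if (n_el > max_elements) {
    warning(sprintf("%d unspecified stereo elements; enumerating only the first %d",
                    n_el, max_elements))
    keep <- seq_len(max_elements)
    el_is_center <- c(rep(TRUE, length(centers)), rep(FALSE, length(dbonds)))[keep]
    ids <- c(centers, dbonds)[keep]
    centers <- ids[el_is_center]
    dbonds <- ids[!el_is_center]
    n_el <- max_elements
  }
  if (n_el == 0L) return(list(g))

  grid <- expand.grid(rep(list(c(1L, 2L)), n_el))
  lapply(seq_len(nrow(grid)), function(r) {
    iso <- g
    col <- 1L
    for (a in centers) {
      iso$atoms$parity[a] <- grid[r, col]
      col <- col + 1L
    }
    for (k in dbonds) {
      iso$bonds$geom[k] <- c("E", "Z")[grid[r, col]]
      col <- col + 1L
    }
    iso
  })
}
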