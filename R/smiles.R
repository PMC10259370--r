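# SMILES parsing into molecular graphs.
#
# The dialect is Daylight-style: organic subset atoms (B, C, N, O, P, S, F,
# Cl, Br, I and their aromatic lowercase forms), bracket atoms with isotope,
# chirality (@/@@), hydrogen count, formal charge and atom-map class (:n),
# ring-bond digits including %nn, branches, dot-separated fragments and the
# bond symbols - = # : / \. Aromaticity follows the notation: lowercase atoms
# are aromatic, and an unannotated bond between two aromatic atoms is
# aromatic when it lies in a ring (resolved after parsing) and single
# otherwise.

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.aromatic_organic <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a molecular graph
#'
#' Builds a [molgraph] with perceived (notation-based) aromaticity, formal
#' charges, implicit hydrogen counts and optional atom-map indices. Hydrogens
#' stay implicit unless written as explicit `[H]` atoms.
#'
#' @param smiles A single SMILES string.
#' @return A [molgraph] object.
#' @examples
#' g <- parse_smiles("Oc1ccccc1")   # phenol
#' sum(g$atoms$element != "H")      # 7 heavy atoms
#' parse_smiles("[O-]c1ccccc1")$total_charge  # phenolate, -1
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty SMILES string")

  atoms <- list()     # each: list(element, charge, aromatic, h_explicit, map, parity, isotope)
  bonds <- list()     # each: list(i, j, sym) with sym the bond token ("" = default)
  prev <- NA_integer_
  pending <- ""       # bond symbol awaiting the next atom
  stack <- integer(0)
  rings <- list()     # open ring bonds: key = ring number, value = list(atom, sym, pos)

  fail <- function(pos, msg) {
    stop(sprintf("SMILES parse error at position %d ('%s'): %s",
                 pos, substr(smiles, pos, pos), msg), call. = FALSE)
  }

  add_atom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = idx, sym = pending)
    }
    prev <<- idx
    pending <<- ""
    idx
  }

  close_ring <- function(num, pos) {
    key <- as.character(num)
    if (is.na(prev)) fail(pos, "ring bond before any atom")
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, sym = pending, pos = pos)
    } else {
      open <- rings[[key]]
      sym <- pending
      if (nzchar(open$sym) && nzchar(sym) && open$sym != sym) {
        fail(pos, sprintf("conflicting ring-bond symbols '%s' vs '%s'",
                          open$sym, sym))
      }
      if (!nzchar(sym)) sym <- open$sym
      if (open$atom == prev) fail(pos, "ring bond to the same atom")
      bonds[[length(bonds) + 1L]] <<- list(i = open$atom, j = prev, sym = sym)
      rings[[key]] <<- NULL
    }
    pending <<- ""
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) fail(i, "branch cannot start a SMILES")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) fail(i, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (nzchar(pending)) fail(i, "two bond symbols in a row")
      pending <- ch
      i <- i + 1L
    } else if (ch == ".") {
      if (nzchar(pending)) fail(i, "bond symbol before '.'")
      prev <- NA_integer_
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch), i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("[0-9]", chars[i + 1L]) ||
          !grepl("[0-9]", chars[i + 2L])) {
        fail(i, "'%' must be followed by two digits")
      }
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])), i)
      i <- i + 3L
    } else if (ch == "[") {
      res <- .parse_bracket(chars, i, fail)
      add_atom(res$atom)
      i <- res$next_pos
    } else {
      # organic subset, two-letter symbols first
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(list(element = two, charge = 0L, aromatic = FALSE,
                      h_explicit = NA_integer_, map = NA_integer_,
                      parity = NA_integer_, isotope = NA_integer_))
        i <- i + 2L
      } else if (ch %in% .organic_subset) {
        add_atom(list(element = ch, charge = 0L, aromatic = FALSE,
                      h_explicit = NA_integer_, map = NA_integer_,
                      parity = NA_integer_, isotope = NA_integer_))
        i <- i + 1L
      } else if (ch %in% .aromatic_organic) {
        add_atom(list(element = toupper(ch), charge = 0L, aromatic = TRUE,
                      h_explicit = NA_integer_, map = NA_integer_,
                      parity = NA_integer_, isotope = NA_integer_))
        i <- i + 1L
      } else {
        fail(i, "unexpected character")
      }
    }
  }
  if (length(stack) > 0L) stop("SMILES parse error: unmatched '('")
  if (length(rings) > 0L) {
    stop("SMILES parse error: unclosed ring bond(s) ",
         paste(names(rings), collapse = ", "))
  }
  if (nzchar(pending)) stop("SMILES parse error: dangling bond symbol")

  .assemble_molgraph(atoms, bonds, smiles)
}

# Parse a bracket atom starting at position pos (chars[pos] == "["). Returns
# list(atom = ..., next_pos = ...).
.parse_bracket <- function(chars, pos, fail) {
  n <- length(chars)
  i <- pos + 1L
  take_digits <- function(i) {
    j <- i
    while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
    list(value = if (j > i) as.integer(paste(chars[i:(j - 1L)], collapse = "")) else NA_integer_,
         next_pos = j)
  }
  d <- take_digits(i)
  isotope <- d$value
  i <- d$next_pos
  if (i > n) fail(pos, "unterminated bracket atom")

  aromatic <- FALSE
  two <- if (i < n) paste0(chars[i], chars[i + 1L]) else ""
  if (grepl("^[A-Z][a-z]$", two) && two %in% .element_table$symbol) {
    element <- two
    i <- i + 2L
  } else if (grepl("^[A-Z]$", chars[i]) && chars[i] %in% .element_table$symbol) {
    element <- chars[i]
    i <- i + 1L
  } else if (two %in% c("se", "as")) {
    element <- paste0(toupper(substr(two, 1, 1)), substr(two, 2, 2))
    aromatic <- TRUE
    i <- i + 2L
  } else if (chars[i] %in% .aromatic_organic) {
    element <- toupper(chars[i])
    aromatic <- TRUE
    i <- i + 1L
  } else {
    fail(i, "expected element symbol in bracket atom")
  }

  parity <- NA_integer_
  if (i <= n && chars[i] == "@") {
    parity <- 1L
    i <- i + 1L
    if (i <= n && chars[i] == "@") {
      parity <- 2L
      i <- i + 1L
    }
  }

  h_explicit <- 0L
  if (i <= n && chars[i] == "H") {
    i <- i + 1L
    d <- take_digits(i)
    h_explicit <- if (is.na(d$value)) 1L else d$value
    i <- d$next_pos
  }

  charge <- 0L
  if (i <= n && chars[i] %in% c("+", "-")) {
    sign <- if (chars[i] == "+") 1L else -1L
    sym <- chars[i]
    i <- i + 1L
    d <- take_digits(i)
    if (!is.na(d$value)) {
      charge <- sign * d$value
      i <- d$next_pos
    } else {
      charge <- sign
      while (i <= n && chars[i] == sym) {
        charge <- charge + sign
        i <- i + 1L
      }
    }
  }

  map <- NA_integer_
  if (i <= n && chars[i] == ":") {
    i <- i + 1L
    d <- take_digits(i)
    if (is.na(d$value)) fail(i, "':' in bracket atom must be followed by a map index")
    map <- d$value
    i <- d$next_pos
  }

  if (i > n || chars[i] != "]") fail(min(i, n), "expected ']'")
  list(atom = list(element = element, charge = charge, aromatic = aromatic,
                   h_explicit = h_explicit, map = map, parity = parity,
                   isotope = isotope),
       next_pos = i + 1L)
}

# Turn raw parser output into a validated molgraph: resolve default bond
# orders, demote would-be aromatic bonds that are not in a ring, assign
# implicit hydrogens and mark stereo-specified double bonds.
.assemble_molgraph <- function(atoms, bonds, smiles) {
  na <- length(atoms)
  atom_df <- data.frame(
    element = vapply(atoms, `[[`, character(1), "element"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    h_explicit = vapply(atoms, `[[`, integer(1), "h_explicit"),
    map_index = vapply(atoms, `[[`, integer(1), "map"),
    parity = vapply(atoms, `[[`, integer(1), "parity"),
    isotope = vapply(atoms, `[[`, integer(1), "isotope"),
    stringsAsFactors = FALSE
  )

  nb <- length(bonds)
  bi <- vapply(bonds, `[[`, integer(1), "i")
  bj <- vapply(bonds, `[[`, integer(1), "j")
  sym <- vapply(bonds, `[[`, character(1), "sym")
  if (nb > 0 && anyDuplicated(paste(pmin(bi, bj), pmax(bi, bj)))) {
    stop("SMILES parse error: duplicate bond between the same atoms")
  }

  order <- numeric(nb)
  geom_sym <- character(nb)
  for (k in seq_len(nb)) {
    order[k] <- switch(sym[k],
      "-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "/" = 1, "\\" = 1,
      # default bond: aromatic candidate when both atoms are aromatic
      if (atom_df$aromatic[bi[k]] && atom_df$aromatic[bj[k]]) 1.5 else 1
    )
    geom_sym[k] <- if (sym[k] %in% c("/", "\\")) sym[k] else ""
  }

  # Demote default aromatic bonds that do not lie in a ring (e.g. biphenyl's
  # inter-ring bond): a bond is in a ring iff it is not a graph bridge.
  candidate <- order == 1.5 & sym == ""
  if (any(candidate) && nb > 0) {
    g <- igraph::make_graph(rbind(bi, bj), n = na, directed = FALSE)
    bridge_ids <- igraph::bridges(g)
    in_ring <- !(seq_len(nb) %in% as.integer(bridge_ids))
    order[candidate & !in_ring] <- 1
  }

  bond_df <- data.frame(i = bi, j = bj, order = order,
                        geom = rep(NA_character_, nb),
                        stringsAsFactors = FALSE)

  # Double bonds flanked by a directional bond are stereo-specified.
  if (nb > 0) {
    directional_atoms <- unique(c(bi[geom_sym != ""], bj[geom_sym != ""]))
    dbl <- which(order == 2)
    for (k in dbl) {
      if (bi[k] %in% directional_atoms || bj[k] %in% directional_atoms) {
        bond_df$geom[k] <- "specified"
      }
    }
  }

  # Implicit hydrogens: bracket atoms carry their explicit count; organic
  # subset atoms get the smallest default valence accommodating the bond sum
  # (aromatic bonds count 1.5).
  implicit_h <- integer(na)
  for (a in seq_len(na)) {
    if (!is.na(atom_df$h_explicit[a])) {
      implicit_h[a] <- atom_df$h_explicit[a]
      next
    }
    vs <- .default_valences[[atom_df$element[a]]]
    if (is.null(vs)) {
      implicit_h[a] <- 0L
      next
    }
    bsum <- sum(bond_df$order[bond_df$i == a | bond_df$j == a])
    need <- as.integer(ceiling(bsum - 1e-9))
    v <- vs[vs >= need]
    implicit_h[a] <- if (length(v) == 0L) 0L else v[1] - need
  }
  atom_df$implicit_h <- implicit_h
  atom_df$h_explicit <- NULL

  molgraph(atoms = atom_df, bonds = bond_df,
           total_charge = sum(atom_df$charge), smiles = smiles)
}

#' Parse a (possibly atom-mapped) reaction SMILES
#'
#' Splits `reactants>agents>products` on `>` and each side on `.` into
#' individual molecular graphs.
#'
#' @param rxn_smiles A reaction SMILES string with two `>` separators.
#' @return A list with components `reactants`, `agents` and `products`, each a
#'   list of [molgraph] objects (possibly empty for `agents`).
#' @export
parse_reaction_smiles <- function(rxn_smiles) {
  stopifnot(is.character(rxn_smiles), length(rxn_smiles) == 1L)
  parts <- strsplit(rxn_smiles, ">", fixed = TRUE)[[1]]
  if (length(parts) == 2L) parts <- c(parts[1], "", parts[2])
  if (length(parts) != 3L) {
    stop("reaction SMILES must contain exactly two '>' separators")
  }
  side <- function(txt) {
    if (!nzchar(txt)) return(list())
    lapply(strsplit(txt, ".", fixed = TRUE)[[1]], parse_smiles)
  }
  list(reactants = side(parts[1]), agents = side(parts[2]),
       products = side(parts[3]))
}
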