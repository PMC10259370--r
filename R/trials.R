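# Constrained bimolecular reactive-trial enumeration.
#
# A trial brings two molecules together with exactly one forming
# intermolecular bond, parameterized by the atom pair, a rotamer index and an
# attack-point index. Default constraints mirror a narrow production setup:
# bimolecular only, one bond modification, every non-hydrogen atom reactive,
# two rotamers and two attack points per reactive pair. An atom-to-atom
# mapping, when available, prunes the enumeration to the bonds that actually
# form in the mapped reaction.

#' Trial-generation constraints
#'
#' @param reactive_atom_rule `"heavy"` (default; every non-hydrogen atom is
#'   reactive) or `"all"`.
#' @param mapping Optional [derive_mapping()] result; restricts reactive
#'   atoms to those participating in a formed bond, and trial pairs to the
#'   formed cross-bonds.
#' @param n_rotamers Rotamer structures per reactive pair (default 2).
#' @param n_attack_points Attack points per reactive pair (default 2).
#' @param max_bond_modifications Simultaneous bond modifications (default 1;
#'   larger values broaden the search and are accepted for counting purposes
#'   only).
#' @param allow_unimolecular,allow_dissociation Off by default, matching the
#'   bimolecular-association-only search narrowing.
#' @return An object of class `trial_constraints`.
#' @export
trial_constraints <- function(reactive_atom_rule = c("heavy", "all"),
                              mapping = NULL, n_rotamers = 2L,
                              n_attack_points = 2L,
                              max_bond_modifications = 1L,
                              allow_unimolecular = FALSE,
                              allow_dissociation = FALSE) {
  reactive_atom_rule <- match.arg(reactive_atom_rule)
  stopifnot(n_rotamers >= 1L, n_attack_points >= 1L,
            max_bond_modifications >= 1L)
  if (!is.null(mapping)) stopifnot(inherits(mapping, "atom_mapping"))
  structure(list(reactive_atom_rule = reactive_atom_rule, mapping = mapping,
                 n_rotamers = as.integer(n_rotamers),
                 n_attack_points = as.integer(n_attack_points),
                 max_bond_modifications = as.integer(max_bond_modifications),
                 allow_unimolecular = allow_unimolecular,
                 allow_dissociation = allow_dissociation),
            class = "trial_constraints")
}

#' Reactive atoms of a molecule under the active constraints
#'
#' Default rule: all non-hydrogen atoms. With an atom mapping: only atoms
#' whose map index participates in a *formed* bond — the atoms that actually
#' build the new connection; atoms that merely lose bonds (leaving groups)
#' are not attack sites for a bond-formation trial.
#'
#' @param x A [molgraph] or `qc_structure`.
#' @param constraints A [trial_constraints()].
#' @return Integer vector of (heavy-graph) atom indices.
#' @export
reactive_atoms <- function(x, constraints = trial_constraints()) {
  g <- if (inherits(x, "qc_structure")) x$heavy_graph else x
  stopifnot(inherits(g, "molgraph"))
  idx <- if (constraints$reactive_atom_rule == "heavy") {
    which(g$atoms$element != "H")
  } else {
    seq_len(nrow(g$atoms))
  }
  m <- constraints$mapping
  if (!is.null(m)) {
    if (all(is.na(g$atoms$map_index))) {
      stop("mapping constraint given but the molecule carries no atom-map indices")
    }
    forming <- unique(as.integer(m$formed_bonds))
    present <- g$atoms$map_index[!is.na(g$atoms$map_index)]
    if (length(intersect(m$changed_atoms, present)) == 0L &&
        length(intersect(forming, present)) == 0L) {
      stop("mapping references map indices absent from this molecule")
    }
    idx <- idx[g$atoms$map_index[idx] %in% forming]
  }
  idx
}

#' Enumerate constrained bimolecular trials
#'
#' Cross product of the reactive atoms of `a` and `b` with every rotamer and
#' attack point, in lexicographic order `(atom_a, atom_b, rotamer, attack)`
#' so trial logs are reproducible and diffable. With a mapping constraint,
#' only atom pairs that are formed cross-bonds survive. An empty reactive set
#' on either side yields an empty trial list (not an error).
#'
#' @param a,b `qc_structure` objects (homo-coupling is allowed: `b` may
#'   reference the same compound as `a`).
#' @param constraints A [trial_constraints()].
#' @return A data frame of class `trial_set` with columns `atom_a`, `atom_b`,
#'   `rotamer`, `attack`; the structures ride along as attributes
#'   `structure_a` / `structure_b`.
#' @export
generate_trials <- function(a, b, constraints = trial_constraints()) {
  stopifnot(inherits(a, "qc_structure"), inherits(b, "qc_structure"))
  ra <- reactive_atoms(a, constraints)
  rb <- reactive_atoms(b, constraints)
  pairs <- expand.grid(atom_a = ra, atom_b = rb, KEEP.OUT.ATTRS = FALSE)
  m <- constraints$mapping
  if (!is.null(m) && nrow(pairs) > 0) {
    fb <- m$formed_bonds
    fkey <- c(paste(fb[, 1], fb[, 2]), paste(fb[, 2], fb[, 1]))
    ma <- a$heavy_graph$atoms$map_index[pairs$atom_a]
    mb <- b$heavy_graph$atoms$map_index[pairs$atom_b]
    pairs <- pairs[paste(ma, mb) %in% fkey, , drop = FALSE]
  }
  grid <- expand.grid(attack = seq_len(constraints$n_attack_points) - 1L,
                      rotamer = seq_len(constraints$n_rotamers) - 1L,
                      row = seq_len(nrow(pairs)), KEEP.OUT.ATTRS = FALSE)
  trials <- data.frame(atom_a = pairs$atom_a[grid$row],
                       atom_b = pairs$atom_b[grid$row],
                       rotamer = grid$rotamer, attack = grid$attack)
  trials <- trials[order(trials$atom_a, trials$atom_b, trials$rotamer,
                         trials$attack), , drop = FALSE]
  rownames(trials) <- NULL
  attr(trials, "structure_a") <- a
  attr(trials, "structure_b") <- b
  class(trials) <- c("trial_set", "data.frame")
  trials
}

#' Closed-form trial count
#'
#' `nA * nB * n_rotamers * n_attack_points`: the bimolecular trial space is
#' quadratic in system size, so doubling both reactant sizes quadruples the
#' count.
#'
#' @param n_a,n_b Reactive-atom counts of the two molecules (non-negative).
#' @param constraints A [trial_constraints()].
#' @return Integer trial count.
#' @examples
#' count_trials(3, 7)  # 84 with the default 2 rotamers x 2 attack points
#' @export
count_trials <- function(n_a, n_b, constraints = trial_constraints()) {
  stopifnot(n_a >= 0, n_b >= 0)
  as.integer(n_a) * as.integer(n_b) * constraints$n_rotamers *
    constraints$n_attack_points
}
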