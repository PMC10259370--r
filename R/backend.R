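# Energy backends: the calculator contract used by the exploration loop.
#
# Two implementations ship here. The surrogate backend is a deterministic
# graph-level bond-increment model plus an explicit rule table for
# elementary-step outcomes; it exists so the whole pipeline (trial
# enumeration, network aggregation, feasibility verdicts) runs and is
# testable without any electronic-structure program. The external backend is
# a subprocess adapter for a semiempirical program (e.g. an xtb-style
# tight-binding code): it writes an XYZ file plus charge/multiplicity flags,
# parses the total energy from standard output and converts Hartree to
# kJ/mol. Transition-state searching itself is delegated to the external
# program; the adapter only defines the contract.

#' Hartree to kJ/mol conversion factor
#'
#' @format Numeric scalar, 2625.499639 kJ/mol per Hartree.
#' @export
HARTREE_KJ_PER_MOL <- 2625.499639

#' Default bond-increment table of the surrogate backend
#'
#' Named vector of bond energies in kJ/mol keyed by sorted element pair
#' (`"C-H"`), with `":"` marking aromatic bonds (`"C:C"`). The values are a
#' self-consistent toy parameterization, not fitted to any real method; the
#' surrogate's job is determinism, not accuracy.
#'
#' @return Named numeric vector.
#' @export
default_bond_increments <- function() {
  c("C-H" = -400, "C-C" = -350, "C-O" = -360, "O-H" = -460, "C-I" = -230,
    "C:C" = -500, "C=C" = -600, "C#C" = -800, "C=O" = -700, "C-N" = -300,
    "N-H" = -390, "N-O" = -200, "N=O" = -450, "C:N" = -470, "C-F" = -480,
    "C-Cl" = -330, "H-I" = -290, "Al-Cl" = -420, "H-H" = -430, "O-O" = -140)
}

.bond_key <- function(el_i, el_j, order) {
  els <- sort(c(el_i, el_j))
  sep <- if (order == 1.5) ":" else if (order == 2) "=" else if (order == 3) "#" else "-"
  paste0(els[1], sep, els[2])
}

#' Create the deterministic surrogate backend
#'
#' @param increments Bond-increment table (see [default_bond_increments()]).
#' @param rules List of step rules; each rule is a list with fields `key_a`,
#'   `atom_a`, `key_b`, `atom_b` (connectivity key and heavy-atom index of
#'   the two reactants; `NA` atom index matches any atom), optional `rotamer`
#'   and `attack` (`NA` matches any), `products` (character vector of product
#'   SMILES), `barrier` and `reaction_energy` in kJ/mol. The first matching
#'   rule (either orientation) decides the trial outcome; trials matching no
#'   rule yield `no_step`.
#' @param default_increment Energy for bond types absent from the table,
#'   kJ/mol.
#' @param embed_seed Seed used when embedding product structures, so results
#'   are reproducible.
#' @return An object of class `c("surrogate_backend", "energy_backend")`.
#' @export
surrogate_backend <- function(increments = default_bond_increments(),
                              rules = list(), default_increment = -300,
                              embed_seed = 1L) {
  # normalize keys to sorted element order so "O-H" and "H-O" are the same
  names(increments) <- vapply(names(increments), function(k) {
    sep <- regmatches(k, regexpr("[-=#:]", k))
    paste(sort(strsplit(k, "[-=#:]")[[1]]), collapse = sep)
  }, character(1))
  be <- structure(list(increments = increments, rules = rules,
                       default_increment = default_increment,
                       embed_seed = as.integer(embed_seed),
                       cache = new.env(parent = emptyenv())),
                  class = c("surrogate_backend", "energy_backend"))
  be
}

#' Single-point energy of a structure
#'
#' Generic calculator entry point. The surrogate backend sums bond increments
#' over the explicit-hydrogen graph, so its energy is a pure function of the
#' molecular graph: identical graphs always give identical energies.
#'
#' @param backend An energy backend.
#' @param s A `qc_structure`.
#' @return A `calc_result` list: `energy` (kJ/mol, `NA` when not converged),
#'   `converged` (logical), `wall_seconds` (informational), `diagnostic`.
#' @export
calc_energy <- function(backend, s) UseMethod("calc_energy")

#' @export
calc_energy.surrogate_backend <- function(backend, s) {
  stopifnot(inherits(s, "qc_structure"))
  g <- s$graph
  if (nrow(g$atoms) == 0L) stop("cannot evaluate the energy of an empty molecule")
  b <- g$bonds
  e <- 0
  for (k in seq_len(nrow(b))) {
    key <- .bond_key(g$atoms$element[b$i[k]], g$atoms$element[b$j[k]], b$order[k])
    inc <- backend$increments[key]
    e <- e + if (is.na(inc)) backend$default_increment else unname(inc)
  }
  list(energy = e, converged = TRUE, wall_seconds = 0, diagnostic = NULL)
}

# Memoized embedding of product SMILES inside a backend.
.backend_embed <- function(backend, smiles) {
  key <- paste0(smiles, "#", backend$embed_seed)
  if (!is.null(backend$cache[[key]])) return(backend$cache[[key]])
  s <- embed_3d(parse_smiles(smiles), seed = backend$embed_seed)
  backend$cache[[key]] <- s
  s
}

#' Run an elementary-step search for one trial
#'
#' The surrogate backend looks the trial up in its rule table: a match yields
#' `step_found` with an [elementary_step()] whose reactant energy comes from
#' the bond-increment model and whose transition-state and product energies
#' are offset by the rule's barrier and reaction energy; no match yields
#' `no_step`. The external backend delegates to the configured program and
#' reports `error` when it is unavailable.
#'
#' @param backend An energy backend.
#' @param trials A `trial_set` from [generate_trials()].
#' @param i Row index of the trial to run.
#' @return A `step_search_result` list: `outcome` (`"step_found"`,
#'   `"no_step"` or `"error"`), `step` (present iff found), `diagnostic`.
#' @export
search_step <- function(backend, trials, i) UseMethod("search_step")

#' @export
search_step.surrogate_backend <- function(backend, trials, i) {
  stopifnot(inherits(trials, "trial_set"), i >= 1L, i <= nrow(trials))
  a <- attr(trials, "structure_a")
  b <- attr(trials, "structure_b")
  tr <- trials[i, ]
  key_a <- structure_key(a)
  key_b <- structure_key(b)

  match_rule <- function(rule) {
    ok_fwd <- identical(rule$key_a, key_a) && identical(rule$key_b, key_b) &&
      (is.na(rule$atom_a) || rule$atom_a == tr$atom_a) &&
      (is.na(rule$atom_b) || rule$atom_b == tr$atom_b)
    ok_rev <- identical(rule$key_a, key_b) && identical(rule$key_b, key_a) &&
      (is.na(rule$atom_a) || rule$atom_a == tr$atom_b) &&
      (is.na(rule$atom_b) || rule$atom_b == tr$atom_a)
    ok_rot <- is.null(rule$rotamer) || is.na(rule$rotamer) ||
      rule$rotamer == tr$rotamer
    ok_att <- is.null(rule$attack) || is.na(rule$attack) ||
      rule$attack == tr$attack
    (ok_fwd || ok_rev) && ok_rot && ok_att
  }

  for (rule in backend$rules) {
    if (!match_rule(rule)) next
    e_react <- calc_energy(backend, a)$energy + calc_energy(backend, b)$energy
    products <- lapply(rule$products, function(sm) .backend_embed(backend, sm))
    step <- elementary_step(
      reactants = list(a, b), products = products,
      e_react = e_react,
      e_ts = e_react + rule$barrier,
      e_prod = e_react + rule$reaction_energy)
    return(list(outcome = "step_found", step = step, diagnostic = NULL))
  }
  list(outcome = "no_step", step = NULL, diagnostic = NULL)
}

#' Configure an external subprocess backend
#'
#' Adapter contract for an external semiempirical program: single-point
#' energies are requested by writing an XYZ file and invoking
#' `executable xyz --chrg <q> --uhf <2S>` plus `extra_args`; the total energy
#' in Hartree is scraped from standard output with `energy_pattern` and
#' converted with [HARTREE_KJ_PER_MOL]. Spin multiplicity and charge are
#' passed through verbatim. Per-calculation wall time is capped at
#' `timeout_s`.
#'
#' @param executable Program name or path (e.g. `"xtb"`).
#' @param method Method label passed through `extra_args` conventions.
#' @param extra_args Character vector of additional command-line flags.
#' @param energy_pattern Regex with one capture group extracting the total
#'   energy (Hartree) from program output.
#' @param timeout_s Per-calculation wall-clock limit in seconds (default 300).
#' @param workdir Scratch directory for adapter I/O.
#' @return An object of class `c("external_backend", "energy_backend")`.
#' @export
external_backend <- function(executable = "xtb", method = "gfn2",
                             extra_args = character(0),
                             energy_pattern = "TOTAL ENERGY\\s+(-?[0-9.]+)",
                             timeout_s = 300, workdir = tempdir()) {
  structure(list(executable = executable, method = method,
                 extra_args = extra_args, energy_pattern = energy_pattern,
                 timeout_s = timeout_s, workdir = workdir),
            class = c("external_backend", "energy_backend"))
}

#' Build the command line an external backend would run
#'
#' Exposed separately so launch options can be inspected and tested without
#' invoking the program.
#'
#' @param backend An [external_backend()].
#' @param xyz_path Path of the XYZ input file.
#' @param charge Total charge.
#' @param multiplicity Spin multiplicity (2S+1); passed as the number of
#'   unpaired electrons.
#' @return Character vector: the executable followed by its arguments.
#' @export
external_command <- function(backend, xyz_path, charge, multiplicity) {
  c(backend$executable, xyz_path,
    "--chrg", as.character(charge),
    "--uhf", as.character(multiplicity - 1L),
    backend$extra_args)
}

#' @export
calc_energy.external_backend <- function(backend, s) {
  stopifnot(inherits(s, "qc_structure"))
  if (nrow(s$graph$atoms) == 0L) stop("cannot evaluate the energy of an empty molecule")
  exe <- Sys.which(backend$executable)
  if (!nzchar(exe)) {
    return(list(energy = NA_real_, converged = FALSE, wall_seconds = 0,
                diagnostic = sprintf(
                  "external program '%s' not found on PATH; install it or point external_backend(executable=) at it",
                  backend$executable)))
  }
  xyz <- tempfile("qcfill-", tmpdir = backend$workdir, fileext = ".xyz")
  write_xyz(s, xyz)
  on.exit(unlink(xyz), add = TRUE)
  cmd <- external_command(backend, xyz, s$charge, s$multiplicity)
  t0 <- proc.time()["elapsed"]
  out <- suppressWarnings(tryCatch(
    system2(cmd[1], cmd[-1], stdout = TRUE, stderr = TRUE,
            timeout = backend$timeout_s),
    error = function(e) structure(character(0), status = 127L,
                                  diagnostic = conditionMessage(e))))
  wall <- unname(proc.time()["elapsed"] - t0)
  status <- attr(out, "status")
  hits <- regmatches(out, regexec(backend$energy_pattern, out))
  vals <- vapply(hits, function(h) if (length(h) >= 2) h[2] else NA_character_,
                 character(1))
  vals <- vals[!is.na(vals)]
  if ((!is.null(status) && status != 0) || length(vals) == 0) {
    return(list(energy = NA_real_, converged = FALSE, wall_seconds = wall,
                diagnostic = paste("backend run failed or produced no parsable energy;",
                                   "last output lines:",
                                   paste(utils::tail(out, 3), collapse = " / "))))
  }
  list(energy = as.numeric(vals[length(vals)]) * HARTREE_KJ_PER_MOL,
       converged = TRUE, wall_seconds = wall, diagnostic = NULL)
}

#' @export
search_step.external_backend <- function(backend, trials, i) {
  exe <- Sys.which(backend$executable)
  if (!nzchar(exe)) {
    return(list(outcome = "error", step = NULL,
                diagnostic = sprintf(
                  "external program '%s' not found on PATH; elementary-step searches need a working installation (configure external_backend(executable=))",
                  backend$executable)))
  }
  # A double-ended / induced-reaction-coordinate search is the external
  # program's job; adapters for specific programs implement it by driving the
  # forming bond recorded in the trial and verifying the program's own
  # convergence verdict. No bundled driver is provided here.
  list(outcome = "error", step = NULL,
       diagnostic = "no step-search driver configured for the external backend")
}
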