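# Reaction network store with compound-level aggregation: structures sharing
# a connectivity key form one compound, and elementary steps sharing the same
# (reactant compounds, product compounds) multiset pair form one reaction.
# The network is an environment-backed registry so registration mutates in
# place and returns identifiers, mirroring how exploration software streams
# results into a database.

#' Create an empty reaction network
#'
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function() {
  net <- new.env(parent = emptyenv())
  net$structures <- list()   # id -> qc_structure (plus $compound_id)
  net$compounds <- list()    # id -> list(id, key, members)
  net$key_index <- character(0)  # names: key, values: compound id
  net$steps <- list()        # id -> elementary step (plus $reaction_id)
  net$reactions <- list()    # id -> list(id, reactants, products, members, ...)
  net$rxn_index <- character(0)
  net$provenance <- list()   # step id -> trial descriptor
  net$counters <- c(structure = 0L, compound = 0L, step = 0L, reaction = 0L)
  class(net) <- "reaction_network"
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("<reaction_network> %d compounds, %d structures, %d steps, %d reactions (%d endothermic)\n",
              s$n_compounds, s$n_structures, s$n_steps, s$n_reactions,
              s$n_endothermic))
  invisible(x)
}

.id_prefix <- c(structure = "s", compound = "c", step = "e", reaction = "r")

.next_id <- function(net, what) {
  net$counters[what] <- net$counters[what] + 1L
  paste0(.id_prefix[[what]], net$counters[what])
}

#' Register a structure, aggregating by connectivity
#'
#' Idempotent on connectivity: structures with the same connectivity key land
#' in the same compound; registering a byte-identical structure twice does
#' not create a duplicate entry.
#'
#' @param net A [reaction_network()].
#' @param s A `qc_structure` or a [molgraph] (embedded on the fly with a
#'   fixed seed in the latter case).
#' @return The compound id (character), invisibly carrying the structure id
#'   as attribute `structure_id`.
#' @export
register_structure <- function(net, s) {
  stopifnot(inherits(net, "reaction_network"))
  if (inherits(s, "molgraph")) s <- embed_3d(s, seed = 1L)
  stopifnot(inherits(s, "qc_structure"))
  key <- structure_key(s)

  cid <- unname(net$key_index[key])
  if (is.na(cid) || is.null(cid)) {
    cid <- .next_id(net, "compound")
    net$compounds[[cid]] <- list(id = cid, key = key, members = character(0))
    net$key_index[key] <- cid
  }
  # structure-level dedup: identical coordinates within one compound
  for (sid in net$compounds[[cid]]$members) {
    if (isTRUE(all.equal(net$structures[[sid]]$coords, s$coords,
                         tolerance = 1e-12))) {
      out <- cid
      attr(out, "structure_id") <- sid
      return(invisible(out))
    }
  }
  sid <- .next_id(net, "structure")
  s$id <- sid
  s$compound_id <- cid
  net$structures[[sid]] <- s
  net$compounds[[cid]]$members <- c(net$compounds[[cid]]$members, sid)
  out <- cid
  attr(out, "structure_id") <- sid
  invisible(out)
}

#' Construct an elementary step
#'
#' A single-transition-state transformation between one or two reactant
#' structures and its products, with energies on a common reference in
#' kJ/mol. The transition-state energy may be absent for barrierless steps.
#'
#' @param reactants,products Lists of `qc_structure` objects (1 or 2
#'   reactants).
#' @param e_react,e_prod Total energies of the reactant and product
#'   super-systems, kJ/mol.
#' @param e_ts Transition-state energy, kJ/mol, or `NA` for barrierless.
#' @param tol Tolerance for the saddle-point inequalities, kJ/mol (default 1).
#' @return An object of class `elementary_step`.
#' @export
elementary_step <- function(reactants, products, e_react, e_prod, e_ts = NA_real_,
                            tol = 1) {
  stopifnot(is.list(reactants), length(reactants) %in% c(1L, 2L),
            is.list(products), length(products) >= 1L)
  step <- structure(list(reactants = reactants, products = products,
                         e_react = e_react, e_ts = e_ts, e_prod = e_prod,
                         tol = tol),
                    class = "elementary_step")
  validate_elementary_step(step)
  step
}

#' Validate elementary-step invariants
#'
#' The transition state must lie above both endpoints (within `tol`), and the
#' two sides must differ in connectivity.
#'
#' @param step An [elementary_step()].
#' @return `step` invisibly; errors name the violated inequality.
#' @export
validate_elementary_step <- function(step) {
  stopifnot(inherits(step, "elementary_step"))
  if (!is.na(step$e_ts)) {
    if (step$e_ts < step$e_react - step$tol) {
      stop(sprintf("elementary step invariant violated: E_TS (%.3f) < E_react (%.3f) - tol",
                   step$e_ts, step$e_react))
    }
    if (step$e_ts < step$e_prod - step$tol) {
      stop(sprintf("elementary step invariant violated: E_TS (%.3f) < E_prod (%.3f) - tol",
                   step$e_ts, step$e_prod))
    }
  }
  rkeys <- sort(vapply(step$reactants, structure_key, character(1)))
  pkeys <- sort(vapply(step$products, structure_key, character(1)))
  if (identical(rkeys, pkeys)) {
    stop("elementary step invariant violated: reactant and product connectivity must differ")
  }
  invisible(step)
}

#' Barrier and reaction energy of an elementary step
#'
#' The barrier is `E_TS - E_react` (0 for barrierless downhill steps, the
#' endothermicity for barrierless uphill steps); the reaction energy is
#' `E_prod - E_react`. Both in kJ/mol.
#'
#' @param step An [elementary_step()].
#' @return Named numeric vector with `barrier` and `energy`.
#' @export
step_energetics <- function(step) {
  barrier <- if (is.na(step$e_ts)) max(0, step$e_prod - step$e_react)
             else step$e_ts - step$e_react
  c(barrier = max(0, barrier), energy = step$e_prod - step$e_react)
}

#' Register an elementary step, aggregating into reactions
#'
#' Reactant and product structures are registered (idempotently) first. Steps
#' whose compound multiset pair matches an existing reaction merge into it;
#' the reaction's `best_barrier` and `reaction_energy` are running minima
#' over member steps, so registration order does not matter.
#'
#' @param net A [reaction_network()].
#' @param step An [elementary_step()].
#' @param trial Optional provenance descriptor (stored per step).
#' @return The reaction id, invisibly.
#' @export
register_step <- function(net, step, trial = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  validate_elementary_step(step)
  rres <- lapply(step$reactants, function(s) register_structure(net, s))
  pres <- lapply(step$products, function(s) register_structure(net, s))
  for (k in seq_along(rres)) {
    step$reactants[[k]]$id <- attr(rres[[k]], "structure_id")
  }
  for (k in seq_along(pres)) {
    step$products[[k]]$id <- attr(pres[[k]], "structure_id")
  }
  rcids <- sort(vapply(rres, as.character, character(1)))
  pcids <- sort(vapply(pres, as.character, character(1)))
  rxn_key <- paste(paste(rcids, collapse = "+"), paste(pcids, collapse = "+"),
                   sep = ">")
  rid <- unname(net$rxn_index[rxn_key])
  en <- step_energetics(step)
  if (is.na(rid) || is.null(rid)) {
    rid <- .next_id(net, "reaction")
    net$reactions[[rid]] <- list(id = rid, key = rxn_key,
                                 reactants = rcids, products = pcids,
                                 members = character(0),
                                 best_barrier = Inf, reaction_energy = Inf)
    net$rxn_index[rxn_key] <- rid
  }
  sid <- .next_id(net, "step")
  step$id <- sid
  step$reaction_id <- rid
  net$steps[[sid]] <- step
  rx <- net$reactions[[rid]]
  rx$members <- c(rx$members, sid)
  rx$best_barrier <- min(rx$best_barrier, en["barrier"])
  rx$reaction_energy <- min(rx$reaction_energy, en["energy"])
  net$reactions[[rid]] <- rx
  if (!is.null(trial)) net$provenance[[sid]] <- trial
  invisible(rid)
}

#' Summary counts of a reaction network
#'
#' @param net A [reaction_network()].
#' @param endo_tol Reactions with `reaction_energy > endo_tol` (kJ/mol) count
#'   as endothermic (default 0).
#' @return A list with `n_compounds`, `n_structures`, `n_steps`,
#'   `n_reactions`, `n_endothermic`.
#' @export
network_summary <- function(net, endo_tol = 0) {
  stopifnot(inherits(net, "reaction_network"))
  energies <- vapply(net$reactions, function(r) r$reaction_energy, numeric(1))
  list(n_compounds = length(net$compounds),
       n_structures = length(net$structures),
       n_steps = length(net$steps),
       n_reactions = length(net$reactions),
       n_endothermic = sum(energies > endo_tol))
}

#' Reactions of a network as a data frame
#'
#' @param net A [reaction_network()].
#' @return Data frame with one row per reaction: id, reactant/product
#'   compound ids (collapsed with `+`), number of member steps,
#'   `best_barrier` and `reaction_energy` in kJ/mol.
#' @export
network_reactions <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  if (length(net$reactions) == 0L) {
    return(data.frame(id = character(0), reactants = character(0),
                      products = character(0), n_steps = integer(0),
                      best_barrier = numeric(0), reaction_energy = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(net$reactions, function(r) {
    data.frame(id = r$id, reactants = paste(r$reactants, collapse = "+"),
               products = paste(r$products, collapse = "+"),
               n_steps = length(r$members),
               best_barrier = unname(r$best_barrier),
               reaction_energy = unname(r$reaction_energy),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Serialize a reaction network to JSON
#'
#' Schema `qcfill-net/1`. Energies and coordinates are written at full double
#' precision so a round trip preserves them.
#'
#' @param net A [reaction_network()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to file).
#' @export
network_to_json <- function(net, path = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  ser_structure <- function(s) {
    list(id = s$id, compound_id = s$compound_id,
         elements = s$graph$atoms$element,
         coords = unname(s$coords), charge = s$charge,
         multiplicity = s$multiplicity,
         smiles = if (is.null(s$heavy_graph$smiles)) NA else s$heavy_graph$smiles)
  }
  ser_step <- function(st) {
    list(id = st$id, reaction_id = st$reaction_id,
         reactants = vapply(st$reactants, function(s) s$id %||% NA_character_, character(1)),
         products = vapply(st$products, function(s) s$id %||% NA_character_, character(1)),
         e_react = st$e_react, e_ts = st$e_ts, e_prod = st$e_prod)
  }
  doc <- list(
    schema = "qcfill-net/1",
    compounds = lapply(net$compounds, function(cp)
      list(id = cp$id, key = cp$key, members = cp$members)),
    structures = lapply(net$structures, ser_structure),
    steps = lapply(net$steps, ser_step),
    reactions = lapply(net$reactions, function(r)
      list(id = r$id, key = r$key, reactants = r$reactants,
           products = r$products, members = r$members,
           best_barrier = unname(r$best_barrier),
           reaction_energy = unname(r$reaction_energy))),
    provenance = net$provenance
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                          na = "null")
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rebuild a reaction network from its JSON serialization
#'
#' Inverse of [network_to_json()]: ids, connectivity keys, membership and
#' energies are restored exactly; structures are re-instantiated from their
#' stored SMILES and coordinates.
#'
#' @param json A JSON string or path to a JSON file written by
#'   [network_to_json()].
#' @return A [reaction_network()].
#' @export
network_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(doc$schema, "qcfill-net/1")) {
    stop("unsupported network schema: ", doc$schema %||% "<missing>")
  }
  net <- reaction_network()
  for (cp in doc$compounds) {
    net$compounds[[cp$id]] <- list(id = cp$id, key = cp$key,
                                   members = as.character(unlist(cp$members)))
    net$key_index[cp$key] <- cp$id
  }
  for (st in doc$structures) {
    coords <- do.call(rbind, lapply(st$coords, function(r) unlist(r)))
    g <- parse_smiles(st$smiles)
    s <- qc_structure(g, coords, charge = st$charge,
                      multiplicity = st$multiplicity)
    s$id <- st$id
    s$compound_id <- st$compound_id
    net$structures[[st$id]] <- s
  }
  for (r in doc$reactions) {
    net$reactions[[r$id]] <- list(
      id = r$id, key = r$key,
      reactants = as.character(unlist(r$reactants)),
      products = as.character(unlist(r$products)),
      members = as.character(unlist(r$members)),
      best_barrier = as.numeric(r$best_barrier),
      reaction_energy = as.numeric(r$reaction_energy))
    net$rxn_index[r$key] <- r$id
  }
  for (st in doc$steps) {
    step <- structure(list(
      reactants = lapply(as.character(unlist(st$reactants)),
                         function(id) net$structures[[id]]),
      products = lapply(as.character(unlist(st$products)),
                        function(id) net$structures[[id]]),
      e_react = as.numeric(st$e_react),
      e_ts = as.numeric(st$e_ts %||% NA_real_),
      e_prod = as.numeric(st$e_prod), tol = 1,
      id = st$id, reaction_id = st$reaction_id), class = "elementary_step")
    net$steps[[st$id]] <- step
  }
  net$provenance <- doc$provenance %||% list()
  ids <- function(prefix, lst) {
    nums <- as.integer(sub(paste0("^", prefix), "", names(lst)))
    if (length(nums) == 0L) 0L else max(nums)
  }
  net$counters <- c(structure = ids("s", net$structures),
                    compound = ids("c", net$compounds),
                    step = ids("e", net$steps),
                    reaction = ids("r", net$reactions))
  net
}

#' Export the compound-reaction bipartite graph as an edge list
#'
#' One TSV row per (compound, reaction) incidence with a `side` column
#' (`reactant` or `product`).
#'
#' @param net A [reaction_network()].
#' @param path Optional TSV path.
#' @return The edge-list data frame (invisibly when written to file).
#' @export
network_edge_list <- function(net, path = NULL) {
  rows <- list()
  for (r in net$reactions) {
    for (cp in r$reactants) rows[[length(rows) + 1L]] <-
      data.frame(compound = cp, reaction = r$id, side = "reactant")
    for (cp in r$products) rows[[length(rows) + 1L]] <-
      data.frame(compound = cp, reaction = r$id, side = "product")
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(compound = character(0), reaction = character(0),
                        side = character(0))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
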