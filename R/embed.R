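# Deterministic 3D structure generation from molecular graphs.
#
# SMILES fixes connectivity but not coordinates; backends need Cartesian
# starting structures whose atoms do not overlap (clashing atoms make
# electronic-structure calculations fail outright). The embedder here builds
# a chemically reasonable *starting guess*: seeded random placement refined
# by a spring model (bonded pairs pulled to the sum of covalent radii,
# nonbonded pairs pushed apart), followed by a hard clash-repair pass that
# guarantees a minimum interatomic distance. Geometries are starting points
# for an energy backend, not equilibrium structures.

#' Construct a 3D structure
#'
#' @param graph A [molgraph]; hydrogens are made explicit.
#' @param coords Numeric n-by-3 matrix of Cartesian coordinates in Angstrom
#'   for the explicit-hydrogen graph.
#' @param charge Total charge (defaults to the graph's).
#' @param multiplicity Spin multiplicity 2S+1 (defaults to
#'   [guess_multiplicity()]).
#' @param d_min Minimum allowed interatomic distance in Angstrom.
#' @return An object of class `qc_structure` with fields `graph` (explicit-H
#'   [molgraph]), `heavy_graph` (the input graph), `coords`, `charge`,
#'   `multiplicity`.
#' @export
qc_structure <- function(graph, coords, charge = NULL, multiplicity = NULL,
                         d_min = 0.5) {
  gH <- molgraph_explicit_h(graph)
  stopifnot(is.matrix(coords), ncol(coords) == 3, nrow(coords) == nrow(gH$atoms))
  if (is.null(charge)) charge <- graph$total_charge
  if (is.null(multiplicity)) multiplicity <- guess_multiplicity(graph)
  s <- structure(list(graph = gH, heavy_graph = graph, coords = coords,
                      charge = as.integer(charge),
                      multiplicity = as.integer(multiplicity),
                      d_min = d_min,
                      conn_key = connectivity_key(graph)),
                 class = "qc_structure")
  validate_structure(s)
  s
}

# Cached connectivity key of a structure.
structure_key <- function(s) {
  if (!is.null(s$conn_key)) s$conn_key else connectivity_key(s$heavy_graph)
}

#' Validate structure invariants
#'
#' Minimum interatomic distance at least `d_min`, and multiplicity parity
#' consistent with the electron count (odd electron count requires an even
#' multiplicity and vice versa).
#'
#' @param s A `qc_structure`.
#' @return `s` invisibly; errors on violation.
#' @export
validate_structure <- function(s) {
  stopifnot(inherits(s, "qc_structure"))
  if (nrow(s$coords) > 1L) {
    dmin <- min(stats::dist(s$coords))
    if (dmin < s$d_min - 1e-9) {
      stop(sprintf("structure invariant violated: minimum interatomic distance %.3f < %.3f Angstrom",
                   dmin, s$d_min))
    }
  }
  ne <- electron_count(s$heavy_graph)
  if ((ne %% 2L == 0L) != (s$multiplicity %% 2L == 1L)) {
    stop(sprintf("structure invariant violated: %d electrons incompatible with multiplicity %d",
                 ne, s$multiplicity))
  }
  invisible(s)
}

#' @export
print.qc_structure <- function(x, ...) {
  cat(sprintf("<qc_structure> %d atoms (%d heavy), charge %+d, multiplicity %d\n",
              nrow(x$coords), n_heavy_atoms(x$heavy_graph), x$charge,
              x$multiplicity))
  invisible(x)
}

#' Embed a molecular graph in 3D
#'
#' Deterministic for a fixed seed: the same graph and seed always give
#' byte-identical coordinates. Hydrogens are made explicit and appended after
#' the heavy atoms, so heavy-atom indices are preserved.
#'
#' @param graph A [molgraph] with at least one atom.
#' @param seed Integer seed for the (package-local) random number stream.
#' @param d_min Minimum interatomic distance in Angstrom (default 0.5).
#' @param restarts Number of re-seeded attempts before giving up (default 5).
#' @param multiplicity Optional spin multiplicity override.
#' @return A `qc_structure`.
#' @export
embed_3d <- function(graph, seed = 1L, d_min = 0.5, restarts = 5L,
                     multiplicity = NULL) {
  stopifnot(inherits(graph, "molgraph"), nrow(graph$atoms) >= 1L)
  gH <- molgraph_explicit_h(graph)
  n <- nrow(gH$atoms)
  rcov <- covalent_radius(gH$atoms$element)

  if (n == 1L) {
    return(qc_structure(graph, matrix(0, 1, 3), multiplicity = multiplicity,
                        d_min = d_min))
  }

  b <- gH$bonds
  bond_pairs <- cbind(b$i, b$j)
  r0 <- rcov[b$i] + rcov[b$j]
  pairs <- t(utils::combn(n, 2))
  bonded_key <- paste(pmin(bond_pairs[, 1], bond_pairs[, 2]),
                      pmax(bond_pairs[, 1], bond_pairs[, 2]))
  nonb <- pairs[!(paste(pairs[, 1], pairs[, 2]) %in% bonded_key), , drop = FALSE]
  rmin <- 0.9 * (rcov[nonb[, 1]] + rcov[nonb[, 2]]) + 0.55

  objective <- function(x) {
    xm <- matrix(x, ncol = 3)
    dvec_b <- xm[bond_pairs[, 1], , drop = FALSE] - xm[bond_pairs[, 2], , drop = FALSE]
    db <- sqrt(rowSums(dvec_b^2))
    val <- sum((db - r0)^2)
    if (nrow(nonb) > 0) {
      dvec_n <- xm[nonb[, 1], , drop = FALSE] - xm[nonb[, 2], , drop = FALSE]
      dn <- sqrt(rowSums(dvec_n^2))
      pen <- pmax(0, rmin - dn)
      val <- val + sum(pen^2)
    }
    val
  }
  gradient <- function(x) {
    xm <- matrix(x, ncol = 3)
    g <- matrix(0, n, 3)
    dvec_b <- xm[bond_pairs[, 1], , drop = FALSE] - xm[bond_pairs[, 2], , drop = FALSE]
    db <- pmax(sqrt(rowSums(dvec_b^2)), 1e-9)
    coef <- 2 * (db - r0) / db
    for (k in seq_len(nrow(bond_pairs))) {
      gk <- coef[k] * dvec_b[k, ]
      g[bond_pairs[k, 1], ] <- g[bond_pairs[k, 1], ] + gk
      g[bond_pairs[k, 2], ] <- g[bond_pairs[k, 2], ] - gk
    }
    if (nrow(nonb) > 0) {
      dvec_n <- xm[nonb[, 1], , drop = FALSE] - xm[nonb[, 2], , drop = FALSE]
      dn <- pmax(sqrt(rowSums(dvec_n^2)), 1e-9)
      pen <- rmin - dn
      act <- which(pen > 0)
      for (k in act) {
        gk <- (-2 * pen[k] / dn[k]) * dvec_n[k, ]
        g[nonb[k, 1], ] <- g[nonb[k, 1], ] + gk
        g[nonb[k, 2], ] <- g[nonb[k, 2], ] - gk
      }
    }
    as.numeric(g)
  }

  box <- max(3, 1.5 * n^(1/3) * 2)
  for (attempt in seq_len(restarts)) {
    rng <- lcg_new(seed + 997L * (attempt - 1L))
    u <- lcg_runif(rng, 3L * n)$values
    x0 <- (u - 0.5) * box
    fit <- stats::optim(x0, objective, gradient, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10))
    coords <- matrix(fit$par, ncol = 3)
    coords <- repair_clashes(coords, d_min = d_min)
    if (min(stats::dist(coords)) >= d_min - 1e-9) {
      coords <- round(coords - matrix(colMeans(coords), n, 3, byrow = TRUE), 6)
      if (min(stats::dist(coords)) >= d_min - 1e-9) {
        return(qc_structure(graph, coords, multiplicity = multiplicity,
                            d_min = d_min))
      }
    }
  }
  stop(sprintf("sanitization error: embedding failed after %d restarts (atoms still within %.2f Angstrom)",
               restarts, d_min))
}

#' Repair atom clashes in a coordinate set
#'
#' Iteratively pushes any atom pair closer than `d_min` apart along their
#' connecting axis until the minimum interatomic distance is at least
#' `d_min`. Deterministic: coincident atoms are separated along a fixed
#' axis. This is the overlap sanitization step applied to every embedded
#' structure before it is handed to an energy backend.
#'
#' @param coords Numeric n-by-3 matrix.
#' @param d_min Minimum allowed distance in Angstrom (default 0.5).
#' @param max_iter Safety cap on repair sweeps.
#' @return The repaired coordinate matrix.
#' @export
repair_clashes <- function(coords, d_min = 0.5, max_iter = 500L) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  n <- nrow(coords)
  if (n < 2L) return(coords)
  for (it in seq_len(max_iter)) {
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    if (min(d) >= d_min) break
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    v <- coords[i, ] - coords[j, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) {
      v <- c(1, 0, 0) * (1 + (i %% 3)) / (1 + (i %% 3))  # fixed axis
      nv <- 1
    }
    shift <- (d_min - min(nv, d_min)) / 2 * 1.05 + 1e-6
    coords[i, ] <- coords[i, ] + v / nv * shift
    coords[j, ] <- coords[j, ] - v / nv * shift
  }
  coords
}
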