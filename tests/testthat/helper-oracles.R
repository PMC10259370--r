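# Shared test helpers: independent oracles and small builders.

# Numerical-quadrature oracle for the Maxwell-Boltzmann kinetic-energy
# survival probability: integrate the 3-degree-of-freedom density
# f(E) = 2 sqrt(E/pi) (RT)^(-3/2) exp(-E/RT) from E to infinity.
# Independent of the closed form used by the package.
mb_survival_quadrature <- function(E, config = feasibility_config()) {
  rt <- config$gas_constant * config$temperature
  vapply(E, function(e) {
    # truncate the infinite tail at e + 60 RT (relative truncation error
    # ~exp(-60)); a finite range keeps the quadrature accurate in relative
    # terms even when the survival probability is ~1e-40
    stats::integrate(function(x) 2 * sqrt(x / pi) * rt^(-1.5) * exp(-x / rt),
                     lower = e, upper = e + 60 * rt, rel.tol = 1e-12)$value
  }, numeric(1))
}

# Brute-force trial enumeration oracle: nested loops over reactive atom
# indices, rotamers and attack points.
brute_force_trials <- function(ra, rb, n_rot, n_att) {
  rows <- list()
  for (a in ra) for (b in rb) for (r in seq_len(n_rot) - 1L)
    for (t in seq_len(n_att) - 1L) {
      rows[[length(rows) + 1L]] <- c(a, b, r, t)
    }
  if (length(rows) == 0L) {
    return(matrix(integer(0), ncol = 4,
                  dimnames = list(NULL, c("atom_a", "atom_b", "rotamer", "attack"))))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("atom_a", "atom_b", "rotamer", "attack")
  m[order(m[, 1], m[, 2], m[, 3], m[, 4]), , drop = FALSE]
}

# Embedded linear-alkane structures by heavy-atom count, cached so repeated
# property tests do not re-run the embedder.
.alkane_cache <- new.env(parent = emptyenv())
alkane_structure <- function(n_heavy) {
  key <- as.character(n_heavy)
  if (is.null(.alkane_cache[[key]])) {
    .alkane_cache[[key]] <- embed_3d(parse_smiles(strrep("C", n_heavy)),
                                     seed = 100L + n_heavy)
  }
  .alkane_cache[[key]]
}

# The Williamson fixture is used across several test files; build it once.
.fixture_cache <- new.env(parent = emptyenv())
cached_williamson_report <- function() {
  if (is.null(.fixture_cache$williamson)) {
    fx <- williamson_fixture()
    .fixture_cache$williamson <-
      list(fixture = fx, report = validate_step(fx$step, fx$config))
  }
  .fixture_cache$williamson
}
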