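# Periodic-table lookups shared across the package.

.element_table <- local({
  sym <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
           "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
           "Ti", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge",
           "As", "Se", "Br", "Kr", "Pd", "Ag", "Cd", "Sn", "Sb", "Te",
           "I", "Xe", "Pt", "Au", "Hg", "Pb", "Bi")
  z <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L,
         11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L, 20L,
         22L, 24L, 25L, 26L, 27L, 28L, 29L, 30L, 31L, 32L,
         33L, 34L, 35L, 36L, 46L, 47L, 48L, 50L, 51L, 52L,
         53L, 54L, 78L, 79L, 80L, 82L, 83L)
  # Single-bond covalent radii in Angstrom (Cordero-style values).
  rcov <- c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
            1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
            1.60, 1.39, 1.39, 1.32, 1.26, 1.24, 1.32, 1.22, 1.22, 1.20,
            1.19, 1.20, 1.20, 1.16, 1.39, 1.45, 1.44, 1.39, 1.39, 1.38,
            1.39, 1.40, 1.36, 1.36, 1.32, 1.46, 1.48)
  data.frame(symbol = sym, z = z, rcov = rcov, stringsAsFactors = FALSE)
})

#' Atomic number of an element symbol
#'
#' @param symbol Character vector of element symbols (case-sensitive, e.g.
#'   `"Cl"`).
#' @return Integer vector of atomic numbers.
#' @keywords internal
atomic_number <- function(symbol) {
  idx <- match(symbol, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "))
  }
  .element_table$z[idx]
}

#' Covalent radius in Angstrom
#' @inheritParams atomic_number
#' @return Numeric vector of single-bond covalent radii.
#' @keywords internal
covalent_radius <- function(symbol) {
  idx <- match(symbol, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "))
  }
  .element_table$rcov[idx]
}

# Default valences for implicit-hydrogen assignment on organic-subset atoms.
# For elements with several common valences the smallest one that accommodates
# the explicit bond-order sum is used.
.default_valences <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

# Simple deterministic linear congruential generator. Used wherever the
# package needs seeded randomness without touching R's global RNG stream
# (3D embedding starts, synthetic fixtures).
lcg_new <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  list(state = state)
}

lcg_next <- function(rng) {
  # Park-Miller minimal standard generator.
  rng$state <- (16807 * rng$state) %% 2147483647
  rng
}

# n uniform deviates in [0, 1); returns list(values, rng).
lcg_runif <- function(rng, n) {
  out <- numeric(n)
  for (k in seq_len(n)) {
    rng <- lcg_next(rng)
    out[k] <- rng$state / 2147483647
  }
  list(values = out, rng = rng)
}
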