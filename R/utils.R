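# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, restores. All stochastic
#' operations in the package funnel through this so that a given seed is
#' bit-reproducible regardless of surrounding RNG use.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  force(expr)
}

# Approximate monoisotopic-free atomic masses for centre-of-mass work.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974)

#' Guess a particle mass from its atom/bead name
#'
#' PDB atom names start with the element for standard protein atoms ("CA",
#' "N", "O", "CB"...). Coarse-grained bead names ("BB", "SC1") do not map to
#' an element and get unit mass, matching the unit-mass convention for beads.
#' @noRd
guess_mass <- function(atom_name) {
  nm <- toupper(sub("[0-9']+", "", atom_name))
  first <- substr(nm, 1L, 1L)
  m <- .atomic_masses[first]
  m[is.na(m) | nm %in% c("BB", "SC")] <- 1
  # CG bead names like BB/SC* never start with a recognised element letter
  # except SCx (S = sulphur); treat any SC-prefixed bead as unit mass.
  m[startsWith(nm, "SC")] <- 1
  unname(m)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_interval <- function(x) {
  is.numeric(x) && length(x) == 2L && all(is.finite(x))
}

#' Residues covered by a 1-based half-open interval [start, end)
#' @noRd
interval_residues <- function(interval) {
  seq.int(interval[1L], interval[2L] - 1L)
}
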