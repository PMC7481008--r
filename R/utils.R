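# Physical constants and shared helpers.

# Boltzmann constant, J/K (SI, exact)
.kB <- 1.380649e-23
# Avogadro constant, 1/mol (exact)
.NA_const <- 6.02214076e23

#' Thermal energy in kJ/mol
#'
#' Converts an absolute temperature to the thermal energy scale used for
#' work values and free energies, \eqn{k_B T} in kJ/mol
#' (2.479 kJ/mol at 298 K).
#'
#' @param temperature Temperature in kelvin.
#' @return Thermal energy in kJ/mol.
#' @export
#' @examples
#' kT_kJ_per_mol(298)
kT_kJ_per_mol <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  .kB * .NA_const * temperature / 1000
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# input validation helper: scalar positive number
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "mdinfer_input_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "mdinfer_input_error")
  }
  invisible(as.integer(x))
}

# deterministic sub-stream seed derivation; keeps results invariant to the
# order in which sub-units (windows, trajectories) are generated
substream_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(index) * 7919L
}

# seed the RNG for the calling function only: the caller's stream is
# saved and restored when the frame exits, so generators never perturb
# user-level reproducibility
local_rng <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  withr::defer({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  invisible(seed)
}
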