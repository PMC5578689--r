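# internal helpers shared across modules

.kB_KCAL <- 0.0019872041 # Boltzmann constant, kcal/mol/K

#' Thermal energy kT at a given temperature
#'
#' @param temperature temperature in Kelvin (default 300 K, matching a
#'   standard simulation thermostat).
#' @return kT in kcal/mol (0.5961 kcal/mol at 300 K).
#' @export
kT_at <- function(temperature = 300) .kB_KCAL * temperature

# classed errors so callers can distinguish validation failures
abort_allokin <- function(message, class = "allokin_error") {
  stop(structure(
    class = c(class, "allokin_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# evaluate `code` under a temporary RNG state; restores the caller's stream
# so adding one generator call never perturbs another's output
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1)
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# symmetric PSD square root; rejects matrices with eigenvalues below -1e-10
# (relative to the spectral radius) with a named validation error
psd_sqrt <- function(sigma, tol = 1e-10) {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma)) {
    abort_allokin("covariance must be a square matrix",
                  "allokin_invalid_covariance")
  }
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    abort_allokin("covariance must be symmetric", "allokin_invalid_covariance")
  }
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  scale <- max(abs(e$values), 1)
  if (min(e$values) < -tol * scale) {
    abort_allokin(
      sprintf("covariance is not positive semi-definite (min eigenvalue %.3g)",
              min(e$values)),
      "allokin_invalid_covariance"
    )
  }
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# atomic masses in amu for the elements that occur in protein topologies
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, MN = 54.938,
  "NA" = 22.990, CL = 35.45, K = 39.098, CA = 40.078
)

mass_of_element <- function(element) {
  m <- .ATOMIC_MASS[toupper(element)]
  m[is.na(m)] <- 12.011 # unknown heavy atom: carbon-like placeholder
  unname(m)
}

# PDB atom names -> element guess (first alphabetic character; handles
# leading digits as in "1HB")
guess_element <- function(name) {
  vapply(name, function(x) {
    ch <- regmatches(x, regexpr("[A-Za-z]", x))
    if (length(ch) == 0) "C" else toupper(ch)
  }, character(1), USE.NAMES = FALSE)
}
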