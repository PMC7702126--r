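# Physical constants (CODATA 2018).
.MU0 <- 1.25663706212e-6        # vacuum permeability, N A^-2
.HBAR <- 1.054571817e-34        # reduced Planck constant, J s
.GAMMA_H <- 2.6752218744e8      # 1H gyromagnetic ratio, rad s^-1 T^-1
.GAMMA_C <- 6.728284e7          # 13C gyromagnetic ratio, rad s^-1 T^-1
.R_KCAL <- 1.987204259e-3       # gas constant, kcal mol^-1 K^-1

.err <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("rdcrank_", class), "rdcrank_error")))
}

# Evaluate expr under a local RNG state; seed = NULL leaves the RNG alone.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  withr::with_seed(as.integer(seed), eval.parent(substitute(expr)),
                   .rng_kind = "Mersenne-Twister")
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) .err("invalid_input", "cannot normalize a zero vector")
  v / n
}

#' Gyromagnetic ratios and physical constants used by the package
#'
#' @return named list with \code{gammaH}, \code{gammaC} (rad s^-1 T^-1),
#'   \code{mu0} (N A^-2) and \code{hbar} (J s), CODATA 2018 values.
#' @examples
#' physicalConstants()$gammaH
#' @export
physicalConstants <- function() {
  list(gammaH = .GAMMA_H, gammaC = .GAMMA_C, mu0 = .MU0, hbar = .HBAR)
}
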