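#' Haldane mapping function
#'
#' Converts a genetic distance into a recombination fraction under the Haldane
#' model (crossovers as a Poisson process along the genetic map, no
#' interference): \eqn{r = \frac{1}{2}\left(1 - e^{-2d}\right)} with \eqn{d}
#' in Morgans. Distances here are supplied in centiMorgans, the unit genetic
#' maps are published in.
#'
#' @param d_cm Genetic distance in centiMorgans (cM). Vectorised; all values
#'   must be non-negative.
#'
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @seealso [haldane_inverse()] for the inverse transform.
#' @examples
#' haldane_r(0)       # complete linkage
#' haldane_r(4.5093)  # ~0.0431
#' haldane_r(1e4)     # approaches free recombination, 0.5
#' @export
haldane_r <- function(d_cm) {
  if (!is.numeric(d_cm) || anyNA(d_cm)) {
    abort("`d_cm` must be numeric with no missing values.")
  }
  if (any(d_cm < 0)) {
    abort("`d_cm` must be non-negative: a genetic distance cannot be negative.")
  }
  0.5 * (1 - exp(-2 * d_cm / 100))
}

#' Inverse Haldane mapping function
#'
#' Recovers the genetic distance (cM) corresponding to a recombination
#' fraction: \eqn{d = -50 \ln(1 - 2r)}.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`. Vectorised.
#'
#' @return Genetic distance(s) in centiMorgans.
#' @examples
#' haldane_inverse(0.25)  # 50 * log(2)
#' haldane_inverse(haldane_r(12.5))
#' @export
haldane_inverse <- function(r) {
  if (!is.numeric(r) || anyNA(r)) {
    abort("`r` must be numeric with no missing values.")
  }
  if (any(r < 0) || any(r >= 0.5)) {
    abort("`r` must lie in [0, 0.5): 0.5 is the free-recombination asymptote.")
  }
  -50 * log(1 - 2 * r)
}
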