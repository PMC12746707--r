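#' Specify a two-locus segregation configuration
#'
#' Describes the observed inheritance pattern in a nuclear family: `n`
#' children, of whom a named subset `subset_c` (size `k`) is expected to carry
#' haplotype 1 of the transmitting parent at both loci A and B, while the
#' complement carries haplotype 2. The genetic distance `d` between the loci
#' can be given directly or derived from two genetic positions
#' (`d = |cM_b - cM_a|`), which in turn may come from
#' [locus_cm_position()].
#'
#' @param n_children Number of children (meioses from the transmitting
#'   parent), an integer >= 1.
#' @param cm_a,cm_b Genetic positions (cM) of loci A and B. Alternatively give
#'   `d_cm` directly.
#' @param d_cm Genetic distance between the loci in cM; overridden by
#'   `cm_a`/`cm_b` when both are supplied.
#' @param subset_c Optional character vector naming the children expected to
#'   carry haplotype 1; must be a subset of `children`. The pattern
#'   probability depends only on `n_children`, not on which children are in
#'   the subset, but the labels document the tested configuration.
#' @param children Optional character vector of all child identifiers
#'   (defaults to `"child_1"..."child_n"`).
#' @param transmitting_parent Optional identifier of the phase-informative
#'   parent.
#'
#' @return A list of class `segregation_config`.
#' @examples
#' segregation_config(4, cm_a = 196.1223, cm_b = 200.6316,
#'                    subset_c = c("child_4", "child_6"),
#'                    children = paste0("child_", 3:6))
#' @export
segregation_config <- function(n_children, cm_a = NULL, cm_b = NULL,
                               d_cm = NULL, subset_c = NULL, children = NULL,
                               transmitting_parent = NULL) {
  if (!is.numeric(n_children) || length(n_children) != 1 ||
      n_children < 1 || n_children != floor(n_children)) {
    abort("`n_children` must be a single integer >= 1 (no meioses, no pattern).")
  }
  n_children <- as.integer(n_children)
  if (!is.null(cm_a) && !is.null(cm_b)) {
    d_cm <- abs(cm_b - cm_a)
  }
  if (is.null(d_cm)) {
    abort("Supply either `d_cm` or both `cm_a` and `cm_b`.")
  }
  if (!is.finite(d_cm) || d_cm < 0) {
    abort("`d_cm` must be a finite non-negative genetic distance.")
  }
  children <- children %||% paste0("child_", seq_len(n_children))
  if (length(children) != n_children) {
    abort("`children` must have length `n_children`.")
  }
  subset_c <- subset_c %||% character(0)
  if (!all(subset_c %in% children)) {
    abort("`subset_c` must be a subset of `children`.")
  }
  structure(
    list(
      n_children = n_children, d_cm = as.numeric(d_cm),
      cm_a = cm_a, cm_b = cm_b,
      children = children, subset_c = subset_c,
      transmitting_parent = transmitting_parent
    ),
    class = "segregation_config"
  )
}

#' Per-child probability of receiving a specific haplotype without
#' recombination
#'
#' In one meiosis the transmitting parent passes either of its two haplotypes
#' with equal probability; the child carries a *specific* haplotype intact at
#' both loci with probability \eqn{(1 - r)/2}. The expression is symmetric in
#' the two haplotypes, so it applies to children expected to carry haplotype 1
#' and to those expected to carry haplotype 2 alike.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Probability in `(0.25, 0.5]`.
#' @examples
#' per_child_no_recomb_prob(0)        # 0.5, a fair coin on the two haplotypes
#' per_child_no_recomb_prob(0.0431)
#' @export
per_child_no_recomb_prob <- function(r) {
  if (!is.numeric(r) || anyNA(r) || any(r < 0) || any(r >= 0.5)) {
    abort("`r` must be a recombination fraction in [0, 0.5).")
  }
  (1 - r) / 2
}

#' Exact probability of a two-locus segregation pattern
#'
#' Probability, under Mendelian segregation with recombination, that all `n`
#' children of a nuclear family show the specified two-locus haplotype
#' configuration: each child in the subset C inherits haplotype 1 of the
#' transmitting parent at both loci and each remaining child inherits
#' haplotype 2. With recombination fraction `r` from the Haldane function,
#' each meiosis independently matches its assigned haplotype with probability
#' `(1 - r)/2`, so the pattern probability is \eqn{((1-r)/2)^n} — independent
#' of how many children fall in C.
#'
#' @param config A [segregation_config()].
#' @param phase_agnostic If `TRUE`, report the probability of the bipartition
#'   regardless of which haplotype is assigned to C (twice the labeled
#'   probability). The default `FALSE` scores the specific labeled
#'   configuration.
#'
#' @return A one-row tibble of class `pattern_prob` with columns `d_cm`, `r`,
#'   `per_child_prob`, `total_prob`, `total_pct` (percent, rounded half-up to
#'   2 decimals), `n_children`, `k`.
#' @examples
#' cfg <- segregation_config(4, cm_a = 196.1223, cm_b = 200.6316)
#' pattern_probability(cfg)
#' @export
pattern_probability <- function(config, phase_agnostic = FALSE) {
  if (!inherits(config, "segregation_config")) {
    abort("`config` must be created with segregation_config().")
  }
  r <- haldane_r(config$d_cm)
  pc <- per_child_no_recomb_prob(r)
  p <- pc^config$n_children
  if (phase_agnostic) p <- 2 * p
  out <- tibble(
    d_cm = config$d_cm, r = r, per_child_prob = pc,
    total_prob = p, total_pct = round_half_up(100 * p, 2),
    n_children = config$n_children, k = length(config$subset_c)
  )
  class(out) <- c("pattern_prob", class(out))
  out
}

#' @method tidy pattern_prob
#' @export
tidy.pattern_prob <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pattern_prob")
  out
}

#' @method glance pattern_prob
#' @export
glance.pattern_prob <- function(x, ...) {
  tibble(
    n_children = x$n_children, d_cm = x$d_cm,
    total_prob = x$total_prob, total_pct = x$total_pct
  )
}

#' Monte-Carlo meiosis oracle for the pattern probability
#'
#' Simulates families directly from the meiotic model instead of using the
#' closed form: each child draws its transmitted haplotype at locus A
#' uniformly from \{1, 2\} and a crossover between A and B occurs with
#' probability `r` (Bernoulli, no interference), flipping the haplotype at
#' locus B. The estimate is the fraction of simulated families in which every
#' child matches its assigned haplotype at both loci, with a binomial
#' standard error.
#'
#' @param config A [segregation_config()].
#' @param n_sim Number of simulated families (>= 1).
#' @param seed Integer seed; fully determines the output.
#'
#' @return A one-row tibble with columns `estimate`, `se`, `n_sim`,
#'   `analytic` (the closed-form value for reference), `z` (standardised
#'   difference).
#' @examples
#' cfg <- segregation_config(4, d_cm = 0)
#' simulate_meioses(cfg, n_sim = 10000, seed = 1)
#' @export
simulate_meioses <- function(config, n_sim, seed) {
  if (!inherits(config, "segregation_config")) {
    abort("`config` must be created with segregation_config().")
  }
  if (!is.numeric(n_sim) || length(n_sim) != 1 || n_sim < 1) {
    abort("`n_sim` must be a single integer >= 1.")
  }
  if (missing(seed) || is.null(seed)) abort("`seed` must be supplied.")
  n_sim <- as.integer(n_sim)
  set.seed(seed)
  n <- config$n_children
  r <- haldane_r(config$d_cm)
  # expected haplotype per child: 1 for members of C, 2 otherwise
  expected <- ifelse(config$children %in% config$subset_c, 1L, 2L)
  hap_a <- matrix(sample(c(1L, 2L), n_sim * n, replace = TRUE), n_sim, n)
  flip <- matrix(runif(n_sim * n) < r, n_sim, n)
  hap_b <- ifelse(flip, 3L - hap_a, hap_a)
  ok <- hap_a == matrix(expected, n_sim, n, byrow = TRUE) & hap_b == hap_a
  hits <- rowSums(ok) == n
  est <- mean(hits)
  se <- sqrt(est * (1 - est) / n_sim)
  analytic <- per_child_no_recomb_prob(r)^n
  tibble(
    estimate = est, se = se, n_sim = n_sim, analytic = analytic,
    z = if (se > 0) (est - analytic) / se else 0
  )
}
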