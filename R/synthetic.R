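#' Specification for a synthetic combinatorial landscape
#'
#' Defines a complete `alphabet_size^k` landscape whose fitness decomposes
#' into per-site additive effects plus higher-order epistatic interaction
#' effects, with optional Gaussian measurement noise. It emulates the
#' structure of combinatorially complete protein datasets (a handful of
#' mutated active-site residues, substantial pairwise epistasis) so that
#' campaigns and metrics are testable without external downloads.
#'
#' Defaults mirror a four-residue site-saturation library over the 20 amino
#' acids with half of the fitness variance carried by pairwise interactions
#' and no measurement noise.
#'
#' @param k number of mutated sites.
#' @param alphabet_size symbols per site (<= 20; the first `alphabet_size`
#'   canonical amino acids are used).
#' @param interaction_order highest order of epistatic terms; 1 = purely
#'   additive.
#' @param epistasis_weight fraction of fitness variance contributed by
#'   interaction terms, in \[0, 1\].
#' @param noise_sd standard deviation of additive Gaussian measurement
#'   noise, on the scale of the unit-variance latent fitness.
#' @param seed integer seed; identical specs generate byte-identical
#'   landscapes.
#' @return An object of class `alde_synthetic_spec`.
#' @export
synthetic_spec <- function(k = 4, alphabet_size = 20, interaction_order = 2,
                           epistasis_weight = 0.5, noise_sd = 0, seed = 1) {
  stopifnot(k >= 1, alphabet_size >= 2, alphabet_size <= 20,
            interaction_order >= 1, interaction_order <= k,
            epistasis_weight >= 0, epistasis_weight <= 1, noise_sd >= 0)
  structure(list(k = k, alphabet_size = alphabet_size,
                 interaction_order = interaction_order,
                 epistasis_weight = epistasis_weight,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "alde_synthetic_spec")
}

#' Generate a complete synthetic landscape
#'
#' Per-site effects and interaction effects are drawn from standard normal
#' distributions. The additive and epistatic components are each
#' standardized to unit variance over the full design space and combined as
#' `sqrt(1 - w) * additive + sqrt(w) * epistatic`, so that `w =
#' epistasis_weight` is exactly the fraction of (noise-free) fitness
#' variance carried by interactions. Gaussian noise of sd `noise_sd` is then
#' added and the result is shifted and scaled to \[0, 1\].
#'
#' @param spec an [synthetic_spec()] object.
#' @param max_size capacity guard forwarded to [enumerate_design_space()].
#' @return A complete [landscape()] over `alphabet_size^k` variants;
#'   `metadata$generator` records the spec.
#' @export
generate_synthetic_landscape <- function(spec, max_size = 2e6) {
  stopifnot(inherits(spec, "alde_synthetic_spec"))
  alphabet <- AA20[seq_len(spec$alphabet_size)]
  combos <- enumerate_design_space(spec$k, alphabet, max_size = max_size)
  n <- length(combos)
  a <- spec$alphabet_size
  # n x k matrix of 1-based alphabet indices per site
  idx <- matrix(match(unlist(strsplit(combos, ""), use.names = FALSE),
                      alphabet),
                nrow = n, ncol = spec$k, byrow = TRUE)
  with_seed(spec$seed, {
    site_eff <- matrix(stats::rnorm(spec$k * a), nrow = spec$k)
    additive <- numeric(n)
    for (s in seq_len(spec$k)) additive <- additive + site_eff[s, idx[, s]]

    epistatic <- numeric(n)
    if (spec$interaction_order >= 2) {
      for (m in 2:spec$interaction_order) {
        subsets <- utils::combn(spec$k, m, simplify = FALSE)
        for (ss in subsets) {
          eff <- stats::rnorm(a^m)
          # linear index of the m-site sub-combination into eff
          lin <- idx[, ss[1]] - 1L
          for (j in seq_along(ss)[-1]) lin <- lin * a + (idx[, ss[j]] - 1L)
          epistatic <- epistatic + eff[lin + 1L]
        }
      }
    }
    std <- function(x) {
      s <- stats::sd(x)
      if (s > 0) (x - mean(x)) / s else x * 0
    }
    w <- spec$epistasis_weight
    f <- sqrt(1 - w) * std(additive) + sqrt(w) * std(epistatic)
    if (spec$noise_sd > 0) f <- f + stats::rnorm(n, sd = spec$noise_sd)
    rng <- range(f)
    f <- if (rng[2] > rng[1]) (f - rng[1]) / (rng[2] - rng[1]) else rep(1, n)
    landscape(combos, f, alphabet = alphabet,
              metadata = list(generator = unclass(spec)))
  })
}
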