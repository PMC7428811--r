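#' Species definition
#'
#' @param name species label.
#' @param weight body mass in kg (> 0).
#' @param lifespan lifespan in years (> 0).
#' @return A `"species_spec"` list.
#' @examples
#' species_spec("mouse", weight = 0.02, lifespan = 2)
#' @export
species_spec <- function(name, weight, lifespan) {
  weight <- as.numeric(weight)
  lifespan <- as.numeric(lifespan)
  if (!is.finite(weight) || weight <= 0) stop("'weight' must be > 0")
  if (!is.finite(lifespan) || lifespan <= 0) stop("'lifespan' must be > 0")
  structure(list(name = as.character(name), weight = weight,
                 lifespan = lifespan),
            class = "species_spec")
}

#' Tissue stem-cell compartment definition
#'
#' Stem-cell count and division rate of a cancer type's at-risk compartment,
#' as measured in the reference species (human in the shipped configuration).
#'
#' @param name tissue / cancer-type label.
#' @param cells stem-cell count in the reference species (>= 1).
#' @param divisions_per_year stem-cell division rate in the reference
#'   species (> 0).
#' @return A `"tissue_spec"` list.
#' @examples
#' tissue_spec("colorectal", cells = 2e8, divisions_per_year = 73)
#' @export
tissue_spec <- function(name, cells, divisions_per_year) {
  cells <- as.numeric(cells)
  divisions_per_year <- as.numeric(divisions_per_year)
  if (!is.finite(cells) || cells < 1) stop("'cells' must be >= 1")
  if (!is.finite(divisions_per_year) || divisions_per_year <= 0)
    stop("'divisions_per_year' must be > 0")
  structure(list(name = as.character(name), cells = cells,
                 divisions_per_year = divisions_per_year),
            class = "tissue_spec")
}

#' Relative cellular metabolic rate
#'
#' Kleiber-type allometry: whole-body basal metabolic rate scales as roughly
#' `W^0.7`, so the per-unit-mass (cellular) rate scales as `R = W^-0.3`.
#'
#' @param W body mass in kg (> 0); vectorized.
#' @return Relative cellular metabolic rate `W^-0.3`.
#' @examples
#' cellular_metabolic_rate(1)
#' cellular_metabolic_rate(0.02) / cellular_metabolic_rate(60)  # ~11x
#' @export
cellular_metabolic_rate <- function(W) {
  if (any(!is.finite(W)) || any(W <= 0)) stop("'W' must be > 0")
  W^-0.3
}

#' Scale a tissue's stem-cell count to another body size
#'
#' Cell number in a tissue is assumed proportional to body mass, so
#' `C = C_ref * (W_species / W_reference)`.
#'
#' @param tissue a [tissue_spec()] measured in `reference`.
#' @param species target [species_spec()].
#' @param reference reference [species_spec()] (the one whose `cells` value
#'   was measured).
#' @return Scaled stem-cell count (may be non-integer).
#' @examples
#' mouse <- species_spec("mouse", 0.02, 2)
#' human <- species_spec("human", 60, 80)
#' colorectal <- tissue_spec("colorectal", 2e8, 73)
#' scale_cell_count(colorectal, mouse, human)  # ~6.67e4
#' @export
scale_cell_count <- function(tissue, species, reference) {
  stopifnot(inherits(tissue, "tissue_spec"),
            inherits(species, "species_spec"),
            inherits(reference, "species_spec"))
  tissue$cells * species$weight / reference$weight
}

#' Scale a tissue's division rate by metabolic-rate allometry
#'
#' Under the metabolic-rate (MR) hypothesis the somatic mutation accumulation
#' rate `u*k` scales with the cellular metabolic rate; the effect is carried
#' by the division rate `k` (the model only ever uses the product `u*k`):
#' `k = k_ref * (W_species / W_reference)^beta`, with `beta = 0` (no MR
#' effect), `-0.15` (intermediate) or `-0.3` (full cellular MR scaling).
#' Because tissue cell number is proportional to mass, scaling by the mass
#' ratio is equivalent to the `C^beta` form up to a constant absorbed in the
#' reference rate.
#'
#' @inheritParams scale_cell_count
#' @param beta MR scaling exponent (<= 0).
#' @return Scaled division rate (divisions/year).
#' @examples
#' mouse <- species_spec("mouse", 0.02, 2)
#' human <- species_spec("human", 60, 80)
#' colorectal <- tissue_spec("colorectal", 2e8, 73)
#' scale_division_rate(colorectal, mouse, human, beta = -0.15)  # ~242.6
#' @export
scale_division_rate <- function(tissue, species, reference, beta = 0) {
  stopifnot(inherits(tissue, "tissue_spec"),
            inherits(species, "species_spec"),
            inherits(reference, "species_spec"))
  if (!is.finite(beta) || beta > 0) stop("'beta' must be <= 0")
  tissue$divisions_per_year * (species$weight / reference$weight)^beta
}

#' Intraspecific scaling exponent of cancer risk with body size
#'
#' Within a species, with lifespan held constant and metabolic-rate scaling
#' `u*k` proportional to `C^beta`, the small-risk form gives
#' `p` proportional to `C^(1 + beta*M)`. With the full MR exponent
#' `beta = -0.3`, risk increases with size for `M = 2` (exponent 0.4), is
#' nearly flat for `M = 3` (0.1), and declines for `M >= 4` (-0.2) — the
#' pattern against which the MR hypothesis is judged.
#'
#' @param M number of driver mutations (>= 1); vectorized.
#' @param beta MR scaling exponent (default -0.3).
#' @return Exponent of `C` in the risk-size relation, `1 + beta*M`.
#' @examples
#' intraspecific_risk_exponent(2:4)   # 0.4, 0.1, -0.2
#' @export
intraspecific_risk_exponent <- function(M, beta = -0.3) {
  if (any(!is.finite(M)) || any(M < 1)) stop("'M' must be >= 1")
  1 + beta * M
}

#' Scaling exponent implied by an observed rate ratio
#'
#' Given an observed ratio of somatic mutation rates between a small and a
#' large species, the equivalent allometric exponent is
#' `-log(rate_ratio) / log(W_large / W_small)`. A 3-fold mouse/human ratio
#' over 0.02 vs 60 kg gives -0.137, i.e. about -0.14.
#'
#' @param rate_ratio small-species rate divided by large-species rate (> 0).
#' @param W_small,W_large body masses in kg (> 0, distinct).
#' @return Implied scaling exponent.
#' @examples
#' implied_exponent(3, 0.02, 60)
#' @export
implied_exponent <- function(rate_ratio, W_small, W_large) {
  if (any(!is.finite(rate_ratio)) || any(rate_ratio <= 0))
    stop("'rate_ratio' must be > 0")
  if (any(W_small <= 0) || any(W_large <= 0)) stop("masses must be > 0")
  if (any(W_small == W_large)) stop("masses must be distinct")
  -log(rate_ratio) / log(W_large / W_small)
}

#' Lifespan implied by body size
#'
#' The interspecific lifespan/body-size relation `T = T' * C^0.3`. Composed
#' with the `u*k` scaling at `beta = -0.3`, the product `u*k*T` is
#' size-independent, so the small-risk lifetime risk grows linearly in `C`.
#'
#' @param T_prime lifespan scale constant (> 0).
#' @param C body size measured as cell count (>= 1); vectorized.
#' @param exponent lifespan scaling exponent (default 0.3).
#' @return Lifespan in years.
#' @examples
#' lifespan_from_size(1, c(1, 2)) # doubling size multiplies T by 2^0.3
#' @export
lifespan_from_size <- function(T_prime, C, exponent = 0.3) {
  if (!is.finite(T_prime) || T_prime <= 0) stop("'T_prime' must be > 0")
  if (any(C < 1)) stop("'C' must be >= 1")
  T_prime * C^exponent
}
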