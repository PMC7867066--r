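# Isotope cost planning for labeling media recipes.

GLUCOSE_MW_13C <- 186.11   # U-13C6 D-glucose, g/mol
GLUCOSE_MW_12C <- 180.16   # natural-abundance D-glucose, g/mol

#' Construct a labeling media recipe
#'
#' @param components data.frame with columns `name`, `grams` (per litre),
#'   `price` (per gram; currency-agnostic, EUR in the shipped examples),
#'   `tag` (one of `13C-glucose`, `12C-glucose`, `15N-ammonium`, `other`)
#'   and optionally `molar_mass` (g/mol; defaulted for the two glucoses).
#' @return data.frame of class `media_recipe`.
#' @export
media_recipe <- function(components) {
  need <- c("name", "grams", "price", "tag")
  miss <- setdiff(need, names(components))
  if (length(miss)) {
    abort_fracnmr(paste("recipe missing columns:", paste(miss, collapse = ", ")),
                  "fracnmr_bad_input")
  }
  ok_tags <- c("13C-glucose", "12C-glucose", "15N-ammonium", "other")
  if (!all(components$tag %in% ok_tags)) {
    abort_fracnmr(paste("recipe tags must be one of:",
                        paste(ok_tags, collapse = ", ")), "fracnmr_bad_input")
  }
  if (any(components$grams < 0) || any(components$price < 0)) {
    abort_fracnmr("grams and prices must be non-negative", "fracnmr_bad_input")
  }
  if (is.null(components$molar_mass)) {
    components$molar_mass <- rep(NA_real_, nrow(components))
  }
  def <- c("13C-glucose" = GLUCOSE_MW_13C, "12C-glucose" = GLUCOSE_MW_12C)
  idx <- is.na(components$molar_mass) & components$tag %in% names(def)
  components$molar_mass[idx] <- def[components$tag[idx]]
  structure(components, class = c("media_recipe", "data.frame"))
}

#' Example recipes for the fractional and uniform labeling schemes
#'
#' `frac20` and `uniform` use the costing amounts (0.4 / 2.0 g 13C-glucose
#' at 100 per gram plus 0.8 g 15NH4Cl at 25 per gram, per litre of M9);
#' `frac20_prep` is the as-prepared fractional medium (0.42 g/L labeled +
#' 1.6 g/L unlabeled glucose) used for effective-fraction calculations.
#'
#' @return named list of [media_recipe()] objects.
#' @export
example_recipes <- function() {
  list(
    frac20 = media_recipe(data.frame(
      name = c("U-13C6 glucose", "15NH4Cl"),
      grams = c(0.4, 0.8), price = c(100, 25),
      tag = c("13C-glucose", "15N-ammonium"))),
    uniform = media_recipe(data.frame(
      name = c("U-13C6 glucose", "15NH4Cl"),
      grams = c(2.0, 0.8), price = c(100, 25),
      tag = c("13C-glucose", "15N-ammonium"))),
    frac20_prep = media_recipe(data.frame(
      name = c("U-13C6 glucose", "glucose", "15NH4Cl"),
      grams = c(0.42, 1.6, 0.8), price = c(100, 0, 25),
      tag = c("13C-glucose", "12C-glucose", "15N-ammonium")))
  )
}

#' Cost per litre of a media recipe
#'
#' Sum of grams times price over all components (unlabeled components at
#' their stated price, default 0).
#'
#' @param recipe a [media_recipe()].
#' @return cost per litre.
#' @export
scheme_cost <- function(recipe) {
  if (nrow(recipe) == 0L) return(0)
  sum(recipe$grams * recipe$price)
}

#' Cost ratio between two recipes
#'
#' @param recipe_a,recipe_b recipes; returns cost(a) / cost(b).
#' @return ratio.
#' @export
cost_ratio <- function(recipe_a, recipe_b) {
  cb <- scheme_cost(recipe_b)
  if (cb <= 0) {
    abort_fracnmr("denominator recipe has zero cost", "fracnmr_bad_input")
  }
  scheme_cost(recipe_a) / cb
}

#' Effective 13C molar fraction of a media recipe
#'
#' Molar fraction of labeled glucose among all glucose, corrected for the
#' molar-mass difference between U-13C6 glucose (186.11 g/mol) and
#' natural-abundance glucose (180.16 g/mol).  With
#' `include_natural_abundance = TRUE`, returns instead the per-carbon 13C
#' probability: fraction * purity + (1 - fraction) * nat_abund.
#'
#' @param recipe a [media_recipe()] containing at least one glucose
#'   component.
#' @param include_natural_abundance see above (default FALSE).
#' @param nat_abund,purity used only with the flag (defaults 0.011, 0.99).
#' @return molar fraction in \[0, 1\].
#' @examples
#' effective_13c_fraction(example_recipes()$frac20_prep)  # ~0.203
#' @export
effective_13c_fraction <- function(recipe, include_natural_abundance = FALSE,
                                   nat_abund = 0.011, purity = 0.99) {
  lab <- recipe[recipe$tag == "13C-glucose", , drop = FALSE]
  unl <- recipe[recipe$tag == "12C-glucose", , drop = FALSE]
  if (nrow(lab) + nrow(unl) == 0L) {
    abort_fracnmr("recipe has no glucose component", "fracnmr_bad_input")
  }
  mol_lab <- sum(lab$grams / lab$molar_mass)
  mol_unl <- if (nrow(unl)) sum(unl$grams / unl$molar_mass) else 0
  frac <- mol_lab / (mol_lab + mol_unl)
  if (include_natural_abundance) {
    frac * purity + (1 - frac) * nat_abund
  } else {
    frac
  }
}
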