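#' Compound descriptors
#'
#' @param name compound name.
#' @param molecularWeight molecular weight in g/mol (> 0).
#' @return data.frame row with `name` and `molecular_weight`.
#' @export
#' @examples
#' compound("methylene blue", 374)
compound <- function(name, molecularWeight) {
  if (any(molecularWeight <= 0)) stop("molecular weight must be > 0")
  data.frame(name = as.character(name),
             molecular_weight = molecularWeight, stringsAsFactors = FALSE)
}

#' Relative diffusion coefficient from molecular weights
#'
#' Estimates how fast a reference (dye) compound diffuses relative to a drug
#' cocktail from molecular weights alone, via the Stokes-Einstein scaling
#' \eqn{D \propto MW^{-e}} (hydrodynamic radius grows roughly as the cube
#' root of mass, hence the default exponent 1/3). The cocktail coefficient
#' is the mean of its members' coefficients; the returned ratio is
#' \eqn{D_{reference} / D_{cocktail}}, so a value below 1 means the
#' reference diffuses slower and its visualized spread is a conservative
#' stand-in for the drug field.
#'
#' @param reference one-row data.frame from [compound()] (or any data.frame
#'   with a `molecular_weight` column).
#' @param cocktail data.frame of one or more compounds.
#' @param exponent positive scaling exponent (default 1/3).
#' @return list: `ratio` (D_reference / D_cocktail), `exponent`, and
#'   `convention` describing the direction of the ratio.
#' @export
#' @examples
#' relativeDiffusion(compound("methylene blue", 374),
#'                   compound("glutamatergic cocktail", 201))$ratio
relativeDiffusion <- function(reference, cocktail, exponent = 1/3) {
  stopifnot(nrow(reference) == 1L, nrow(cocktail) >= 1L, exponent > 0)
  if (any(c(reference$molecular_weight, cocktail$molecular_weight) <= 0))
    stop("molecular weight must be > 0")
  dRef <- reference$molecular_weight^(-exponent)
  dCock <- mean(cocktail$molecular_weight^(-exponent))
  list(ratio = dRef / dCock, exponent = exponent,
       convention = "D_reference / D_cocktail; < 1 means the reference diffuses slower")
}
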