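#' Molarity of a staining solution from its mass-per-volume percent
#'
#' Converts a mass/volume concentration (g per 100 mL) and a molecular
#' weight to millimolarity: `(mass_percent * 10 / mw) * 1000` mmol/L. A
#' 6.3 m/V% solution of a 1500 g/mol agent is 42 mmol/L; 3.5 m/V% at
#' 9473 g/mol is 3.69 mmol/L.
#'
#' @param mass_percent concentration in g per 100 mL (> 0).
#' @param mw molecular weight in g/mol (> 0).
#' @return Concentration in mmol/L.
#' @export
molarity_from_mass_percent <- function(mass_percent, mw) {
  if (any(mass_percent <= 0) || any(mw <= 0))
    stop("mass_percent and mw must be > 0", call. = FALSE)
  mass_percent * 10 / mw * 1000
}

#' Staining solution descriptor
#'
#' Bundles a staining agent's name, mass-per-volume concentration and
#' molecular weight with its derived molarity.
#'
#' @param name agent name.
#' @param mass_percent g per 100 mL.
#' @param mw molecular weight, g/mol.
#' @return A `staining_solution`: list with the inputs plus `mmol_per_L`.
#' @export
staining_solution <- function(name, mass_percent, mw) {
  structure(list(name = name, mass_percent = mass_percent, mw = mw,
                 mmol_per_L = molarity_from_mass_percent(mass_percent, mw)),
            class = "staining_solution")
}
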