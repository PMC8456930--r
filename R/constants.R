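#' Physical constants and reporting conventions
#'
#' @description
#' `oxd_gas_constant` is the molar gas constant in kcal mol^-1 K^-1
#' (1.98720425e-3), the unit system of docking binding energies.
#'
#' `oxd_default_temperature` is the default absolute temperature (303.15 K,
#' i.e. 30 degrees C, a typical whole-cell biotransformation temperature) used
#' whenever ddG is interconverted with an E-value and no temperature is given.
#' Every function performing that conversion exposes a `temperature` argument;
#' the default is never applied silently to stored results (result tables carry
#' their temperature as an attribute).
#'
#' `oxd_default_e_cap` is the conventional reporting cap for enantiomeric
#' ratios: chiral-phase analytics cannot distinguish E-values much above 200,
#' so values beyond the cap are displayed as the cap with a `capped` flag.
#' Capping is applied only at the reporting layer; raw values are always kept
#' alongside.
#'
#' @name oxd-constants
NULL

#' @rdname oxd-constants
#' @export
oxd_gas_constant <- 1.98720425e-3

#' @rdname oxd-constants
#' @export
oxd_default_temperature <- 303.15

#' @rdname oxd-constants
#' @export
oxd_default_e_cap <- 200

# descriptor names shared by CatalyticGeometry, pharmacophore queries and
# match reports
oxd_descriptors <- c(
  "fe_n_dist", "o_ser_dist", "o_his_dist", "his_o_ser_angle", "c_n_o_o_dihedral"
)
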