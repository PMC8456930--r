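#' ddG and predicted enantiopreference from paired binding energies
#'
#' For each enantiomer pair within one E/Z isomer the selectivity proxy is the
#' absolute binding-energy difference `ddg = |dG_R - dG_S|` (kcal/mol); the
#' predicted configuration is the enantiomer with the lower (more negative)
#' binding energy — the more tightly bound enantiomer is the one converted to
#' the nitrile — and `"none"` on an exact tie.
#'
#' @param pairs A data frame with columns `substrate_id`, `ez`, `delta_g_R`,
#'   `delta_g_S` (see [pair_enantiomers()]).
#'
#' @return The input tibble with columns `ddg` and `predicted_config` added.
#' @examples
#' delta_delta_g(data.frame(substrate_id = "3F", ez = "E",
#'                          delta_g_R = -7.68, delta_g_S = -9.66))
#' @export
delta_delta_g <- function(pairs) {
  pairs <- as_tibble(pairs)
  pairs %>%
    mutate(
      ddg = abs(.data$delta_g_R - .data$delta_g_S),
      predicted_config = case_when(
        .data$delta_g_R < .data$delta_g_S ~ "R",
        .data$delta_g_S < .data$delta_g_R ~ "S",
        TRUE ~ "none"
      )
    )
}

#' Interconvert ddG and the enantiomeric ratio E
#'
#' Transition-state theory relates the free-energy difference between the
#' diastereomeric enzyme-substrate complexes to the ratio of apparent rate
#' constants: `E = exp(ddg / (R T))` with the gas constant
#' R = 1.98720425e-3 kcal/(mol K).  `ddg_from_e()` is the exact inverse,
#' `R T log(E)`.  Neither function caps; capping is a reporting convention,
#' see [cap_e()].
#'
#' @param ddg Free-energy difference(s), kcal/mol, `>= 0`.
#' @param e Enantiomeric ratio(s), `>= 1`.
#' @param temperature Absolute temperature, K.
#'
#' @return A numeric vector: E-values (`>= 1`) or ddG values (kcal/mol).
#' @examples
#' e_from_ddg(1.98, temperature = 303.15)
#' ddg_from_e(9, temperature = 298.15)
#' @export
e_from_ddg <- function(ddg, temperature = oxd_default_temperature) {
  if (any(!is.finite(ddg)) || any(ddg < 0)) abort("`ddg` must be finite and >= 0.")
  if (temperature <= 0) abort("`temperature` must be positive (Kelvin).")
  exp(ddg / (oxd_gas_constant * temperature))
}

#' @rdname e_from_ddg
#' @export
ddg_from_e <- function(e, temperature = oxd_default_temperature) {
  if (any(!is.finite(e)) || any(e < 1)) abort("`e` must be finite and >= 1.")
  if (temperature <= 0) abort("`temperature` must be positive (Kelvin).")
  oxd_gas_constant * temperature * log(e)
}

#' Cap E-values for reporting
#'
#' Chiral analytics cannot resolve enantiomeric ratios far above 200, so
#' E-values beyond the cap are conventionally displayed as the cap ("> 200").
#'
#' @param e Numeric E-values.
#' @param cap Reporting cap (default 200); `Inf` disables capping.
#' @return A tibble with columns `e_capped` (`pmin(e, cap)`) and `capped`
#'   (`e > cap`).
#' @examples
#' cap_e(c(5, 374))
#' @export
cap_e <- function(e, cap = oxd_default_e_cap) {
  tibble(e_capped = pmin(e, cap), capped = e > cap)
}

#' E-value from conversion and product ee (irreversible kinetic resolution)
#'
#' For an irreversible, competitive, (pseudo-)first-order resolution of a
#' racemate the enantiomeric ratio follows from one (conversion, product-ee)
#' measurement via the Chen–Sih relation
#' `E = log(1 - c (1 + ee_p)) / log(1 - c (1 - ee_p))`.
#' `ee_from_conversion_e()` is the inverse: the unique product ee solving the
#' relation at a given conversion, found by bracketed root-finding (tolerance
#' 1e-10) on `[0, min(1, 1/c - 1))` — the upper end is the mass-balance
#' ceiling on the product ee.
#'
#' @param conversion Fraction(s) of total substrate consumed, in (0, 1).
#' @param ee_product Product enantiomeric excess(es), fraction in \[0, 1\].
#' @param e Enantiomeric ratio(s), `>= 1`.
#'
#' @return A numeric vector of E-values (`>= 1`; `Inf` when `ee_product = 1`
#'   with positive conversion) or of product-ee fractions.
#'
#' @examples
#' e_from_conversion_ee(0.50, 0.65)   # ~9
#' e_from_conversion_ee(0.34, 0.93)   # ~44
#' ee_from_conversion_e(0.45, 112)    # ~0.958
#' @export
e_from_conversion_ee <- function(conversion, ee_product) {
  n <- max(length(conversion), length(ee_product))
  c_ <- rep_len(conversion, n)
  ee <- rep_len(ee_product, n)
  if (any(!is.finite(c_)) || any(c_ <= 0) || any(c_ >= 1)) {
    abort("`conversion` must be in (0, 1).")
  }
  if (any(!is.finite(ee)) || any(ee < 0) || any(ee > 1)) {
    abort("`ee_product` must be in [0, 1].")
  }
  infeasible <- c_ * (1 + ee) >= 1 & ee < 1
  if (any(infeasible)) {
    abort(sprintf(
      "Infeasible (conversion, ee) pair(s): conversion * (1 + ee) >= 1, e.g. (%.3f, %.3f).",
      c_[infeasible][1], ee[infeasible][1]))
  }
  out <- ifelse(
    ee >= 1,
    Inf,
    log1p(-c_ * (1 + ee)) / log1p(-c_ * (1 - ee))
  )
  # ee = 0 gives exactly 1; guard rounding for tiny ee
  pmax(out, 1)
}

#' @rdname e_from_conversion_ee
#' @export
ee_from_conversion_e <- function(conversion, e) {
  n <- max(length(conversion), length(e))
  c_ <- rep_len(conversion, n)
  ev <- rep_len(e, n)
  if (any(!is.finite(c_)) || any(c_ <= 0) || any(c_ >= 1)) {
    abort("`conversion` must be in (0, 1).")
  }
  if (any(ev < 1)) abort("`e` must be >= 1.")
  map_dbl(seq_len(n), function(i) {
    if (ev[i] == 1) return(0)
    upper <- min(1, 1 / c_[i] - 1) - 1e-12
    f <- function(ee) {
      val <- log1p(-c_[i] * (1 + ee)) / log1p(-c_[i] * (1 - ee))
      if (!is.finite(val)) val <- .Machine$double.xmax
      val - ev[i]
    }
    if (f(upper) < 0) {
      abort(sprintf("No feasible product ee at conversion %.3f for E = %.3g.",
                    c_[i], ev[i]))
    }
    uniroot(f, c(0, upper), tol = 1e-10)$root
  })
}

#' Predict enantioselectivity from a docking score table
#'
#' Chains [pair_enantiomers()], [delta_delta_g()] and [e_from_ddg()]: per
#' `(substrate_id, ez)` pair it reports ddG, the predicted configuration, and
#' the predicted E-value raw, rounded and capped.
#'
#' @param records A docking record data frame (`substrate_id`, `ez`, `rs`,
#'   `delta_g`), see [read_docking_table()].
#' @param temperature Absolute temperature (K) of the TST conversion.
#' @param e_cap Reporting cap for E-values.
#'
#' @return A tibble of class `oxd_prediction` with columns `substrate_id`,
#'   `ez`, `delta_g_R`, `delta_g_S`, `ddg`, `predicted_config`, `e_raw`,
#'   `e_rounded`, `e_capped`, `capped`; attributes `temperature`, `e_cap`,
#'   `unpaired`.
#'
#' @examples
#' read_docking_table(oxdock_example("oxdre_docking_scores.tsv")) %>%
#'   predict_selectivity()
#' @export
predict_selectivity <- function(records,
                                temperature = oxd_default_temperature,
                                e_cap = oxd_default_e_cap) {
  pairs <- pair_enantiomers(records)
  unpaired <- attr(pairs, "unpaired")
  out <- pairs %>%
    delta_delta_g() %>%
    mutate(e_raw = e_from_ddg(.data$ddg, temperature),
           e_rounded = round(.data$e_raw))
  capped_tab <- cap_e(out$e_raw, e_cap)
  out$e_capped <- capped_tab$e_capped
  out$capped <- capped_tab$capped
  structure(out,
            temperature = temperature, e_cap = e_cap, unpaired = unpaired,
            class = c("oxd_prediction", class(out)))
}

#' Experimental E-values and ddG from resolution observations
#'
#' Per observation (one biotransformation stopped at a given conversion) the
#' experimental enantiomeric ratio is computed from (conversion, product ee)
#' with [e_from_conversion_ee()] and converted to an equivalent free-energy
#' difference at the stated temperature.  Rows violating the mass-balance
#' feasibility condition `conversion * (1 + ee) < 1` are flagged
#' (`feasible = FALSE`, values `NA`), not dropped and not fatal.
#'
#' @param observations A data frame with columns `substrate_id`, `ez`,
#'   `conversion`, `ee_product` (fractions), `preferred_config`; see
#'   [read_resolution_table()].
#' @inheritParams predict_selectivity
#'
#' @return A tibble of class `oxd_resolution_analysis`: the input plus
#'   `feasible`, `e_raw`, `e_rounded`, `e_capped`, `capped`, `ddg_exp`;
#'   attributes `temperature`, `e_cap`.
#'
#' @examples
#' read_resolution_table(oxdock_example("oxdre_wt_biotransformations.tsv")) %>%
#'   analyze_resolution()
#' @export
analyze_resolution <- function(observations,
                               temperature = oxd_default_temperature,
                               e_cap = oxd_default_e_cap) {
  obs <- as_tibble(observations)
  feasible <- obs$conversion > 0 & obs$conversion < 1 &
    obs$ee_product >= 0 & obs$ee_product <= 1 &
    (obs$conversion * (1 + obs$ee_product) < 1 | obs$ee_product >= 1)
  e_raw <- rep(NA_real_, nrow(obs))
  if (any(feasible)) {
    e_raw[feasible] <- e_from_conversion_ee(obs$conversion[feasible],
                                            obs$ee_product[feasible])
  }
  capped_tab <- cap_e(e_raw, e_cap)
  ddg_exp <- rep(NA_real_, length(e_raw))
  ok <- is.finite(e_raw)
  if (any(ok)) ddg_exp[ok] <- ddg_from_e(pmax(e_raw[ok], 1), temperature)
  out <- obs %>%
    mutate(
      feasible = feasible,
      e_raw = e_raw,
      e_rounded = round(e_raw),
      e_capped = capped_tab$e_capped,
      capped = capped_tab$capped %in% TRUE,
      ddg_exp = ddg_exp
    )
  structure(out, temperature = temperature, e_cap = e_cap,
            class = c("oxd_resolution_analysis", class(out)))
}

#' Compare predicted and experimental enantioselectivity
#'
#' Joins predictions (from docking, [predict_selectivity()]) with experimental
#' observations (from biotransformations, [analyze_resolution()]) on
#' `(substrate_id, ez)` and reports, per pair, whether the predicted
#' configuration matches the experimentally preferred one, side by side with
#' predicted and experimental E-values (raw and capped) and the experimental
#' ddG.  Keys present on only one side are reported with `matched = FALSE`,
#' never dropped silently.
#'
#' @param predictions An `oxd_prediction` (or compatible data frame with
#'   `substrate_id`, `ez`, `ddg`, `predicted_config`, `e_raw`).
#' @param observations A resolution observation data frame (fractions), or an
#'   `oxd_resolution_analysis`.
#' @inheritParams predict_selectivity
#'
#' @return A tibble of class `oxd_comparison`; `glance()` gives pair and
#'   concordance counts.
#'
#' @examples
#' preds <- read_docking_table(oxdock_example("oxdre_docking_scores.tsv")) %>%
#'   predict_selectivity()
#' obs <- read_resolution_table(oxdock_example("oxdre_wt_biotransformations.tsv"))
#' compare_predictions(preds, obs) %>% glance()
#' @export
compare_predictions <- function(predictions, observations,
                                temperature = NULL,
                                e_cap = oxd_default_e_cap) {
  temperature <- temperature %||% attr(predictions, "temperature") %||%
    oxd_default_temperature
  if (!inherits(observations, "oxd_resolution_analysis")) {
    observations <- analyze_resolution(observations, temperature, e_cap)
  }
  pred <- as_tibble(predictions) %>%
    select("substrate_id", "ez", "ddg", "predicted_config",
           e_pred_raw = "e_raw")
  obs <- as_tibble(observations) %>%
    select("substrate_id", "ez", "preferred_config", "conversion",
           "ee_product", e_exp_raw = "e_raw", "ddg_exp")
  joined <- full_join(pred, obs, by = c("substrate_id", "ez"))
  unmatched <- sum(is.na(joined$predicted_config) | is.na(joined$preferred_config))
  if (unmatched > 0) {
    warn(sprintf("%d (substrate, ez) key(s) present on one side only.", unmatched))
  }
  pred_cap <- cap_e(joined$e_pred_raw, e_cap)
  exp_cap <- cap_e(joined$e_exp_raw, e_cap)
  out <- joined %>%
    mutate(
      matched = !is.na(.data$predicted_config) & !is.na(.data$preferred_config),
      concordant = .data$matched & .data$predicted_config == .data$preferred_config,
      e_pred_capped = pred_cap$e_capped,
      e_pred_is_capped = pred_cap$capped %in% TRUE,
      e_exp_capped = exp_cap$e_capped,
      e_exp_is_capped = exp_cap$capped %in% TRUE
    )
  structure(out, temperature = temperature, e_cap = e_cap,
            class = c("oxd_comparison", class(out)))
}
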