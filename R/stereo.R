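#' Assign E/Z double-bond geometry to an aldoxime pose
#'
#' The C=N configuration is read off the torsion of the heavy substituent
#' around the oxime double bond: with `d = dihedral(SUBSTITUENT, C, N, O)`,
#' the pose is Z when `|d| < 90` degrees (substituent cis to the hydroxyl
#' oxygen) and E otherwise; exactly 90 degrees is assigned E as a
#' deterministic tie-break.  Reflection preserves `|d|`, so mirror images keep
#' their E/Z label.
#'
#' @param pose An `oxd_pose`.
#' @param map An `oxd_atom_map`; roles `LIG_SUBSTITUENT_HEAVY`, `LIG_C`,
#'   `LIG_N`, `LIG_O` must resolve.
#'
#' @return `"E"` or `"Z"`.
#' @examples
#' assign_ez(synthesize_pose(ez = "Z"), default_atom_map())
#' @export
assign_ez <- function(pose, map = default_atom_map()) {
  res <- resolve_atom_map(pose, map)
  pos <- function(role) {
    row <- res[res$role == role, ]
    c(row$x, row$y, row$z)
  }
  d <- vec_dihedral(pos("LIG_SUBSTITUENT_HEAVY"), pos("LIG_C"),
                    pos("LIG_N"), pos("LIG_O"))
  if (abs(d) < 90) "Z" else "E"
}

#' Assign the R/S label of the aldoxime stereocenter
#'
#' Uses the signed volume spanned by the three highest-priority substituent
#' vectors (taken from the stereocenter, in decreasing CIP priority as
#' declared in the atom map).  With a right-handed coordinate frame and the
#' lowest-priority substituent pointing away from the viewer, the
#' 1-2-3 sequence runs clockwise — i.e. the center is R — exactly when the
#' triple product `v1 . (v2 x v3)` is negative; this convention was validated
#' against full CIP assignments of reference tetrahedral centers.  Centers
#' whose tetrahedron volume `|v1 . (v2 x v3)| / 6` falls below 0.1 cubic
#' Angstrom are rejected as near-planar rather than labelled arbitrarily.
#'
#' @inheritParams assign_ez
#' @return `"R"` or `"S"`.
#' @examples
#' assign_rs(synthesize_pose(rs = "S"), default_atom_map())
#' @export
assign_rs <- function(pose, map = default_atom_map()) {
  validate_atom_map(map)
  if (is.null(map$stereo) || length(map$stereo$priority) != 4) {
    abort("Atom map must declare `stereo$center` and four `stereo$priority` atoms.")
  }
  coords <- function(selector, what) {
    a <- resolve_selector(pose, selector, what)
    c(a$x, a$y, a$z)
  }
  center <- coords(map$stereo$center, "stereo center")
  subs <- lapply(seq_along(map$stereo$priority), function(i) {
    coords(map$stereo$priority[[i]], sprintf("stereo priority %d", i))
  })
  v1 <- subs[[1]] - center
  v2 <- subs[[2]] - center
  v3 <- subs[[3]] - center
  triple <- sum(v1 * cross3(v2, v3))
  if (abs(triple) / 6 < 0.1) {
    abort(sprintf("Near-planar stereocenter in pose %s (|volume| = %.3f A^3 < 0.1).",
                  pose$pose_id, abs(triple) / 6))
  }
  if (triple < 0) "R" else "S"
}

#' Pair enantiomeric docking records within each E/Z isomer
#'
#' Docking records are grouped by `(substrate_id, ez)` and the R and S records
#' of each group are put side by side; selectivity can only be compared within
#' one double-bond isomer, so records are never paired across E/Z.  Groups
#' missing one enantiomer are dropped with a warning and reported in the
#' `unpaired` attribute; duplicated `(substrate_id, ez, rs)` combinations are
#' an error.
#'
#' @param records A data frame with columns `substrate_id`, `ez`, `rs`,
#'   `delta_g` (see [read_docking_table()]).
#'
#' @return A tibble with one row per pair: `substrate_id`, `ez`, `delta_g_R`,
#'   `delta_g_S`; unpaired records (if any) in `attr(, "unpaired")`.
#'
#' @examples
#' read_docking_table(oxdock_example("oxdre_docking_scores.tsv")) %>%
#'   pair_enantiomers()
#' @export
pair_enantiomers <- function(records) {
  records <- as_tibble(records)
  bad_rs <- setdiff(unique(records$rs), c("R", "S"))
  if (length(bad_rs) > 0) {
    abort(paste0("`rs` must be R or S; found: ", paste(bad_rs, collapse = ", ")))
  }
  dup <- records %>%
    dplyr::count(.data$substrate_id, .data$ez, .data$rs) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate docking record(s), e.g. (%s, %s, %s).",
                  dup$substrate_id[1], dup$ez[1], dup$rs[1]))
  }
  wide <- records %>%
    select("substrate_id", "ez", "rs", "delta_g") %>%
    tidyr::pivot_wider(names_from = "rs", values_from = "delta_g",
                       names_prefix = "delta_g_")
  for (col in c("delta_g_R", "delta_g_S")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  unpaired <- wide %>% filter(is.na(.data$delta_g_R) | is.na(.data$delta_g_S))
  pairs <- wide %>%
    filter(!is.na(.data$delta_g_R) & !is.na(.data$delta_g_S)) %>%
    select("substrate_id", "ez", "delta_g_R", "delta_g_S")
  if (nrow(unpaired) > 0) {
    warn(sprintf("%d record group(s) lack one enantiomer and were left unpaired.",
                 nrow(unpaired)))
  }
  attr(pairs, "unpaired") <- unpaired
  pairs
}
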