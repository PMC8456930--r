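#' Elementary vector geometry on atomic coordinates
#'
#' Distances, bond angles and torsion (dihedral) angles between points in
#' Angstrom space.  These are the primitives behind
#' [extract_catalytic_geometry()]; they are exported because pharmacophore
#' debugging routinely needs them on raw coordinates.
#'
#' @param a,b,c,d Numeric 3-vectors (x, y, z) in Angstrom.
#'
#' @return `vec_distance()` returns a non-negative scalar in Angstrom.
#'   `vec_angle()` returns the angle at vertex `b` in degrees, in \[0, 180\].
#'   `vec_dihedral()` returns the signed torsion a-b-c-d in degrees, in
#'   (-180, 180\], following the IUPAC sign convention (identical to
#'   `bio3d::torsion.xyz()`).
#'
#' @details The dot product entering the angle is clamped to \[-1, 1\] before
#' `acos()` so that numerically collinear arms cannot produce `NaN`.
#' `vec_dihedral()` errors when a-b-c or b-c-d are collinear (the torsion is
#' undefined); `vec_angle()` errors on zero-length arms.
#'
#' @examples
#' vec_distance(c(0, 0, 0), c(0, 0, 2.5))
#' vec_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
#' vec_dihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(0, 1, 1))
#' @name vector-geometry
NULL

check_vec3 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 3L || !all(is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric 3-vector.", name))
  }
  as.numeric(x)
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (n < 1e-12) abort("Cannot normalize a (near) zero-length vector.")
  v / n
}

#' @rdname vector-geometry
#' @export
vec_distance <- function(a, b) {
  a <- check_vec3(a, "a"); b <- check_vec3(b, "b")
  norm3(a - b)
}

#' @rdname vector-geometry
#' @export
vec_angle <- function(a, b, c) {
  a <- check_vec3(a, "a"); b <- check_vec3(b, "b"); c <- check_vec3(c, "c")
  u <- a - b
  v <- c - b
  if (norm3(u) < 1e-12 || norm3(v) < 1e-12) {
    abort("Degenerate angle: zero-length arm at vertex `b`.")
  }
  cosang <- sum(u * v) / (norm3(u) * norm3(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' @rdname vector-geometry
#' @export
vec_dihedral <- function(a, b, c, d) {
  a <- check_vec3(a, "a"); b <- check_vec3(b, "b")
  c <- check_vec3(c, "c"); d <- check_vec3(d, "d")
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (norm3(n1) < 1e-10 || norm3(n2) < 1e-10) {
    abort("Degenerate dihedral: collinear a-b-c or b-c-d.")
  }
  m1 <- cross3(n1, unit3(b2))
  phi <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  phi
}

#' Extract the catalytic binding-motif descriptors of a pose
#'
#' Measures the five internal coordinates that define a catalytically
#' productive aldoxime pose in the Oxd active site: the Fe-N coordination
#' distance, the two hydrogen-bond distances from the oxime oxygen to the
#' Ser-OG and the His donor nitrogen, the His-O-Ser angle at the oxime oxygen,
#' and the C-N-O-O dihedral that fixes the orientation of the oxime plane
#' relative to the serine oxygen.
#'
#' @param pose An `oxd_pose`, see [read_poses()] or [synthesize_pose()].
#' @param map A catalytic atom map, see [default_atom_map()].
#'
#' @return A one-row tibble with columns `fe_n_dist`, `o_ser_dist`,
#'   `o_his_dist` (Angstrom), `his_o_ser_angle` (degrees, \[0, 180\]) and
#'   `c_n_o_o_dihedral` (degrees, (-180, 180\]).
#'
#' @examples
#' pose <- synthesize_pose()
#' extract_catalytic_geometry(pose, default_atom_map())
#' @export
extract_catalytic_geometry <- function(pose, map) {
  res <- resolve_atom_map(pose, map)
  pos <- function(role) {
    row <- res[res$role == role, ]
    c(row$x, row$y, row$z)
  }
  fe <- pos("FE"); ser_o <- pos("SER_O"); his <- pos("HIS_DONOR")
  lig_n <- pos("LIG_N"); lig_o <- pos("LIG_O"); lig_c <- pos("LIG_C")
  partner <- pos("PARTNER_O")
  tibble(
    fe_n_dist = vec_distance(fe, lig_n),
    o_ser_dist = vec_distance(lig_o, ser_o),
    o_his_dist = vec_distance(lig_o, his),
    his_o_ser_angle = vec_angle(his, lig_o, ser_o),
    c_n_o_o_dihedral = vec_dihedral(lig_c, lig_n, lig_o, partner)
  )
}

#' Pharmacophore query for the Oxd catalytic binding motif
#'
#' A pharmacophore query is one reference value plus a symmetric tolerance per
#' binding-motif descriptor.  The defaults encode the motif measured on the
#' n-propanal oxime co-crystal redock: Fe-N 2.5 A, O-Ser 2.8 A, O-His 2.7 A,
#' His-O-Ser 115 deg, C-N-O-O 85 deg.  The crystallographic values are quoted
#' as approximate, so the tolerances are a package choice: +-0.5 A on
#' distances, +-15 deg on the angle, +-25 deg on the dihedral — wide enough to
#' accept the redocked co-crystal pose, tight enough to reject poses that miss
#' the motif outright.  The dihedral is matched on its absolute value by
#' default because the motif is quoted without sign.
#'
#' @param fe_n,o_ser,o_his Reference distances, Angstrom.
#' @param his_o_ser_angle Reference angle, degrees.
#' @param c_n_o_o_dihedral Reference dihedral, degrees.
#' @param tol_dist Tolerance applied to each distance, Angstrom.
#' @param tol_angle,tol_dihedral Tolerances in degrees.
#' @param abs_dihedral Match the dihedral on `abs(value)`?
#'
#' @return A tibble with columns `descriptor`, `reference`, `tolerance`,
#'   `abs_value` (one row per descriptor).
#'
#' @seealso [match_pharmacophore()], [read_pharmacophore()]
#' @examples
#' pharmacophore_query()
#' pharmacophore_query(tol_dist = 0.3, abs_dihedral = FALSE)
#' @export
pharmacophore_query <- function(fe_n = 2.5, o_ser = 2.8, o_his = 2.7,
                                his_o_ser_angle = 115, c_n_o_o_dihedral = 85,
                                tol_dist = 0.5, tol_angle = 15,
                                tol_dihedral = 25, abs_dihedral = TRUE) {
  q <- tibble(
    descriptor = oxd_descriptors,
    reference = c(fe_n, o_ser, o_his, his_o_ser_angle, c_n_o_o_dihedral),
    tolerance = c(tol_dist, tol_dist, tol_dist, tol_angle, tol_dihedral),
    abs_value = c(FALSE, FALSE, FALSE, FALSE, abs_dihedral)
  )
  if (any(q$tolerance < 0)) abort("Tolerances must be >= 0.")
  q
}

#' Evaluate a pose geometry against a pharmacophore query
#'
#' Each criterion passes iff `|observed - reference| <= tolerance`; when a
#' criterion carries `abs_value = TRUE` both observed and reference enter as
#' absolute values (used for the unsigned C-N-O-O dihedral).  The pose passes
#' overall iff every criterion passes.
#'
#' @param geometry A one-row data frame as returned by
#'   [extract_catalytic_geometry()], or a named numeric vector/list with the
#'   descriptor names.
#' @param query A pharmacophore query, see [pharmacophore_query()].
#'
#' @return A tibble of class `oxd_match_report` with one row per criterion
#'   (`descriptor`, `observed`, `reference`, `tolerance`, `abs_value`,
#'   `deviation`, `pass`) and an attribute `overall` (logical); see
#'   [pharmacophore_pass()], and `tidy()`/`glance()` methods.
#'
#' @examples
#' geom <- extract_catalytic_geometry(synthesize_pose(), default_atom_map())
#' rep <- match_pharmacophore(geom, pharmacophore_query())
#' pharmacophore_pass(rep)
#' @export
match_pharmacophore <- function(geometry, query = pharmacophore_query()) {
  geometry <- as.list(geometry)
  missing <- setdiff(query$descriptor, names(geometry))
  if (length(missing) > 0) {
    abort(paste0("Geometry lacks descriptor(s): ", paste(missing, collapse = ", ")))
  }
  report <- query %>%
    mutate(
      observed = map_dbl(.data$descriptor, ~ as.numeric(geometry[[.x]])),
      deviation = ifelse(.data$abs_value,
                         abs(abs(.data$observed) - abs(.data$reference)),
                         abs(.data$observed - .data$reference)),
      pass = .data$deviation <= .data$tolerance
    ) %>%
    select("descriptor", "observed", "reference", "tolerance",
           "abs_value", "deviation", "pass")
  structure(report,
            overall = all(report$pass),
            class = c("oxd_match_report", class(report)))
}

#' @rdname match_pharmacophore
#' @param report An `oxd_match_report`.
#' @export
pharmacophore_pass <- function(report) {
  isTRUE(attr(report, "overall"))
}

#' Filter a pose ensemble through the pharmacophore and pick the best pose
#'
#' `filter_poses()` evaluates every pose of an ensemble and returns one row
#' per pose with its descriptors, per-criterion outcome and overall flag.
#' `select_best_valid_pose()` implements the aggregation rule used throughout
#' the pipeline: among poses passing the pharmacophore, keep the one with the
#' lowest (most negative) binding energy; ties are broken by lexicographic
#' `pose_id`; `NULL` when no pose passes.
#'
#' @param poses A list of `oxd_pose` objects sharing one ligand identity.
#' @param map Catalytic atom map, see [default_atom_map()].
#' @param query Pharmacophore query, see [pharmacophore_query()].
#'
#' @return `filter_poses()`: a tibble with columns `pose_id`,
#'   `binding_energy`, the five descriptors, `overall`, and a list-column
#'   `report` of `oxd_match_report`s.  `select_best_valid_pose()`: an
#'   `oxd_pose` or `NULL`.
#'
#' @examples
#' ens <- generate_pose_ensemble(2, 2, seed = 1)
#' filter_poses(ens)
#' best <- select_best_valid_pose(ens)
#' best$pose_id
#' @export
filter_poses <- function(poses, map = default_atom_map(),
                         query = pharmacophore_query()) {
  if (length(poses) == 0) {
    warn("No poses supplied; returning an empty report.")
    return(tibble(pose_id = character(), binding_energy = double(),
                  overall = logical()))
  }
  rows <- map(poses, function(pose) {
    geom <- extract_catalytic_geometry(pose, map)
    rep <- match_pharmacophore(geom, query)
    dplyr::bind_cols(
      tibble(pose_id = pose$pose_id,
             binding_energy = pose$binding_energy %||% NA_real_),
      geom,
      tibble(overall = pharmacophore_pass(rep), report = list(rep))
    )
  })
  bind_rows(rows)
}

#' @rdname filter_poses
#' @export
select_best_valid_pose <- function(poses, map = default_atom_map(),
                                   query = pharmacophore_query()) {
  tab <- filter_poses(poses, map, query)
  valid <- which(tab$overall)
  if (length(valid) == 0) return(NULL)
  if (length(valid) > 1 && anyNA(tab$binding_energy[valid])) {
    abort("Multiple poses pass the pharmacophore but lack binding energies; cannot rank.")
  }
  sub <- tab[valid, ]
  ord <- order(sub$binding_energy, sub$pose_id)
  best_id <- sub$pose_id[ord[1L]]
  poses[[which(map_chr(poses, "pose_id") == best_id)[1L]]]
}
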