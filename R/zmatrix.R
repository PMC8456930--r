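#' Build Cartesian coordinates from internal coordinates (z-matrix)
#'
#' Places atoms sequentially by natural-extension-reference-frame (NeRF)
#' construction.  Row i of the z-matrix gives the new atom's bond length to
#' reference atom `ref1`, the angle new-`ref1`-`ref2`, and the torsion
#' new-`ref1`-`ref2`-`ref3`; all references must be previously placed atoms.
#' The first atom sits at the origin, the second along +x from its `ref1`, the
#' third is placed in the xy-plane from its distance and angle.  Measuring any
#' specified internal coordinate on the output (with [vec_distance()],
#' [vec_angle()], [vec_dihedral()]) reproduces it to better than 1e-6.
#'
#' @param zmatrix A data frame with columns `name` (optional, used as row
#'   names of the result), `ref1`, `ref2`, `ref3` (integer indices of earlier
#'   rows; `NA` where not applicable), `distance` (Angstrom), `angle`,
#'   `dihedral` (degrees).
#'
#' @return An n x 3 numeric matrix of coordinates, row names taken from
#'   `name` when present.
#'
#' @examples
#' zm <- data.frame(
#'   name = c("O1", "OG", "NE2"),
#'   ref1 = c(NA, 1, 1), ref2 = c(NA, NA, 2), ref3 = NA,
#'   distance = c(NA, 2.8, 2.7), angle = c(NA, NA, 115), dihedral = NA
#' )
#' xyz <- build_from_internal(zm)
#' vec_angle(xyz["NE2", ], xyz["O1", ], xyz["OG", ])
#' @export
build_from_internal <- function(zmatrix) {
  zm <- as.data.frame(zmatrix)
  n <- nrow(zm)
  if (n == 0) abort("Empty z-matrix.")
  for (col in c("ref1", "ref2", "ref3", "distance", "angle", "dihedral")) {
    if (!col %in% names(zm)) zm[[col]] <- NA_real_
  }
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    refs <- c(zm$ref1[i], zm$ref2[i], zm$ref3[i])
    needed <- min(i - 1L, 3L)
    used <- refs[seq_len(needed)]
    if (any(is.na(used)) || any(used >= i) || any(used < 1) ||
        anyDuplicated(c(used)) > 0) {
      if (i > 1L) abort(sprintf("Invalid reference topology at z-matrix row %d.", i))
    }
    if (i == 1L) {
      xyz[i, ] <- c(0, 0, 0)
    } else if (i == 2L) {
      r <- zm$distance[i]
      if (!is.finite(r) || r <= 0) abort("Row 2 needs a positive distance.")
      xyz[i, ] <- xyz[zm$ref1[i], ] + c(r, 0, 0)
    } else if (i == 3L) {
      r <- zm$distance[i]; th <- zm$angle[i]
      if (!is.finite(r) || !is.finite(th)) abort("Row 3 needs distance and angle.")
      a <- xyz[zm$ref1[i], ]; b <- xyz[zm$ref2[i], ]
      u <- unit3(b - a)
      th <- th * pi / 180
      # rotate u by th in the xy-plane (the first three atoms define the plane)
      perp <- unit3(cross3(cross3(u, c(0, 0, 1)), u))
      xyz[i, ] <- a + r * (cos(th) * u + sin(th) * perp)
    } else {
      r <- zm$distance[i]; th <- zm$angle[i]; ph <- zm$dihedral[i]
      if (!is.finite(r) || !is.finite(th) || !is.finite(ph)) {
        abort(sprintf("Row %d needs distance, angle and dihedral.", i))
      }
      xyz[i, ] <- place_nerf(r, th, ph,
                             xyz[zm$ref1[i], ], xyz[zm$ref2[i], ], xyz[zm$ref3[i], ])
    }
  }
  if (!is.null(zm$name)) rownames(xyz) <- as.character(zm$name)
  xyz
}

# place D with |D-A| = r, angle(D,A,B) = theta, dihedral(D,A,B,C) = phi
# (degrees); sign convention matches vec_dihedral (IUPAC)
place_nerf <- function(r, theta, phi, A, B, C) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  xhat <- unit3(A - B)
  zhat <- unit3(cross3(C - B, A - B))
  yhat <- cross3(zhat, xhat)
  A + (-r * cos(th)) * xhat +
    (-r * sin(th) * cos(ph)) * yhat +
    (-r * sin(th) * sin(ph)) * zhat
}
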