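#' Simulate a competitive irreversible kinetic resolution
#'
#' The minimal kinetic model under which the Chen–Sih E-value relation is
#' exact: the two enantiomers of a racemate (equal initial amounts, here 1
#' each) are consumed irreversibly in parallel pseudo-first-order reactions
#' whose rate constants differ by the factor `true_e`
#' (`d[fast]/dt = -k E [fast]`, `d[slow]/dt = -k [slow]`), with no product
#' inhibition and no E/Z interconversion.  Eliminating time gives
#' `fast = slow^E`, so the closed-form mode solves that relation on a
#' conversion grid by bracketed root-finding (bisection-secant via
#' `stats::uniroot`, tolerance 1e-12 on the slow fraction — robust up to
#' E ~ 1e6); the `ode` mode integrates the rate equations numerically with
#' `deSolve::lsoda` and locates each grid conversion by root-finding in time.
#' The two modes agree to better than 1e-8 in product ee.
#'
#' @param true_e True enantiomeric ratio, `>= 1`.
#' @param stop_conversion Final conversion of the trajectory, in (0, 1).
#' @param n_points Number of equally spaced conversion samples.
#' @param method `"closed_form"` (default) or `"ode"`.
#'
#' @return A tibble of class `oxd_trajectory` with columns `conversion`,
#'   `ee_product`, `ee_substrate`, `frac_fast`, `frac_slow` (remaining
#'   fraction of each enantiomer) and attributes `true_e`, `stop_conversion`,
#'   `method`.  At every point `conversion = 1 - (frac_fast + frac_slow) / 2`.
#'
#' @examples
#' simulate_resolution(44, stop_conversion = 0.4, n_points = 5)
#' @export
simulate_resolution <- function(true_e, stop_conversion = 0.5, n_points = 25,
                                method = c("closed_form", "ode")) {
  method <- match.arg(method)
  if (!is.finite(true_e) || true_e < 1) abort("`true_e` must be >= 1.")
  if (!is.finite(stop_conversion) || stop_conversion <= 0 || stop_conversion >= 1) {
    abort("`stop_conversion` must be in (0, 1).")
  }
  conv <- seq(stop_conversion / n_points, stop_conversion, length.out = n_points)
  fs <- switch(method,
               closed_form = resolution_closed_form(true_e, conv),
               ode = resolution_ode(true_e, conv))
  f <- fs$f
  s <- fs$s
  out <- tibble(
    conversion = conv,
    ee_product = ifelse(conv > 0, (s - f) / (2 * conv), 0),
    ee_substrate = ifelse(s + f > 0, (s - f) / (s + f), 1),
    frac_fast = f,
    frac_slow = s
  )
  structure(out, true_e = true_e, stop_conversion = stop_conversion,
            method = method,
            class = c("oxd_trajectory", class(out)))
}

# solve fast = slow^E at each conversion: (s + s^E)/2 = 1 - c; a bracketed
# root is polished by Newton steps because for very large E the residual
# slope near s = 1 amplifies the 1e-12 bracket tolerance
resolution_closed_form <- function(true_e, conv) {
  s <- map_dbl(conv, function(c_) {
    if (true_e == 1) return(1 - c_)
    g <- function(s) (s + s^true_e) / 2 - (1 - c_)
    root <- uniroot(g, c(0, 1), tol = 1e-12)$root
    for (i in 1:4) {
      step <- g(root) / ((1 + true_e * root^(true_e - 1)) / 2)
      root <- min(max(root - step, 0), 1)
    }
    root
  })
  list(f = s^true_e, s = s)
}

resolution_ode <- function(true_e, conv) {
  rate <- function(t, y, p) list(c(-p * y[1], -y[2]))
  fs_at <- function(t) {
    if (t <= 0) return(c(1, 1))
    out <- deSolve::lsoda(c(f = 1, s = 1), times = c(0, t), func = rate,
                          parms = true_e, rtol = 1e-12, atol = 1e-14)
    as.numeric(out[nrow(out), c("f", "s")])
  }
  conv_at <- function(t) 1 - sum(fs_at(t)) / 2
  res <- map(conv, function(c_) {
    t_hi <- 1
    while (conv_at(t_hi) < c_) t_hi <- t_hi * 2
    t_root <- uniroot(function(t) conv_at(t) - c_, c(0, t_hi), tol = 1e-12)$root
    fs_at(t_root)
  })
  list(f = map_dbl(res, 1), s = map_dbl(res, 2))
}

#' Draw noisy observations from a resolution trajectory
#'
#' Emulates measured biotransformation endpoints: trajectory points (cycled
#' when `n` exceeds the number of points) perturbed by independent Gaussian
#' noise on conversion and product ee, then clipped to the feasible domain
#' (`0 < conversion < 1`, `0 <= ee`, `conversion * (1 + ee) < 1`).  With both
#' standard deviations zero the observations equal the trajectory points.
#' Fully reproducible under a fixed `seed`.
#'
#' @param trajectory An `oxd_trajectory`, see [simulate_resolution()].
#' @param sd_conversion,sd_ee Absolute Gaussian standard deviations on the
#'   conversion and product-ee fractions.
#' @param n Number of observations.
#' @param seed Optional integer seed (local to this call).
#' @param substrate_id,ez,preferred_config Labels stamped on the observations
#'   so they fit the experiment-table schema.
#'
#' @return A tibble of resolution observations (`substrate_id`, `ez`,
#'   `conversion`, `ee_product`, `preferred_config`, plus the noise-free
#'   `true_conversion`, `true_ee_product`), attribute `true_e`.
#'
#' @examples
#' traj <- simulate_resolution(44, 0.4, 10)
#' sample_noisy_observations(traj, 0.01, 0.01, n = 5, seed = 1)
#' @export
sample_noisy_observations <- function(trajectory, sd_conversion = 0.01,
                                      sd_ee = 0.01, n = nrow(trajectory),
                                      seed = NULL, substrate_id = "SIM",
                                      ez = "E", preferred_config = "S") {
  if (n < 1) abort("`n` must be >= 1.")
  if (sd_conversion < 0 || sd_ee < 0) abort("Noise sds must be >= 0.")
  if (!is.null(seed)) withr::local_seed(seed)
  idx <- rep_len(seq_len(nrow(trajectory)), n)
  true_c <- trajectory$conversion[idx]
  true_ee <- trajectory$ee_product[idx]
  conv <- true_c + rnorm(n, 0, sd_conversion)
  ee <- true_ee + rnorm(n, 0, sd_ee)
  conv <- pmin(pmax(conv, 1e-6), 1 - 1e-6)
  ee <- pmax(ee, 0)
  ee <- pmin(ee, (1 - 1e-9) / conv - 1, 1 - 1e-9)
  out <- tibble(
    substrate_id = substrate_id, ez = ez,
    conversion = conv, ee_product = ee,
    preferred_config = preferred_config,
    true_conversion = true_c, true_ee_product = true_ee
  )
  structure(out, true_e = attr(trajectory, "true_e"))
}

#' Fabricate a docking score table with known ddG and preference
#'
#' For every row of the design the preferred enantiomer receives the base
#' binding energy and the other enantiomer `base_dg + ddg` (less negative =
#' weaker binding), so [predict_selectivity()] on the output recovers `ddg`
#' and `preferred_config` exactly.
#'
#' @param design A data frame with columns `substrate_id`, `ez`, `ddg`
#'   (kcal/mol, `>= 0`), `preferred_config` ("R"/"S").
#' @param base_dg Binding energy of the preferred enantiomer, kcal/mol.
#'
#' @return A docking record tibble (`substrate_id`, `ez`, `rs`, `delta_g`)
#'   with two rows per design row.
#'
#' @examples
#' design <- data.frame(substrate_id = "3F", ez = "E", ddg = 1.98,
#'                      preferred_config = "S")
#' generate_docking_table(design) %>% predict_selectivity()
#' @export
generate_docking_table <- function(design, base_dg = -9) {
  design <- as_tibble(design)
  if (any(design$ddg < 0)) abort("`ddg` must be >= 0.")
  if (!all(design$preferred_config %in% c("R", "S"))) {
    abort("`preferred_config` must be R or S.")
  }
  rows <- pmap(design[, c("substrate_id", "ez", "ddg", "preferred_config")],
               function(substrate_id, ez, ddg, preferred_config) {
    other <- if (preferred_config == "R") "S" else "R"
    tibble(substrate_id = substrate_id, ez = ez,
           rs = c(preferred_config, other),
           delta_g = c(base_dg, base_dg + ddg))
  })
  bind_rows(rows)
}

# internal ligand/protein bond lengths and angles of the synthetic active
# site (idealized organic geometry; only the five motif descriptors are
# meaningful)
oxd_scaffold <- list(
  n_o = 1.40, c_n = 1.28, c_c = 1.50, c_methyl = 1.53, c_aryl = 1.51,
  c_h = 1.09, ser_cb = 1.43, his_ce1 = 1.33
)

#' Construct a synthetic active-site pose from internal coordinates
#'
#' Builds a minimal aldoxime/active-site complex whose five binding-motif
#' descriptors take exactly the requested values: ligand oxime fragment
#' (O1-N1=C1), stereocenter C2 with methyl (CM), aryl anchor (CR) and
#' hydrogen (H2) substituents, plus the protein-side anchors Ser219-OG(+CB),
#' His320-NE2(+CE1) and the heme iron.  Placement uses
#' [build_from_internal()]; remaining internal coordinates are idealized
#' organic geometry.  The E/Z label is realized through the C2-C1-N1-O1
#' torsion (180 / 0 degrees) and the R/S label through the arrangement of the
#' three C2 substituents.
#'
#' @inheritParams pharmacophore_query
#' @param ez,rs Requested isomer labels.
#' @param ez_torsion Optional explicit C2-C1-N1-O1 torsion in degrees,
#'   overriding the idealized 180 (E) / 0 (Z); useful for probing the E/Z
#'   decision boundary.
#' @param pose_id,binding_energy Pose metadata.
#' @param rotation,translation Optional rigid motion (3x3 matrix / 3-vector)
#'   applied to all coordinates.
#'
#' @return An `oxd_pose` resolvable by [default_atom_map()].
#'
#' @examples
#' pose <- synthesize_pose(ez = "Z", rs = "R")
#' extract_catalytic_geometry(pose, default_atom_map())
#' @export
synthesize_pose <- function(fe_n = 2.5, o_ser = 2.8, o_his = 2.7,
                            his_o_ser_angle = 115, c_n_o_o_dihedral = 85,
                            ez = "E", rs = "S", ez_torsion = NULL,
                            pose_id = "synthetic_pose",
                            binding_energy = NA_real_,
                            rotation = NULL, translation = NULL) {
  if (!ez %in% c("E", "Z")) abort("`ez` must be E or Z.")
  if (!rs %in% c("R", "S")) abort("`rs` must be R or S.")
  sc <- oxd_scaffold
  ez_dihedral <- ez_torsion %||% (if (ez == "E") 180 else 0)
  # torsions of the three C2 substituents about the C2-C1 bond; swapping two
  # substituents flips the handedness (calibrated against assign_rs / CIP)
  tor <- if (rs == "S") c(cm = 60, cr = 180, h = -60) else c(cm = 180, cr = 60, h = -60)
  zm <- data.frame(
    name = c("O1", "OG", "NE2", "N1", "C1", "FE", "C2", "CM", "CR", "H2",
             "CB", "CE1"),
    ref1 = c(NA, 1, 1, 1, 4, 4, 5, 7, 7, 7, 2, 3),
    ref2 = c(NA, NA, 2, 2, 1, 1, 4, 5, 5, 5, 1, 1),
    ref3 = c(NA, NA, NA, 3, 2, 2, 1, 4, 4, 4, 3, 2),
    distance = c(NA, o_ser, o_his, sc$n_o, sc$c_n, fe_n, sc$c_c,
                 sc$c_methyl, sc$c_aryl, sc$c_h, sc$ser_cb, sc$his_ce1),
    angle = c(NA, NA, his_o_ser_angle, 109, 112, 120, 122,
              109.5, 109.5, 109.5, 110, 125),
    dihedral = c(NA, NA, NA, 120, c_n_o_o_dihedral, -120, ez_dihedral,
                 tor[["cm"]], tor[["cr"]], tor[["h"]], 150, -90)
  )
  xyz <- build_from_internal(zm)
  if (!is.null(rotation)) xyz <- xyz %*% t(rotation)
  if (!is.null(translation)) xyz <- sweep(xyz, 2, translation, "+")
  atoms <- tibble(
    record = c("ATOM", "ATOM", "ATOM", "ATOM", "HETATM",
               rep("HETATM", 7)),
    atom_name = c("OG", "CB", "NE2", "CE1", "FE",
                  "O1", "N1", "C1", "C2", "CM", "CR", "H2"),
    residue_name = c("SER", "SER", "HIS", "HIS", "HEM", rep("LIG", 7)),
    residue_number = c(219L, 219L, 320L, 320L, 400L, rep(900L, 7)),
    chain_id = "A",
    element = c("O", "C", "N", "C", "FE", "O", "N", "C", "C", "C", "C", "H")
  )
  ord <- match(atoms$atom_name, rownames(xyz))
  atoms$x <- xyz[ord, 1]
  atoms$y <- xyz[ord, 2]
  atoms$z <- xyz[ord, 3]
  new_pose(pose_id, atoms, binding_energy = binding_energy, ez = ez, rs = rs)
}

# uniform random rotation matrix (det +1) from QR of a Gaussian matrix
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a pose ensemble with known pharmacophore ground truth
#'
#' Stand-in for docking-engine output: `n_valid` poses whose descriptors are
#' jittered uniformly within half the query tolerance around the reference
#' values (guaranteed passes) and `n_decoy` poses in which one descriptor —
#' cycled through the five — is displaced by twice its tolerance (guaranteed
#' failures), all placed in random rigid frames with random binding energies.
#' Ground truth (validity, violated descriptor, energies, labels) is recorded
#' in the `ground_truth` attribute.  Output is fully deterministic under a
#' fixed `seed`; writing with [write_poses()] is byte-identical across runs.
#'
#' @param n_valid,n_decoy Pose counts, `>= 0`.
#' @param query Pharmacophore query defining reference values and tolerances.
#' @param seed Optional integer seed (local to this call).
#' @param ez,rs Isomer labels given to every pose.
#'
#' @return A list of `oxd_pose` with attribute `ground_truth` (tibble:
#'   `pose_id`, `valid`, `violated`, `binding_energy`).
#'
#' @examples
#' ens <- generate_pose_ensemble(5, 5, seed = 42)
#' sum(filter_poses(ens)$overall)
#' @export
generate_pose_ensemble <- function(n_valid, n_decoy,
                                   query = pharmacophore_query(),
                                   seed = NULL, ez = "E", rs = "S") {
  if (n_valid < 0 || n_decoy < 0) abort("Counts must be >= 0.")
  if (!is.null(seed)) withr::local_seed(seed)
  ref <- setNames(query$reference, query$descriptor)
  tol <- setNames(query$tolerance, query$descriptor)
  n_total <- n_valid + n_decoy
  poses <- vector("list", n_total)
  truth <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    valid <- i <= n_valid
    desc <- ref + runif(5, -tol / 2, tol / 2)
    violated <- NA_character_
    if (!valid) {
      k <- ((i - n_valid - 1) %% 5) + 1
      violated <- names(ref)[k]
      desc[k] <- ref[k] + sample(c(-1, 1), 1) * 2 * tol[k]
    }
    energy <- round(runif(1, -10, -5), 2)
    id <- sprintf("pose_%03d", i)
    poses[[i]] <- synthesize_pose(
      fe_n = desc[["fe_n_dist"]], o_ser = desc[["o_ser_dist"]],
      o_his = desc[["o_his_dist"]],
      his_o_ser_angle = desc[["his_o_ser_angle"]],
      c_n_o_o_dihedral = desc[["c_n_o_o_dihedral"]],
      ez = ez, rs = rs, pose_id = id, binding_energy = energy,
      rotation = random_rotation(),
      translation = runif(3, -20, 20)
    )
    truth[[i]] <- tibble(pose_id = id, valid = valid, violated = violated,
                         binding_energy = energy)
  }
  structure(poses, ground_truth = bind_rows(truth))
}

#' Write a complete synthetic dataset bundle
#'
#' One call produces everything the pipeline consumes, with ground truth:
#' a noise-free resolution trajectory and noisy observations at the headline
#' `true_e`; a docking design (three substrates times E/Z, E preferring S and
#' Z preferring R, as for OxdRE) realized as a score table; a pose ensemble as
#' a multi-model PDB; and a JSON manifest recording the seed and all ground
#' truth.  Deterministic under `seed`: the same seed reproduces the bundle
#' byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param true_e True enantiomeric ratio of the simulated resolution.
#' @param stop_conversion,n_points Trajectory grid, see
#'   [simulate_resolution()].
#' @param n_obs,sd_conversion,sd_ee Noisy observation sampling, see
#'   [sample_noisy_observations()].
#' @param n_valid,n_decoy Pose ensemble composition.
#' @param base_dg Base binding energy of the docking design, kcal/mol.
#' @param seed Integer seed for the whole bundle.
#'
#' @return Invisibly, a named list with the file paths and the manifest list.
#'
#' @examples
#' paths <- simulate_bundle(tempfile("bundle"), true_e = 44, seed = 7,
#'                          n_obs = 10)
#' basename(unlist(paths$files))
#' @export
simulate_bundle <- function(out_dir, true_e = 44, stop_conversion = 0.4,
                            n_points = 25, n_obs = 50, sd_conversion = 0.01,
                            sd_ee = 0.01, n_valid = 5, n_decoy = 5,
                            base_dg = -9, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::local_seed(seed)
  traj <- simulate_resolution(true_e, stop_conversion, n_points)
  obs <- sample_noisy_observations(traj, sd_conversion, sd_ee, n = n_obs)
  design <- tibble(
    substrate_id = rep(c("2F", "3F", "4F"), each = 2),
    ez = rep(c("E", "Z"), 3),
    ddg = round(runif(6, 0.5, 3), 2),
    preferred_config = rep(c("S", "R"), 3)
  )
  docking <- generate_docking_table(design, base_dg = base_dg)
  ensemble <- generate_pose_ensemble(n_valid, n_decoy)
  files <- list(
    trajectory = file.path(out_dir, "trajectory.tsv"),
    observations = file.path(out_dir, "observations.tsv"),
    docking = file.path(out_dir, "docking.tsv"),
    poses = file.path(out_dir, "poses.pdb"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_tsv(traj, files$trajectory)
  readr::write_tsv(obs, files$observations)
  readr::write_tsv(docking, files$docking)
  write_poses(ensemble, files$poses)
  manifest <- list(
    seed = seed, true_e = true_e, stop_conversion = stop_conversion,
    sd_conversion = sd_conversion, sd_ee = sd_ee, base_dg = base_dg,
    docking_design = design,
    pose_ground_truth = attr(ensemble, "ground_truth")
  )
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(list(files = files, manifest = manifest))
}
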