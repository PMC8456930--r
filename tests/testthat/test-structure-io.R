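test_that("write-then-read round-trips coordinates to PDB precision and metadata", {
  poses <- generate_pose_ensemble(2, 1, seed = 21)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_poses(poses, tf)
  back <- read_poses(tf)
  expect_length(back, 3)
  for (i in seq_along(poses)) {
    expect_equal(back[[i]]$pose_id, poses[[i]]$pose_id)
    expect_equal(back[[i]]$binding_energy, poses[[i]]$binding_energy,
                 tolerance = 1e-8)
    expect_equal(back[[i]]$ez, poses[[i]]$ez)
    expect_equal(back[[i]]$rs, poses[[i]]$rs)
    expect_lt(
      max(abs(as.matrix(back[[i]]$atoms[, c("x", "y", "z")]) -
              as.matrix(poses[[i]]$atoms[, c("x", "y", "z")]))),
      1e-3 + 1e-12
    )
  }
  # a second parse of a re-write is bitwise coordinate-stable
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  write_poses(back, tf2)
  again <- read_poses(tf2)
  expect_equal(as.matrix(again[[1]]$atoms[, c("x", "y", "z")]),
               as.matrix(back[[1]]$atoms[, c("x", "y", "z")]))
})

test_that("model count and ligand detection follow the PDB content", {
  # hand-written single-model file: 5 ligand HETATMs plus excluded water/heme
  lines <- c(
    "HETATM    1 FE   HEM A 400       0.000   0.000   0.000  1.00  0.00          FE",
    "ATOM      2  OG  SER A 219       2.800   0.000   0.000  1.00  0.00           O",
    "HETATM    3  O   HOH A 501       9.000   9.000   9.000  1.00  0.00           O",
    sprintf("HETATM    %d  C%d  LIG A 900       %.3f   1.000   1.000  1.00  0.00           C",
            4:8, 1:5, seq(1, 3, length.out = 5)),
    "END"
  )
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  poses <- read_poses(tf)
  expect_length(poses, 1)
  expect_equal(nrow(ligand_atoms(poses[[1]])), 5)
  # heme and water are protein-side / excluded from the ligand
  prot <- protein_atoms(poses[[1]])
  expect_true(all(c("HEM", "SER", "HOH") %in% prot$residue_name))
  expect_false("HEM" %in% ligand_atoms(poses[[1]])$residue_name)
})

test_that("unreadable or atom-free files are errors", {
  expect_error(read_poses(file.path(tempdir(), "no_such_file.pdb")), "not found")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), tf)
  expect_error(read_poses(tf), "No ATOM/HETATM")
})

test_that("atom-map resolution binds all nine roles, deterministically", {
  pose <- synthesize_pose()
  map <- default_atom_map()
  res <- resolve_atom_map(pose, map)
  expect_equal(nrow(res), 9)
  expect_setequal(res$role, c("FE", "SER_O", "HIS_DONOR", "LIG_N", "LIG_O",
                              "LIG_C", "LIG_SUBSTITUENT_HEAVY",
                              "LIG_H_AT_STEREOCENTER", "PARTNER_O"))
  # order-independence of the atom records
  shuffled <- pose
  set.seed(3)
  shuffled$atoms <- shuffled$atoms[sample(nrow(shuffled$atoms)), ]
  expect_equal(resolve_atom_map(shuffled, map), res)
})

test_that("unresolved and ambiguous roles are errors", {
  pose <- synthesize_pose()
  map <- default_atom_map()
  map$roles$SER_O <- sel("A", 999, "SER", "OG")
  expect_error(resolve_atom_map(pose, map), "Unresolved role SER_O")
  dup <- synthesize_pose()
  extra <- dup$atoms[dup$atoms$atom_name == "O1", ]
  dup$atoms <- rbind(dup$atoms, extra)
  expect_error(resolve_atom_map(dup, default_atom_map()), "Ambiguous role")
})

test_that("docking tables parse with autodetected delimiter and unicode minus", {
  tab <- reference_docking()
  expect_equal(nrow(tab), 12)
  expect_type(tab$delta_g, "double")
  expect_equal(tab$substrate_id[1], "2F")
  # CSV with a unicode minus parses to the same value as ASCII minus
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("substrate_id,ez_label,rs_label,delta_g",
               "2F,E,R,−7.30", "2F,E,S,-9.17"), tf)
  uni <- read_docking_table(tf)
  expect_equal(uni$delta_g, c(-7.30, -9.17))
})

test_that("docking table problems are reported", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("substrate_id\tez_label\trs_label\tdelta_g", tf)
  expect_warning(empty <- read_docking_table(tf), "empty")
  expect_equal(nrow(empty), 0)
  writeLines(c("substrate_id\tez_label\tdelta_g", "2F\tE\t-7.3"), tf)
  expect_error(read_docking_table(tf), "Missing column")
  writeLines(c("substrate_id\tez_label\trs_label\tdelta_g",
               "2F\tE\tR\tnot_a_number"), tf)
  expect_error(read_docking_table(tf), "Non-numeric")
})

test_that("resolution tables normalize percent and fraction inputs identically", {
  pct <- reference_observations()
  expect_equal(pct$conversion, c(45, 50, 48, 52, 34, 32) / 100)
  expect_equal(pct$ee_product[1], 0.96)
  # extra columns carried through with restored types
  expect_true(is.numeric(pct$reported_e))
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(
    data.frame(substrate_id = "2F", ez = "E", conversion = 0.45,
               ee_product = 0.96, preferred_config = "S"),
    tf
  )
  fr <- read_resolution_table(tf)
  expect_equal(fr$conversion, 0.45)
  expect_equal(fr$ee_product, 0.96)
})

test_that("atom map and pharmacophore YAML files round-trip", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_atom_map(default_atom_map(), tf)
  back <- read_atom_map(tf)
  expect_equal(back$roles, default_atom_map()$roles)
  tf2 <- withr::local_tempfile(fileext = ".yaml")
  q <- pharmacophore_query(tol_dist = 0.35)
  write_pharmacophore(q, tf2)
  expect_equal(read_pharmacophore(tf2), q)
})
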