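# HETATM residues never treated as ligand: waters, the heme cofactor (a
# pharmacophore anchor, so protein-side), and common ions / buffer components
oxd_ligand_exclude <- c(
  "HOH", "WAT", "DOD", "HEM", "NA", "K", "CL", "MG", "CA", "ZN", "FE",
  "MN", "CU", "NI", "CO", "SO4", "PO4", "GOL", "EDO"
)

#' Construct a pose object
#'
#' An `oxd_pose` holds one docked (or crystallographic) ligand placement in a
#' protein frame: a tidy atom table plus an optional docking binding energy
#' and optional E/Z–R/S isomer labels.
#'
#' @param pose_id Character scalar identifying the pose.
#' @param atoms A data frame with columns `record` ("ATOM"/"HETATM"),
#'   `atom_name`, `residue_name`, `residue_number`, `chain_id`, `x`, `y`, `z`,
#'   `element`; optional `eleno`, `is_ligand` (recomputed from `record` +
#'   residue exclusion list when absent).
#' @param binding_energy Optional docking score, kcal/mol (more negative =
#'   stronger binding).
#' @param ez,rs Optional isomer labels ("E"/"Z", "R"/"S").
#'
#' @return An object of class `oxd_pose`.
#' @seealso [read_poses()], [synthesize_pose()]
#' @export
new_pose <- function(pose_id, atoms, binding_energy = NA_real_,
                     ez = NA_character_, rs = NA_character_) {
  atoms <- as_tibble(atoms)
  needed <- c("record", "atom_name", "residue_name", "residue_number",
              "chain_id", "x", "y", "z", "element")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("Atom table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("A pose needs at least one atom.")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("Atom positions must be finite.")
  }
  if (any(!nzchar(atoms$element) | is.na(atoms$element))) {
    abort("Every atom needs a non-empty element.")
  }
  if (!"eleno" %in% names(atoms)) atoms$eleno <- seq_len(nrow(atoms))
  atoms$chain_id <- ifelse(is.na(atoms$chain_id) | !nzchar(atoms$chain_id),
                           "A", atoms$chain_id)
  if (!"is_ligand" %in% names(atoms)) {
    atoms$is_ligand <- atoms$record == "HETATM" &
      !(toupper(atoms$residue_name) %in% oxd_ligand_exclude)
  }
  if (!any(atoms$is_ligand)) abort("Pose contains no ligand atoms.")
  if (!is.na(binding_energy) && !is.finite(binding_energy)) {
    abort("`binding_energy` must be finite (or NA).")
  }
  structure(
    list(pose_id = as.character(pose_id), atoms = atoms,
         binding_energy = as.numeric(binding_energy),
         ez = ez, rs = rs),
    class = "oxd_pose"
  )
}

#' @export
print.oxd_pose <- function(x, ...) {
  cat(sprintf("<oxd_pose> %s: %d protein / %d ligand atoms", x$pose_id,
              sum(!x$atoms$is_ligand), sum(x$atoms$is_ligand)))
  if (!is.na(x$binding_energy)) cat(sprintf(", dG = %.2f kcal/mol", x$binding_energy))
  if (!is.na(x$ez) || !is.na(x$rs)) cat(sprintf(" [%s,%s]", x$ez, x$rs))
  cat("\n")
  invisible(x)
}

#' @rdname new_pose
#' @param pose An `oxd_pose`.
#' @export
ligand_atoms <- function(pose) pose$atoms[pose$atoms$is_ligand, ]

#' @rdname new_pose
#' @export
protein_atoms <- function(pose) pose$atoms[!pose$atoms$is_ligand, ]

#' Read and write pose structures in PDB format
#'
#' `read_poses()` parses a (possibly multi-model) PDB file into a list of
#' [new_pose()] objects, one per MODEL block (one for files without MODEL
#' records).  HETATM records outside the water/heme/ion exclusion list are
#' flagged as ligand atoms; heme atoms (and its Fe) stay on the protein side
#' because the Fe is a pharmacophore anchor.  Alternate locations other than
#' '' / 'A' are dropped.  Blank chains become chain "A".  Residue numbers are
#' taken verbatim from the file.  Pose metadata written by `write_poses()`
#' (pose id, binding energy, isomer labels) is recovered from
#' `REMARK 250 OXDOCK` lines.
#'
#' `write_poses()` writes one or more poses; several poses become MODEL blocks
#' of one file.  Coordinates survive a write/read round trip to 1e-3 Angstrom
#' (the PDB fixed-column precision).  Output is byte-deterministic.
#'
#' @param path Path of a PDB file.
#' @param poses An `oxd_pose` or list of them.
#'
#' @return `read_poses()`: a list of `oxd_pose`.  `write_poses()`: `path`,
#'   invisibly.
#'
#' @examples
#' tf <- tempfile(fileext = ".pdb")
#' write_poses(generate_pose_ensemble(1, 1, seed = 4), tf)
#' length(read_poses(tf))
#' @export
read_poses <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM  |HETATM)", lines))) {
    abort(sprintf("No ATOM/HETATM records in %s", path))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  meta <- parse_oxdock_remarks(lines, n_models)
  base_id <- sub("\\.[^.]*$", "", basename(path))
  out <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    coords <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    elem <- at$elesy
    if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
    elem <- ifelse(is.na(elem) | !nzchar(elem),
                   toupper(substr(gsub("[^A-Za-z].*$", "", at$elety), 1, 1)),
                   elem)
    atoms <- tibble(
      record = at$type,
      eleno = at$eleno,
      atom_name = at$elety,
      residue_name = at$resid,
      residue_number = at$resno,
      chain_id = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      element = elem
    )
    mm <- meta[[m]]
    default_id <- if (n_models == 1) base_id else sprintf("%s_model%d", base_id, m)
    out[[m]] <- new_pose(
      pose_id = mm$pose_id %||% default_id,
      atoms = atoms,
      binding_energy = mm$binding_energy %||% NA_real_,
      ez = mm$ez %||% NA_character_,
      rs = mm$rs %||% NA_character_
    )
  }
  out
}

# split OXDOCK remark lines by MODEL block; returns list (length n_models) of
# lists with pose_id / binding_energy / ez / rs
parse_oxdock_remarks <- function(lines, n_models) {
  is_model <- grepl("^MODEL ", lines)
  model_idx <- cumsum(is_model)
  if (!any(is_model)) model_idx <- rep(1L, length(lines))
  rem <- grepl("^REMARK 250 OXDOCK ", lines)
  out <- rep(list(list()), n_models)
  for (i in which(rem)) {
    m <- max(1L, model_idx[i])
    if (m > n_models) next
    parts <- strsplit(trimws(sub("^REMARK 250 OXDOCK ", "", lines[i])), "\\s+")[[1]]
    if (length(parts) < 2) next
    key <- parts[1]
    val <- paste(parts[-1], collapse = " ")
    out[[m]][[switch(key,
                     POSE_ID = "pose_id",
                     BINDING_ENERGY = "binding_energy",
                     EZ = "ez",
                     RS = "rs",
                     tolower(key))]] <-
      if (key == "BINDING_ENERGY") as.numeric(val) else val
  }
  out
}

#' @rdname read_poses
#' @export
write_poses <- function(poses, path) {
  if (inherits(poses, "oxd_pose")) poses <- list(poses)
  if (length(poses) == 0) abort("No poses to write.")
  bodies <- map(poses, pose_pdb_body)
  if (length(poses) == 1) {
    out <- c(pose_remarks(poses[[1]]), bodies[[1]], "END")
  } else {
    out <- character()
    for (i in seq_along(poses)) {
      out <- c(out, sprintf("MODEL     %4d", i), pose_remarks(poses[[i]]),
               bodies[[i]], "ENDMDL")
    }
    out <- c(out, "END")
  }
  writeLines(out, path)
  invisible(path)
}

pose_remarks <- function(pose) {
  rem <- sprintf("REMARK 250 OXDOCK POSE_ID %s", pose$pose_id)
  if (!is.na(pose$binding_energy)) {
    rem <- c(rem, sprintf("REMARK 250 OXDOCK BINDING_ENERGY %.4f", pose$binding_energy))
  }
  if (!is.na(pose$ez)) rem <- c(rem, sprintf("REMARK 250 OXDOCK EZ %s", pose$ez))
  if (!is.na(pose$rs)) rem <- c(rem, sprintf("REMARK 250 OXDOCK RS %s", pose$rs))
  rem
}

pose_pdb_body <- function(pose) {
  at <- pose$atoms
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  bio3d::write.pdb(
    file = tf,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = at$record, resno = at$residue_number, resid = at$residue_name,
    eleno = at$eleno, elety = at$atom_name, chain = at$chain_id,
    elesy = at$element
  )
  lines <- readLines(tf, warn = FALSE)
  lines[grepl("^(ATOM  |HETATM)", lines)]
}

#' Catalytic atom maps: binding Oxd motif roles to concrete atoms
#'
#' The pharmacophore and stereo-assignment machinery address atoms by *role*
#' (heme iron, Ser-OG acceptor, His donor nitrogen, ligand oxime N/O/C, ...)
#' rather than by name, so the same pipeline runs on crystal structures,
#' docking output and synthetic poses.  A catalytic atom map resolves each
#' role to `(chain, residue number, residue name, atom name)`, and declares
#' the stereocenter with its four substituent anchor atoms in decreasing CIP
#' priority ("CIP-lite": the priorities are stated by the user for the small,
#' fixed ligand set instead of computed by full CIP rules).
#'
#' `default_atom_map()` matches the synthetic active site produced by
#' [synthesize_pose()] / [generate_pose_ensemble()] and the OxdRE numbering
#' (Ser219-OG acceptor, His320-NE2 donor, heme Fe): the His donor defaults to
#' the heavy donor nitrogen because hydrogens are routinely absent from files,
#' and `PARTNER_O` (the fourth atom of the C-N-O-O dihedral) defaults to
#' Ser-OG, the only other motif oxygen.
#'
#' @param lig_resno,lig_resname,lig_chain Residue number / name / chain of the
#'   ligand in the structure.
#' @param fe,ser_o,his_donor Selectors (lists with `chain`, `resno`,
#'   `resname`, `atom`) overriding the protein-side anchors.
#'
#' @return A list of class `oxd_atom_map` with elements `roles` (named list of
#'   selectors for FE, SER_O, HIS_DONOR, LIG_N, LIG_O, LIG_C,
#'   LIG_SUBSTITUENT_HEAVY, LIG_H_AT_STEREOCENTER, PARTNER_O) and `stereo`
#'   (`center` selector plus `priority`, four selectors in decreasing CIP
#'   priority).
#'
#' @seealso [resolve_atom_map()], [read_atom_map()]
#' @export
default_atom_map <- function(lig_resno = 900, lig_resname = "LIG",
                             lig_chain = "A",
                             fe = sel("A", 400, "HEM", "FE"),
                             ser_o = sel("A", 219, "SER", "OG"),
                             his_donor = sel("A", 320, "HIS", "NE2")) {
  lig <- function(atom) sel(lig_chain, lig_resno, lig_resname, atom)
  structure(
    list(
      roles = list(
        FE = fe, SER_O = ser_o, HIS_DONOR = his_donor,
        LIG_N = lig("N1"), LIG_O = lig("O1"), LIG_C = lig("C1"),
        LIG_SUBSTITUENT_HEAVY = lig("C2"),
        LIG_H_AT_STEREOCENTER = lig("H2"),
        PARTNER_O = ser_o
      ),
      stereo = list(
        center = lig("C2"),
        priority = list(lig("C1"), lig("CR"), lig("CM"), lig("H2"))
      )
    ),
    class = "oxd_atom_map"
  )
}

#' @rdname default_atom_map
#' @param chain,resno,resname,atom Selector components; `resname`/`chain` may
#'   be `NULL` to match any.
#' @export
sel <- function(chain, resno, resname, atom) {
  list(chain = chain, resno = resno, resname = resname, atom = atom)
}

oxd_roles <- c("FE", "SER_O", "HIS_DONOR", "LIG_N", "LIG_O", "LIG_C",
               "LIG_SUBSTITUENT_HEAVY", "LIG_H_AT_STEREOCENTER", "PARTNER_O")

validate_atom_map <- function(map) {
  if (!is.list(map) || is.null(map$roles)) abort("Not a catalytic atom map.")
  missing <- setdiff(oxd_roles, names(map$roles))
  if (length(missing) > 0) {
    abort(paste0("Atom map lacks role(s): ", paste(missing, collapse = ", ")))
  }
  invisible(map)
}

# match one selector against a pose atom table; errors when the match is not
# unique
resolve_selector <- function(pose, selector, what) {
  at <- pose$atoms
  hit <- at$atom_name == selector$atom & at$residue_number == selector$resno
  if (!is.null(selector$resname)) hit <- hit & at$residue_name == selector$resname
  if (!is.null(selector$chain)) hit <- hit & at$chain_id == selector$chain
  idx <- which(hit)
  if (length(idx) == 0) {
    abort(sprintf("Unresolved role %s in pose %s: no atom %s in residue %s %s.",
                  what, pose$pose_id, selector$atom,
                  selector$resname %||% "?", selector$resno))
  }
  if (length(idx) > 1) {
    abort(sprintf("Ambiguous role %s in pose %s: %d atoms match.",
                  what, pose$pose_id, length(idx)))
  }
  at[idx, ]
}

#' Resolve a catalytic atom map against a pose
#'
#' Binds every role of the map to exactly one atom of the pose; unresolved or
#' ambiguous roles are errors.  The result is deterministic and independent of
#' atom record order.
#'
#' @param pose An `oxd_pose`.
#' @param map An `oxd_atom_map`, see [default_atom_map()].
#'
#' @return A tibble with one row per role: `role`, `atom_name`, `element`,
#'   `residue_name`, `residue_number`, `chain_id`, `x`, `y`, `z`.
#'
#' @examples
#' resolve_atom_map(synthesize_pose(), default_atom_map())
#' @export
resolve_atom_map <- function(pose, map = default_atom_map()) {
  validate_atom_map(map)
  rows <- imap(map$roles, function(selector, role) {
    a <- resolve_selector(pose, selector, role)
    tibble(role = role, atom_name = a$atom_name, element = a$element,
           residue_name = a$residue_name, residue_number = a$residue_number,
           chain_id = a$chain_id, x = a$x, y = a$y, z = a$z)
  })
  bind_rows(rows)
}

#' @rdname default_atom_map
#' @param path Path of a YAML atom-map file.
#' @export
read_atom_map <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_atom_map(raw)
  structure(raw, class = "oxd_atom_map")
}

#' @rdname default_atom_map
#' @param map An `oxd_atom_map`.
#' @export
write_atom_map <- function(map, path) {
  validate_atom_map(map)
  yaml::write_yaml(unclass(map), path)
  invisible(path)
}

#' @rdname pharmacophore_query
#' @param path Path of a YAML pharmacophore file (per descriptor: `reference`,
#'   `tolerance`, optional `abs_value`).
#' @export
read_pharmacophore <- function(path) {
  raw <- yaml::read_yaml(path)
  crit <- raw$criteria %||% raw
  missing <- setdiff(oxd_descriptors, names(crit))
  if (length(missing) > 0) {
    abort(paste0("Pharmacophore file lacks descriptor(s): ",
                 paste(missing, collapse = ", ")))
  }
  bind_rows(lapply(oxd_descriptors, function(d) {
    tibble(descriptor = d,
           reference = as.numeric(crit[[d]]$reference),
           tolerance = as.numeric(crit[[d]]$tolerance),
           abs_value = isTRUE(crit[[d]]$abs_value))
  }))
}

#' @rdname pharmacophore_query
#' @param query A pharmacophore query tibble.
#' @export
write_pharmacophore <- function(query, path) {
  crit <- setNames(
    lapply(seq_len(nrow(query)), function(i) {
      list(reference = query$reference[i], tolerance = query$tolerance[i],
           abs_value = query$abs_value[i])
    }),
    query$descriptor
  )
  yaml::write_yaml(list(criteria = crit), path)
  invisible(path)
}

# --- tabular inputs -------------------------------------------------------

normalize_minus <- function(x) {
  if (is.character(x)) gsub("[−–—]", "-", x) else x
}

# everything is read as character (ids like "2F" must never be coerced);
# numeric columns are converted explicitly by the callers
read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    col_types = readr::cols(.default = readr::col_character()))
}

# restore numeric/logical types in passthrough columns
retype_cols <- function(tab) {
  tab[] <- lapply(tab, function(col) {
    utils::type.convert(normalize_minus(col), as.is = TRUE)
  })
  tab
}

pick_col <- function(tab, candidates, required = TRUE, path = "") {
  hit <- intersect(candidates, names(tab))
  if (length(hit) == 0) {
    if (!required) return(NULL)
    abort(sprintf("Missing column (one of: %s) in %s",
                  paste(candidates, collapse = ", "), path))
  }
  hit[1]
}

#' Read a docking score table
#'
#' Expects a delimited text file (TSV or CSV, autodetected) with one row per
#' docked isomer and columns `substrate_id`, `ez_label` (or `ez`), `rs_label`
#' (or `rs`) and `delta_g` (binding energy, kcal/mol, more negative =
#' stronger).  Unicode minus signs in the energy column are accepted.
#'
#' @param path Path of the table.
#' @return A tibble with columns `substrate_id`, `ez`, `rs`, `delta_g`.
#' @examples
#' read_docking_table(oxdock_example("oxdre_docking_scores.tsv"))
#' @export
read_docking_table <- function(path) {
  tab <- read_delim_auto(path)
  if (nrow(tab) == 0) {
    warn(sprintf("Docking table %s is empty.", path))
    return(tibble(substrate_id = character(), ez = character(),
                  rs = character(), delta_g = double()))
  }
  cols <- c(
    substrate_id = pick_col(tab, c("substrate_id", "substrate"), path = path),
    ez = pick_col(tab, c("ez_label", "ez"), path = path),
    rs = pick_col(tab, c("rs_label", "rs"), path = path),
    delta_g = pick_col(tab, c("delta_g", "dg"), path = path)
  )
  out <- tibble(
    substrate_id = as.character(tab[[cols[["substrate_id"]]]]),
    ez = toupper(as.character(tab[[cols[["ez"]]]])),
    rs = toupper(as.character(tab[[cols[["rs"]]]])),
    delta_g = suppressWarnings(as.numeric(normalize_minus(tab[[cols[["delta_g"]]]])))
  )
  if (anyNA(out$delta_g)) abort(sprintf("Non-numeric delta_g value(s) in %s", path))
  out
}

#' Read an experimental kinetic-resolution table
#'
#' Expects a delimited text file with one row per biotransformation and
#' columns `substrate_id`, `ez`, `preferred_config` and either percent columns
#' (`conversion_pct`, `ee_pct`) or fraction columns (`conversion`,
#' `ee_product`).  Percent columns are divided by 100; which unit was supplied
#' must be explicit in the column name — values are never guessed from their
#' magnitude.  Extra columns are carried through.
#'
#' @param path Path of the table.
#' @return A tibble with `substrate_id`, `ez`, `conversion`, `ee_product`
#'   (fractions), `preferred_config`, plus any extra input columns.
#' @examples
#' read_resolution_table(oxdock_example("oxdre_wt_biotransformations.tsv"))
#' @export
read_resolution_table <- function(path) {
  tab <- read_delim_auto(path)
  if (nrow(tab) == 0) {
    warn(sprintf("Resolution table %s is empty.", path))
    return(tibble(substrate_id = character(), ez = character(),
                  conversion = double(), ee_product = double(),
                  preferred_config = character()))
  }
  id_col <- pick_col(tab, c("substrate_id", "substrate"), path = path)
  ez_col <- pick_col(tab, c("ez", "ez_label"), path = path)
  pref_col <- pick_col(tab, c("preferred_config", "config"), path = path)
  conv_pct <- pick_col(tab, "conversion_pct", required = FALSE)
  ee_pct <- pick_col(tab, "ee_pct", required = FALSE)
  conv_fr <- pick_col(tab, "conversion", required = FALSE)
  ee_fr <- pick_col(tab, "ee_product", required = FALSE)
  if (is.null(conv_pct) && is.null(conv_fr)) {
    abort(sprintf("Missing conversion column (conversion_pct or conversion) in %s", path))
  }
  if (is.null(ee_pct) && is.null(ee_fr)) {
    abort(sprintf("Missing ee column (ee_pct or ee_product) in %s", path))
  }
  conversion <- if (!is.null(conv_pct)) {
    as.numeric(normalize_minus(tab[[conv_pct]])) / 100
  } else {
    as.numeric(normalize_minus(tab[[conv_fr]]))
  }
  ee_product <- if (!is.null(ee_pct)) {
    as.numeric(normalize_minus(tab[[ee_pct]])) / 100
  } else {
    as.numeric(normalize_minus(tab[[ee_fr]]))
  }
  used <- c(id_col, ez_col, pref_col, conv_pct, ee_pct, conv_fr, ee_fr)
  extra <- retype_cols(tab[, setdiff(names(tab), used), drop = FALSE])
  dplyr::bind_cols(
    tibble(
      substrate_id = as.character(tab[[id_col]]),
      ez = toupper(as.character(tab[[ez_col]])),
      conversion = conversion,
      ee_product = ee_product,
      preferred_config = toupper(as.character(tab[[pref_col]]))
    ),
    extra
  )
}

#' Path of a bundled example data file
#'
#' @param file File name under the package's `extdata/` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @examples
#' oxdock_example()
#' @export
oxdock_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "oxdock")))
  }
  path <- system.file("extdata", file, package = "oxdock")
  if (!nzchar(path)) abort(sprintf("No example file '%s' in oxdock.", file))
  path
}
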