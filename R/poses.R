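# Docked-pose bundles and receptor reference sites.
#
# Pose bundles are exchanged as a multi-model PDB (one MODEL/ENDMDL block of
# HETATM records per pose; each model tagged "REMARK 99 COMPOUND <id> POSE
# <rank>") plus a per-pose CSV energy table with columns compound_id,
# pose_rank, ee, docked_energy — emulating the energies extracted from
# AutoDock docking logs. Models are heterogeneous (different ligands have
# different atom counts), which bio3d's trajectory-oriented multi-model
# reader cannot represent, so the HETATM records are extracted by fixed
# PDB columns here; receptor PDBs go through bio3d::read.pdb.

POLAR_HEAVY <- c("N", "O")

#' Construct a binding-site reference
#'
#' Holds the carboxylate oxygen coordinates of the two negatively charged
#' binding-site residues of hH4R, D3.32 (Asp94) and E5.46 (Glu182), in
#' Ballesteros-Weinstein numbering.
#'
#' @param residues A named list of exactly two numeric matrices (one per
#'   reference residue, e.g. `D3.32`, `E5.46`), each with columns x, y, z
#'   and one row per carboxylate oxygen.
#' @return A `reference_site` object.
#' @export
reference_site <- function(residues) {
  if (!is.list(residues) || length(residues) != 2 || is.null(names(residues))) {
    abort("`residues` must be a named list of exactly 2 residues.")
  }
  for (r in names(residues)) {
    m <- residues[[r]]
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) < 1 || anyNA(m)) {
      abort(sprintf(
        "Residue '%s' must be a numeric matrix with >= 1 row and 3 columns.", r))
    }
  }
  structure(residues, class = "reference_site")
}

#' @export
print.reference_site <- function(x, ...) {
  cat(sprintf("<reference_site: %s>\n",
              paste(sprintf("%s (%d oxygen(s))", names(x),
                            vapply(x, nrow, integer(1))), collapse = ", ")))
  invisible(x)
}

#' Read the reference site from a receptor PDB
#'
#' Extracts the side-chain carboxylate oxygens (OD1/OD2 for Asp, OE1/OE2 for
#' Glu) of the two configured residues.
#'
#' @param pdb_path Path to the receptor PDB file.
#' @param site Either a path to a JSON file or a named list of the form
#'   `list("D3.32" = list(chain = "A", resid = 94),
#'         "E5.46" = list(chain = "A", resid = 182))`.
#' @return A [reference_site()].
#' @export
read_reference_site <- function(pdb_path, site) {
  if (is.character(site) && length(site) == 1) {
    site <- jsonlite::read_json(site)
  }
  if (length(site) != 2) abort("Site configuration must name 2 residues.")
  pdb <- bio3d::read.pdb(pdb_path)
  atoms <- pdb$atom
  residues <- map(site, function(cfg) {
    sel <- atoms$chain == cfg$chain & atoms$resno == cfg$resid &
      atoms$elety %in% c("OD1", "OD2", "OE1", "OE2")
    m <- as.matrix(atoms[sel, c("x", "y", "z")])
    if (nrow(m) == 0) {
      abort(sprintf("No carboxylate oxygens for chain %s residue %s.",
                    cfg$chain, cfg$resid))
    }
    unname(m)
  })
  reference_site(residues)
}

# One pose's atoms as fixed-width HETATM lines.
format_hetatm <- function(atoms) {
  vapply(seq_len(nrow(atoms)), function(i) {
    el <- atoms$element[i]
    sprintf("HETATM%5d  %-3s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, paste0(el, i), atoms$x[i], atoms$y[i], atoms$z[i], el)
  }, character(1))
}

#' Write a docked-pose bundle
#'
#' Writes poses as a multi-model PDB plus the matching per-pose energy CSV
#' (columns `compound_id`, `pose_rank`, `ee`, `docked_energy`).
#'
#' @param poses A pose tibble: `compound_id`, `pose_rank`, `ee`,
#'   `docked_energy`, and an `atoms` list-column of per-pose tibbles with
#'   `element`, `x`, `y`, `z`.
#' @param pdb_path,csv_path Output paths.
#' @return `pdb_path`, invisibly.
#' @export
write_pose_bundle <- function(poses, pdb_path, csv_path) {
  check_columns(poses, c("compound_id", "pose_rank", "ee", "docked_energy",
                         "atoms"), "`poses`")
  lines <- character(0)
  for (i in seq_len(nrow(poses))) {
    lines <- c(
      lines,
      sprintf("MODEL %8d", i),
      sprintf("REMARK 99 COMPOUND %s POSE %d",
              poses$compound_id[i], poses$pose_rank[i]),
      format_hetatm(poses$atoms[[i]]),
      "ENDMDL"
    )
  }
  writeLines(c(lines, "END"), pdb_path)
  readr::write_csv(
    poses[, c("compound_id", "pose_rank", "ee", "docked_energy")], csv_path)
  invisible(pdb_path)
}

# Parse a multi-model ligand PDB into a list of models:
# list(compound_id, pose_rank, atoms tibble). Ids are NA when untagged.
parse_pose_pdb <- function(pdb_path) {
  lines <- readLines(pdb_path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (!length(model_starts)) {
    abort("No MODEL records found in pose PDB.")
  }
  model_ends <- which(trimws(rec) == "ENDMDL")
  if (length(model_ends) != length(model_starts)) {
    abort("Unbalanced MODEL/ENDMDL records in pose PDB.")
  }
  map(seq_along(model_starts), function(m) {
    block <- lines[model_starts[m]:model_ends[m]]
    tag <- grep("^REMARK 99 COMPOUND ", block, value = TRUE)
    compound_id <- NA_character_
    pose_rank <- NA_integer_
    if (length(tag)) {
      parts <- strsplit(trimws(tag[1]), "\\s+")[[1]]
      compound_id <- parts[4]
      pose_rank <- as.integer(parts[6])
    }
    atom_lines <- block[substr(block, 1, 6) %in% c("HETATM", "ATOM  ")]
    if (!length(atom_lines)) {
      abort(sprintf("Model %d of the pose PDB contains no atoms.", m))
    }
    element <- trimws(substr(atom_lines, 77, 78))
    fallback <- !nzchar(element)
    if (any(fallback)) {
      element[fallback] <- substr(trimws(substr(atom_lines[fallback], 13, 16)),
                                  1, 1)
    }
    atoms <- tibble(
      element = element,
      x = as.numeric(substr(atom_lines, 31, 38)),
      y = as.numeric(substr(atom_lines, 39, 46)),
      z = as.numeric(substr(atom_lines, 47, 54)),
      is_polar_heavy = element %in% POLAR_HEAVY
    )
    if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
      abort(sprintf("Non-numeric coordinates in model %d.", m))
    }
    list(compound_id = compound_id, pose_rank = pose_rank, atoms = atoms)
  })
}

#' Read a docked-pose bundle
#'
#' Joins a multi-model ligand PDB with its per-pose energy CSV. When models
#' carry `REMARK 99 COMPOUND <id> POSE <rank>` tags the join is on
#' (`compound_id`, `pose_rank`): CSV rows without a matching model are
#' dropped with a warning, and models without an energy row are collected in
#' the `errors` attribute. Untagged bundles are joined by order, in which
#' case a model/CSV count mismatch is fatal.
#'
#' @param pdb_path Multi-model PDB of ligand poses.
#' @param energy_csv CSV with columns `compound_id`, `pose_rank`, `ee`,
#'   `docked_energy`.
#' @return A pose tibble (`compound_id`, `pose_rank`, `ee`, `docked_energy`,
#'   `atoms` list-column with per-atom `is_polar_heavy` flags).
#' @export
read_pose_bundle <- function(pdb_path, energy_csv) {
  if (!file.exists(pdb_path)) abort(sprintf("File not found: %s", pdb_path))
  if (!file.exists(energy_csv)) abort(sprintf("File not found: %s", energy_csv))
  energies <- readr::read_csv(energy_csv, show_col_types = FALSE,
                              progress = FALSE)
  check_columns(energies, c("compound_id", "pose_rank", "ee", "docked_energy"),
                "Energy CSV")
  energies$compound_id <- as.character(energies$compound_id)
  energies$ee <- suppressWarnings(as.numeric(energies$ee))
  energies$docked_energy <- suppressWarnings(as.numeric(energies$docked_energy))
  bad <- is.na(energies$ee) | is.na(energies$docked_energy)
  if (any(bad)) {
    warn(sprintf("Skipping %d energy row(s) with non-numeric values.",
                 sum(bad)))
    energies <- energies[!bad, , drop = FALSE]
  }
  models <- parse_pose_pdb(pdb_path)
  tagged <- !map_lgl(models, function(m) is.na(m$compound_id))
  unmatched <- character(0)
  if (all(tagged)) {
    key <- function(id, rank) paste(id, rank, sep = "\r")
    model_keys <- map_chr(models, function(m) key(m$compound_id, m$pose_rank))
    csv_keys <- key(energies$compound_id, energies$pose_rank)
    drop <- !(csv_keys %in% model_keys)
    if (any(drop)) {
      warn(sprintf("Dropping %d energy row(s) without a matching model.",
                   sum(drop)))
      energies <- energies[!drop, , drop = FALSE]
      csv_keys <- csv_keys[!drop]
    }
    unmatched <- setdiff(model_keys, csv_keys)
    idx <- match(csv_keys, model_keys)
    atoms <- map(models[idx], "atoms")
  } else {
    if (length(models) != nrow(energies)) {
      abort(sprintf(
        "Untagged pose PDB has %d model(s) but the CSV has %d row(s).",
        length(models), nrow(energies)))
    }
    atoms <- map(models, "atoms")
  }
  if (length(unmatched)) {
    warn(sprintf("%d model(s) have no energy row; see attr(x, 'errors').",
                 length(unmatched)))
  }
  out <- tibble(
    compound_id = energies$compound_id,
    pose_rank = as.integer(energies$pose_rank),
    ee = energies$ee,
    docked_energy = energies$docked_energy,
    atoms = atoms
  )
  attr(out, "errors") <- gsub("\r", "/", unmatched)
  out
}

#' Keep the best docked pose per compound
#'
#' The best pose is the one with minimal total docked energy; ties are broken
#' by the lower pose rank.
#'
#' @param poses A pose tibble.
#' @return One row per compound.
#' @export
best_pose_per_compound <- function(poses) {
  check_columns(poses, c("compound_id", "pose_rank", "docked_energy"),
                "`poses`")
  poses |>
    dplyr::arrange(.data$compound_id, .data$docked_energy, .data$pose_rank) |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}
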