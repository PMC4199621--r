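# Molecule ingestion and 2D descriptor computation.
#
# Structure handling is delegated to OpenBabel through ChemmineOB: SMILES/SDF
# parsing and canonicalization, molecular properties (MW, logP, H-bond
# donors/acceptors), SMARTS matching, and Gasteiger partial charges via MOL2
# conversion. Everything downstream of the descriptor table is pure R.

#' The 2D descriptor panel
#'
#' The ordered set of two-dimensional physico-chemical descriptors used
#' throughout the package, with their units. All are computable from the
#' connection table alone (no 3D conformers):
#'
#' * `molecular_weight` — average molecular weight, Da.
#' * `total_charge` — net formal charge, elementary charges.
#' * `n_nitrogen`, `n_oxygen` — element counts.
#' * `n_aromatic_atoms` — atoms in aromatic rings.
#' * `hbd`, `hba` — hydrogen-bond donor / acceptor counts (OpenBabel
#'   definitions).
#' * `logp` — atom-contribution octanol/water partition estimate (unitless).
#' * `n_rings` — ring count (cyclomatic number of the molecular graph).
#' * `n_rot_bonds` — rotatable bonds (acyclic single bonds between
#'   non-terminal heavy atoms).
#' * `fasa_neg` — fractional negative van der Waals surface area: the VdW
#'   surface of atoms bearing a negative Gasteiger partial charge divided by
#'   the total VdW surface, each atom contributing the sphere area of its
#'   Bondi radius. An approximation of the corresponding MOE descriptor;
#'   fraction in \[0, 1\].
#'
#' @param names Optional character vector selecting a subset of the panel,
#'   in the returned order.
#' @return A tibble with columns `name` and `units`.
#' @export
#' @examples
#' descriptor_panel()
descriptor_panel <- function(names = NULL) {
  panel <- tibble::tribble(
    ~name,               ~units,
    "molecular_weight",  "Da",
    "total_charge",      "e",
    "n_nitrogen",        "count",
    "n_oxygen",          "count",
    "n_aromatic_atoms",  "count",
    "hbd",               "count",
    "hba",               "count",
    "logp",              "",
    "n_rings",           "count",
    "n_rot_bonds",       "count",
    "fasa_neg",          "fraction"
  )
  if (!is.null(names)) {
    unknown <- setdiff(names, panel$name)
    if (length(unknown)) {
      abort(sprintf("Unknown descriptor(s): %s.", paste(unknown, collapse = ", ")))
    }
    panel <- panel[match(names, panel$name), ]
  }
  panel
}

# Rotatable-bond SMARTS: single, acyclic, both atoms non-terminal and not
# triple-bonded (the common rotor definition; amide C-N bonds are counted).
ROTOR_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

# Bondi van der Waals radii (Angstrom); 1.70 for anything unlisted.
BONDI_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
  S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, Si = 2.10, B = 1.92
)

# Canonicalize one SMILES through OpenBabel. Returns NA_character_ when the
# structure does not parse.
ob_canonical <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "CAN", paste0(smiles, "\n"),
      options = data.frame(names = character(), args = character())
    )),
    error = function(e) ""
  )
  line <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
  if (is.na(line) || !nzchar(line)) return(NA_character_)
  sub("\t.*$", "", sub("\t$", "", line))
}

# MW/logP/HBD/HBA/formula/canonical SMILES plus rotor count, one molecule.
ob_properties <- function(smiles) {
  res <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(m) {
      list(
        prop = ChemmineOB::prop_OB(list(m)),
        rot  = ChemmineOB::smartsSearch_OB(list(m), ROTOR_SMARTS,
                                           uniqueMatches = TRUE)
      )
    }),
    error = function(e) NULL
  )
  if (is.null(res) || !length(res)) return(NULL)
  res[[1]]
}

# MOL2 block (2D coordinates, explicit hydrogens, Gasteiger charges) parsed
# with bio3d. Returns list(atoms, bonds) tibbles or NULL on failure.
ob_mol2_graph <- function(smiles) {
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "MOL2", paste0(smiles, "\tmol\n"),
      options = data.frame(names = c("gen2D", "h"), args = c("", ""))
    )),
    error = function(e) ""
  )
  if (!nzchar(txt)) return(NULL)
  tf <- tempfile(fileext = ".mol2")
  on.exit(unlink(tf), add = TRUE)
  writeLines(txt, tf)
  mol <- tryCatch(bio3d::read.mol2(tf), error = function(e) NULL)
  if (is.null(mol)) return(NULL)
  atoms <- tibble(
    element = mol$atom$elena,
    type = mol$atom$elety,
    charge = as.numeric(mol$atom$charge)
  )
  bonds <- if (is.null(mol$bond) || nrow(mol$bond) == 0) {
    tibble(origin = integer(), target = integer(), type = character())
  } else {
    tibble(
      origin = as.integer(mol$bond$origin),
      target = as.integer(mol$bond$target),
      type = as.character(mol$bond$type)
    )
  }
  list(atoms = atoms, bonds = bonds)
}

# Net formal charge read off the bracket atoms of a SMILES string.
smiles_formal_charge <- function(smiles) {
  brackets <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  if (!length(brackets)) return(0L)
  total <- 0L
  for (b in brackets) {
    body <- substr(b, 2, nchar(b) - 1)
    m <- regmatches(body, gregexpr("[+-][0-9]*", body))[[1]]
    for (tok in m) {
      sign <- if (substr(tok, 1, 1) == "+") 1L else -1L
      mag <- if (nchar(tok) > 1) as.integer(substr(tok, 2, nchar(tok))) else 1L
      total <- total + sign * mag
    }
    # runs like ++ or -- beyond the first token are already separate matches
  }
  total
}

# Element counts from a Hill-order molecular formula such as "C14H16ClN3O".
formula_counts <- function(formula) {
  formula <- gsub("[+-][0-9]*$", "", formula)
  m <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  counts <- integer()
  for (tok in m) {
    el <- gsub("[0-9]", "", tok)
    k <- sub("^[A-Za-z]+", "", tok)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) +
      (if (nzchar(k)) as.integer(k) else 1L)
  }
  counts
}

# All panel descriptors for a single SMILES; NULL when the structure fails.
compute_descriptors_one <- function(smiles) {
  props <- ob_properties(smiles)
  graph <- ob_mol2_graph(smiles)
  if (is.null(props) || is.null(graph)) return(NULL)
  p <- props$prop
  counts <- formula_counts(p$formula)
  n_fragments <- length(strsplit(p$cansmiNS, ".", fixed = TRUE)[[1]])
  radii <- unname(BONDI_RADII[graph$atoms$element])
  radii[is.na(radii)] <- 1.70
  area <- 4 * pi * radii^2
  fasa_neg <- if (sum(area) > 0) {
    sum(area[graph$atoms$charge < 0]) / sum(area)
  } else 0
  list(
    molecular_weight = as.numeric(p$MW),
    total_charge = as.numeric(smiles_formal_charge(p$cansmiNS)),
    n_nitrogen = as.numeric(counts["N"] %||% 0L),
    n_oxygen = as.numeric(counts["O"] %||% 0L),
    n_aromatic_atoms = sum(grepl("\\.ar$", graph$atoms$type)),
    hbd = as.numeric(p$HBD),
    hba = as.numeric(p$HBA1),
    logp = as.numeric(p$logP),
    n_rings = nrow(graph$bonds) - nrow(graph$atoms) + n_fragments,
    n_rot_bonds = as.numeric(props$rot),
    fasa_neg = fasa_neg
  )
}

#' Read molecules from a SMILES or SDF file
#'
#' Reads a molecule list, canonicalizes every structure through OpenBabel, and
#' returns one row per parseable record. Unparseable records are skipped with
#' a warning that names the offending line.
#'
#' The `.smi` dialect is one record per line, `SMILES<whitespace>id`; blank
#' lines and lines starting with `#` are ignored; a missing id is replaced by
#' `mol<k>` where `k` is the record number. V2000 SDF is accepted; ids come
#' from the molecule title.
#'
#' @param path Path to the input file.
#' @param format `"smi"` or `"sdf"`.
#' @param label Activity class attached to every molecule: `"active"`,
#'   `"inactive"` or `"unknown"`.
#' @return A tibble with columns `id`, `smiles` (canonical) and `label`.
#'   The number of skipped records is attached as attribute `n_skipped`.
#' @export
#' @examples
#' smi <- tempfile(fileext = ".smi")
#' writeLines("CN1CCN(CC1)C(=O)c1cc2cc(Cl)ccc2[nH]1 jnj7777120", smi)
#' read_molecules(smi, "smi", label = "active")
read_molecules <- function(path, format = c("smi", "sdf"),
                           label = c("unknown", "active", "inactive")) {
  format <- match.arg(format)
  label <- match.arg(label)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
    records <- trimws(lines[keep])
    line_no <- which(keep)
    ids <- character(length(records))
    smis <- character(length(records))
    for (k in seq_along(records)) {
      parts <- strsplit(records[k], "\\s+")[[1]]
      smis[k] <- parts[1]
      ids[k] <- if (length(parts) >= 2) parts[2] else sprintf("mol%d", k)
    }
    canon <- vapply(smis, ob_canonical, character(1), USE.NAMES = FALSE)
    bad <- is.na(canon)
    if (any(bad)) {
      for (k in which(bad)) {
        warn(sprintf("Skipping unparseable SMILES at line %d: %s",
                     line_no[k], smis[k]))
      }
    }
    out <- tibble(id = ids[!bad], smiles = canon[!bad], label = label)
    n_skipped <- sum(bad)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    n_records <- length(gregexpr("\\$\\$\\$\\$", txt)[[1]])
    if (!grepl("\\$\\$\\$\\$", txt)) n_records <- 1L
    conv <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SDF", "CAN", paste0(txt, "\n"),
        options = data.frame(names = character(), args = character())
      )),
      error = function(e) ""
    )
    lines <- strsplit(conv, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    smis <- sub("\t.*$", "", lines)
    ids <- sub("^[^\t]*\t?", "", lines)
    ids[!nzchar(ids)] <- sprintf("mol%d", which(!nzchar(ids)))
    out <- tibble(id = ids, smiles = smis, label = label)
    n_skipped <- max(0L, n_records - nrow(out))
    if (n_skipped > 0) {
      warn(sprintf("Skipped %d unparseable SDF record(s).", n_skipped))
    }
  }
  if (nrow(out) == 0) {
    abort(sprintf("No parseable molecules in %s.", path))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Compute 2D descriptors for a molecule table
#'
#' Appends the panel descriptors as columns to a molecule tibble. Molecules
#' whose structure cannot be processed are flagged `descriptor_ok = FALSE`
#' (with `NA` descriptors) and should be excluded downstream.
#'
#' @param data A tibble with at least a `smiles` column (as returned by
#'   [read_molecules()]).
#' @param panel A descriptor panel tibble from [descriptor_panel()], or a
#'   character vector of panel descriptor names.
#' @return `data` with one numeric column per panel descriptor plus a logical
#'   `descriptor_ok` column.
#' @export
#' @examples
#' mols <- tibble::tibble(id = "methane", smiles = "C", label = "unknown")
#' compute_descriptors(mols)[, c("id", "n_nitrogen", "hbd")]
compute_descriptors <- function(data, panel = descriptor_panel()) {
  check_columns(data, "smiles", "`data`")
  if (is.character(panel)) panel <- descriptor_panel(panel)
  values <- map(data$smiles, compute_descriptors_one)
  ok <- !map_lgl(values, is.null)
  if (any(!ok)) {
    warn(sprintf("Descriptor computation failed for %d molecule(s); flagged.",
                 sum(!ok)))
  }
  for (name in panel$name) {
    data[[name]] <- map_dbl(values, function(v) {
      if (is.null(v)) NA_real_ else v[[name]]
    })
  }
  data$descriptor_ok <- ok
  data
}
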