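# Circular fingerprints and Tanimoto similarity.
#
# The fingerprint is an ECFP4-style extended-connectivity fingerprint:
# radius-2 circular atom environments hashed to a fixed bit width. It is
# computed on the heavy-atom graph of the OpenBabel MOL2 representation
# (hydrogens folded into the atom invariant), and is independent of input
# atom ordering because neighbor environments are combined as sorted
# multisets before hashing.

FP_BITS_DEFAULT <- 2048L

# Initial atom invariant: element, SYBYL atom type (captures hybridization
# and aromaticity), heavy-atom degree and attached-hydrogen count.
fp_initial_invariants <- function(atoms, bonds) {
  n <- nrow(atoms)
  heavy <- atoms$element != "H"
  hydro_count <- integer(n)
  heavy_deg <- integer(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$origin[k]; j <- bonds$target[k]
      if (atoms$element[j] == "H") hydro_count[i] <- hydro_count[i] + 1L
      if (atoms$element[i] == "H") hydro_count[j] <- hydro_count[j] + 1L
      if (atoms$element[i] != "H" && atoms$element[j] != "H") {
        heavy_deg[i] <- heavy_deg[i] + 1L
        heavy_deg[j] <- heavy_deg[j] + 1L
      }
    }
  }
  inv <- vapply(seq_len(n), function(i) {
    str_hash(paste(atoms$element[i], atoms$type[i], heavy_deg[i],
                   hydro_count[i], sep = "|"))
  }, numeric(1))
  list(invariant = inv, heavy = heavy)
}

#' Circular (ECFP4-style) fingerprint of a molecule
#'
#' Hashes radius-0, 1 and 2 atom environments of the heavy-atom graph into a
#' sparse on-bit set of width `bits`.
#'
#' @param smiles A single SMILES string.
#' @param bits Bit width of the hashed fingerprint.
#' @return An integer vector of distinct on-bit indices in `[0, bits)`, with
#'   attribute `bit_width`; `NULL` if the structure cannot be parsed.
#' @export
#' @examples
#' fp <- morgan_fingerprint("c1ccccc1O")
#' length(fp) > 0
morgan_fingerprint <- function(smiles, bits = FP_BITS_DEFAULT) {
  stopifnot_scalar_number(bits, "bits", lower = 2, integerish = TRUE)
  graph <- ob_mol2_graph(smiles)
  if (is.null(graph)) return(NULL)
  atoms <- graph$atoms
  bonds <- graph$bonds
  init <- fp_initial_invariants(atoms, bonds)
  inv <- init$invariant
  heavy <- init$heavy
  heavy_idx <- which(heavy)
  # adjacency over heavy atoms with bond-type labels
  nb <- vector("list", nrow(atoms))
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$origin[k]; j <- bonds$target[k]
      if (heavy[i] && heavy[j]) {
        t <- str_hash(bonds$type[k])
        nb[[i]] <- rbind(nb[[i]], c(j, t))
        nb[[j]] <- rbind(nb[[j]], c(i, t))
      }
    }
  }
  identifiers <- inv[heavy_idx]
  current <- inv
  for (radius in 1:2) {
    updated <- current
    for (i in heavy_idx) {
      if (is.null(nb[[i]])) {
        env <- current[i]
      } else {
        pair_hashes <- sort(vapply(seq_len(nrow(nb[[i]])), function(r) {
          hash_combine(c(nb[[i]][r, 2], current[nb[[i]][r, 1]]))
        }, numeric(1)))
        env <- hash_combine(c(radius, current[i], pair_hashes))
      }
      updated[i] <- env
    }
    current <- updated
    identifiers <- c(identifiers, current[heavy_idx])
  }
  on_bits <- sort(unique(as.integer(identifiers %% bits)))
  structure(on_bits, bit_width = as.integer(bits))
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|` over on-bit sets. Two empty fingerprints
#' are defined to have similarity 0.
#'
#' @param a,b Fingerprints as returned by [morgan_fingerprint()] (on-bit
#'   index vectors with a `bit_width` attribute).
#' @return A similarity in `[0, 1]`.
#' @export
#' @examples
#' tanimoto(
#'   structure(c(1L, 2L, 3L), bit_width = 8L),
#'   structure(c(2L, 3L, 4L), bit_width = 8L)
#' )
tanimoto <- function(a, b) {
  wa <- attr(a, "bit_width") %||% FP_BITS_DEFAULT
  wb <- attr(b, "bit_width") %||% FP_BITS_DEFAULT
  if (wa != wb) {
    abort(sprintf("Fingerprint bit widths differ: %d vs %d.", wa, wb))
  }
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Add a fingerprint list-column to a molecule table
#'
#' @param data A tibble with a `smiles` column.
#' @param bits Fingerprint bit width.
#' @return `data` with a `fingerprint` list-column (`NULL` entries for
#'   unparseable structures).
#' @export
add_fingerprints <- function(data, bits = FP_BITS_DEFAULT) {
  check_columns(data, "smiles", "`data`")
  data$fingerprint <- map(data$smiles, morgan_fingerprint, bits = bits)
  data
}

#' Greedy-leader diversity filter
#'
#' Walks the table in input order, retaining a molecule only if its Tanimoto
#' similarity to every already-retained leader is strictly below `threshold`.
#' Every discarded molecule is therefore at similarity `>= threshold` to at
#' least one retained leader.
#'
#' @param data A molecule tibble. Fingerprints are computed on the fly from
#'   `smiles` unless a `fingerprint` list-column is present.
#' @param threshold Similarity threshold `S` in `(0, 1]`; the screening
#'   protocol used `S < 0.7` for actives and `S < 0.2` for decoys.
#' @param similarity Optional precomputed symmetric similarity matrix
#'   (rows/columns in table order), used instead of fingerprints.
#' @return The retained rows of `data`, in input order.
#' @export
diversity_filter <- function(data, threshold = 0.7, similarity = NULL) {
  stopifnot_scalar_number(threshold, "threshold", lower = 1e-12, upper = 1)
  if (nrow(data) == 0) return(data)
  if (is.null(similarity)) {
    if (!("fingerprint" %in% names(data))) data <- add_fingerprints(data)
    fps <- data$fingerprint
    sim_to <- function(i, leaders) {
      vapply(leaders, function(j) {
        if (is.null(fps[[i]]) || is.null(fps[[j]])) 0 else tanimoto(fps[[i]], fps[[j]])
      }, numeric(1))
    }
  } else {
    if (!is.matrix(similarity) || nrow(similarity) != nrow(data)) {
      abort("`similarity` must be a square matrix matching `data` rows.")
    }
    sim_to <- function(i, leaders) similarity[i, leaders]
  }
  leaders <- integer(0)
  for (i in seq_len(nrow(data))) {
    if (!length(leaders) || all(sim_to(i, leaders) < threshold)) {
      leaders <- c(leaders, i)
    }
  }
  data[leaders, , drop = FALSE]
}
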