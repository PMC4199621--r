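# Shared fixture builders. Everything is generated in code at test time.

# A labelled descriptor tibble with one informative descriptor `x`:
# actives inside [lo, hi], decoys outside.
make_separable_set <- function(n_act = 50, n_inact = 50, lo = 2, hi = 4,
                               seed = 1) {
  withr::with_seed(seed, {
    below <- runif(ceiling(n_inact / 2), 0.1, lo - 0.1)
    above <- runif(floor(n_inact / 2), hi + 0.1, 6)
    tibble::tibble(
      id = sprintf("m%03d", seq_len(n_act + n_inact)),
      label = rep(c("active", "inactive"), c(n_act, n_inact)),
      x = c(runif(n_act, lo + 0.01, hi - 0.01), below, above)
    )
  })
}

# Construct a discretized space directly from explicit cut-points.
make_space <- function(cutpoints) {
  structure(
    list(
      cutpoints = cutpoints,
      edges = lapply(cutpoints, function(cuts) c(-Inf, cuts, Inf)),
      flagged = character(0),
      bins = max(lengths(cutpoints)) + 1L
    ),
    class = "discretized_space"
  )
}

# Independent brute-force search over every axis-aligned interval filter of
# the space (subset sizes smin..smax). MCC is recomputed literally here, so
# the oracle shares no code with the optimizer.
brute_force_best <- function(training, space, smin = 1, smax = 2) {
  desc <- names(space$cutpoints)
  act <- training$label == "active"
  literal_mcc <- function(pass) {
    tp <- 100 * sum(pass & act) / sum(act)
    fp <- 100 * sum(pass & !act) / sum(!act)
    fn <- 100 - tp
    tn <- 100 - fp
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  }
  pairs_of <- function(d) {
    e <- space$edges[[d]]
    out <- list()
    for (i in seq_along(e)) {
      for (j in seq_along(e)) {
        if (j > i) out[[length(out) + 1L]] <- c(e[i], e[j])
      }
    }
    out
  }
  best <- -Inf
  best_constraints <- NULL
  for (s in smin:min(smax, length(desc))) {
    for (sub in utils::combn(desc, s, simplify = FALSE)) {
      pair_lists <- lapply(sub, pairs_of)
      idx_grid <- expand.grid(lapply(pair_lists, seq_along))
      for (r in seq_len(nrow(idx_grid))) {
        pass <- rep(TRUE, nrow(training))
        constraints <- list()
        for (k in seq_along(sub)) {
          iv <- pair_lists[[k]][[idx_grid[r, k]]]
          v <- training[[sub[k]]]
          pass <- pass & v >= iv[1] & v <= iv[2]
          constraints[[sub[k]]] <- iv
        }
        m <- literal_mcc(pass)
        if (m > best) {
          best <- m
          best_constraints <- constraints
        }
      }
    }
  }
  list(mcc = best, constraints = best_constraints)
}

# A minimal receptor PDB with one Asp and one Glu carrying carboxylate
# oxygens at known coordinates (synthetic, for testing only).
write_receptor_fixture <- function(path) {
  atom_line <- function(serial, name, res, resno, x, y, z) {
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            serial, name, res, resno, x, y, z, substr(name, 1, 1))
  }
  lines <- c(
    atom_line(1, "CA", "ASP", 94, -2, 0, 0),
    atom_line(2, "CG", "ASP", 94, -1, 0, 0),
    atom_line(3, "OD1", "ASP", 94, 0, 0, 0),
    atom_line(4, "OD2", "ASP", 94, 1.2, 0.8, 0.3),
    atom_line(5, "CA", "GLU", 182, 6, 0, 0),
    atom_line(6, "CD", "GLU", 182, 7, 0.5, 0),
    atom_line(7, "OE1", "GLU", 182, 8.0, 0.5, 0.2),
    atom_line(8, "OE2", "GLU", 182, 8.9, 1.3, 0.6),
    "END"
  )
  writeLines(lines, path)
  path
}

# Single-pose atom tibble with polar atoms at exact minimum distances from
# the two synthetic site residues: probes sit on the x axis outside the
# outermost oxygen of each residue, so the nearest oxygen is the one the
# distance is measured from.
atoms_at_distances <- function(d1, d2) {
  site <- synthetic_reference_site()
  o1 <- site[[1]][1, ]   # lowest-x oxygen of D3.32
  o2 <- site[[2]][2, ]   # highest-x oxygen of E5.46
  tibble::tibble(
    element = c("N", "N", "C"),
    x = c(o1[1] - d1, o2[1] + d2, 20),
    y = c(o1[2], o2[2], 20),
    z = c(o1[3], o2[3], 20),
    is_polar_heavy = c(TRUE, TRUE, FALSE)
  )
}

# Minimal pose tibble around explicit atoms/energies.
make_poses <- function(ids, ee, docked, atoms_list, ranks = NULL) {
  tibble::tibble(
    compound_id = ids,
    pose_rank = ranks %||% rep(1L, length(ids)),
    ee = ee,
    docked_energy = docked,
    atoms = atoms_list
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
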