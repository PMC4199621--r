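# Synthetic inputs with the statistical structure the screening analysis
# assumes: labelled descriptor sets with a planted range rule, and
# docking-pose populations with planted binders. Generators are pure
# functions of their spec (including its seed): identical spec, identical
# output.

# --- descriptor sets --------------------------------------------------------

dist_spec <- function(family = c("normal", "uniform", "categorical"), ...) {
  family <- match.arg(family)
  params <- list(...)
  needed <- switch(family,
    normal = c("mean", "sd"),
    uniform = c("min", "max"),
    categorical = c("values", "prob")
  )
  missing <- setdiff(needed, names(params))
  if (length(missing)) {
    abort(sprintf("Distribution '%s' needs parameter(s): %s.",
                  family, paste(missing, collapse = ", ")))
  }
  c(list(family = family), params)
}

# Defaults emulate the property structure of known hH4R antagonists versus a
# broad screening-library background: actives dominated by net charge +1,
# 3-7 nitrogens, moderate logP, molecular weight centred above 200 Da, low
# fractional negative surface area; decoys broader on every axis.
default_descriptor_dists <- function() {
  list(
    molecular_weight = list(
      active = dist_spec("normal", mean = 280, sd = 60, min = 100),
      decoy = dist_spec("normal", mean = 330, sd = 110, min = 100)
    ),
    total_charge = list(
      active = dist_spec("categorical", values = c(0, 1, 2),
                         prob = c(0.15, 0.80, 0.05)),
      decoy = dist_spec("categorical", values = c(-1, 0, 1, 2),
                        prob = c(0.15, 0.55, 0.25, 0.05))
    ),
    n_nitrogen = list(
      active = dist_spec("categorical", values = 3:7,
                         prob = c(0.20, 0.25, 0.25, 0.20, 0.10)),
      decoy = dist_spec("categorical", values = 0:8,
                        prob = c(0.18, 0.22, 0.20, 0.14, 0.10, 0.07, 0.05,
                                 0.03, 0.01))
    ),
    fasa_neg = list(
      active = dist_spec("normal", mean = 0.30, sd = 0.06, min = 0, max = 1),
      decoy = dist_spec("normal", mean = 0.45, sd = 0.12, min = 0, max = 1)
    ),
    logp = list(
      active = dist_spec("normal", mean = 2.0, sd = 1.2),
      decoy = dist_spec("normal", mean = 2.5, sd = 1.8)
    )
  )
}

#' Specification of a synthetic labelled descriptor set
#'
#' Describes two classes of descriptor vectors (no chemical structures — the
#' range-learning machinery never consults the structure) with a planted
#' range rule: actives satisfy the rule with probability `1 - label_noise`,
#' decoys with probability `decoy_rule_rate`. The defaults emulate the
#' three-rules regime in which 87% of actives and 5% of decoys pass the
#' planted rule.
#'
#' @param n_active,n_decoy Class sizes.
#' @param descriptors Per-descriptor class distributions: a named list whose
#'   elements are `list(active = dist, decoy = dist)` with distributions
#'   built like `list(family = "normal", mean = , sd = , min = , max = )`,
#'   `list(family = "uniform", min = , max = )` or
#'   `list(family = "categorical", values = , prob = )`.
#' @param planted_rule Named list of closed intervals (as in
#'   [range_filter()]) over descriptor names, or `NULL` for no planted rule.
#' @param label_noise Probability an active violates the planted rule.
#' @param decoy_rule_rate Probability a decoy satisfies the planted rule.
#' @param seed Integer seed owned by the spec.
#' @return A `descriptor_set_spec`.
#' @export
descriptor_set_spec <- function(n_active = 1000, n_decoy = 1000,
                                descriptors = default_descriptor_dists(),
                                planted_rule = list(
                                  total_charge = c(1, 1),
                                  n_nitrogen = c(3, 7),
                                  fasa_neg = c(0, 0.42)
                                ),
                                label_noise = 0.13,
                                decoy_rule_rate = 0.05,
                                seed = 1) {
  stopifnot_scalar_number(n_active, "n_active", lower = 1, integerish = TRUE)
  stopifnot_scalar_number(n_decoy, "n_decoy", lower = 1, integerish = TRUE)
  stopifnot_scalar_number(label_noise, "label_noise", lower = 0, upper = 1)
  stopifnot_scalar_number(decoy_rule_rate, "decoy_rule_rate", lower = 0,
                          upper = 1)
  stopifnot_scalar_number(seed, "seed", integerish = TRUE)
  if (!is.null(planted_rule)) {
    unknown <- setdiff(names(planted_rule), names(descriptors))
    if (length(unknown)) {
      abort(sprintf("Planted rule names unknown descriptor(s): %s.",
                    paste(unknown, collapse = ", ")))
    }
  }
  structure(
    list(n_active = as.integer(n_active), n_decoy = as.integer(n_decoy),
         descriptors = descriptors, planted_rule = planted_rule,
         label_noise = label_noise, decoy_rule_rate = decoy_rule_rate,
         seed = as.integer(seed)),
    class = "descriptor_set_spec"
  )
}

# Truncated-normal sampling by inverse CDF (exact, vectorized).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  if (pu <= pl) abort("Empty truncated-normal support.")
  stats::qnorm(runif(n, pl, pu), mean, sd)
}

# Draw n values from a distribution, optionally restricted to a closed
# interval (`inside = TRUE`) or its complement (`inside = FALSE`).
sample_dist <- function(d, n, interval = NULL, inside = TRUE) {
  if (n == 0) return(numeric(0))
  lo <- if (is.null(interval)) -Inf else interval[1]
  hi <- if (is.null(interval)) Inf else interval[2]
  if (d$family == "categorical") {
    values <- d$values
    prob <- d$prob
    keep <- if (is.null(interval)) {
      rep(TRUE, length(values))
    } else if (inside) {
      values >= lo & values <= hi
    } else {
      values < lo | values > hi
    }
    if (!any(keep & prob > 0)) return(NULL)
    sample(values[keep], n, replace = TRUE, prob = prob[keep])
  } else if (d$family == "uniform") {
    a <- d$min; b <- d$max
    if (is.null(interval) || (inside && lo <= a && hi >= b)) {
      return(runif(n, a, b))
    }
    if (inside) {
      a2 <- max(a, lo); b2 <- min(b, hi)
      if (a2 >= b2) return(NULL)
      runif(n, a2, b2)
    } else {
      # complement: mass below lo plus mass above hi
      wl <- max(0, min(b, lo) - a)
      wu <- max(0, b - max(a, hi))
      if (wl + wu <= 0) return(NULL)
      below <- runif(n) < wl / (wl + wu)
      out <- numeric(n)
      out[below] <- runif(sum(below), a, a + wl)
      out[!below] <- runif(sum(!below), b - wu, b)
      out
    }
  } else {
    a <- d$min %||% -Inf
    b <- d$max %||% Inf
    if (is.null(interval)) return(rnorm_trunc(n, d$mean, d$sd, a, b))
    if (inside) {
      a2 <- max(a, lo); b2 <- min(b, hi)
      if (stats::pnorm(b2, d$mean, d$sd) <= stats::pnorm(a2, d$mean, d$sd)) {
        return(NULL)
      }
      rnorm_trunc(n, d$mean, d$sd, a2, b2)
    } else {
      wl <- stats::pnorm(max(a, min(lo, b)), d$mean, d$sd) -
        stats::pnorm(a, d$mean, d$sd)
      wu <- stats::pnorm(b, d$mean, d$sd) -
        stats::pnorm(min(b, max(hi, a)), d$mean, d$sd)
      if (wl + wu <= 0) return(NULL)
      below <- runif(n) < wl / (wl + wu)
      out <- numeric(n)
      if (any(below)) {
        out[below] <- rnorm_trunc(sum(below), d$mean, d$sd, a, min(lo, b))
      }
      if (any(!below)) {
        out[!below] <- rnorm_trunc(sum(!below), d$mean, d$sd, max(hi, a), b)
      }
      out
    }
  }
}

#' Generate a synthetic labelled descriptor set
#'
#' Draws descriptor vectors per class and enforces the planted rule: each
#' active satisfies it with probability `1 - label_noise`, each decoy with
#' probability `decoy_rule_rate`. The ground-truth membership flag is kept in
#' column `in_rule`.
#'
#' @param spec A [descriptor_set_spec()].
#' @return A tibble with `id`, `label`, `in_rule` and one column per
#'   descriptor; bit-identical across calls with the same spec.
#' @export
#' @examples
#' d <- gen_descriptor_set(descriptor_set_spec(n_active = 50, n_decoy = 50,
#'                                             seed = 7))
#' table(d$label, d$in_rule)
gen_descriptor_set <- function(spec) {
  if (!inherits(spec, "descriptor_set_spec")) {
    abort("`spec` must be a descriptor_set_spec.")
  }
  rule <- spec$planted_rule
  with_seed(spec$seed, {
    gen_class <- function(class, n, rate_in) {
      data <- tibble(.rows = n)
      for (d in names(spec$descriptors)) {
        data[[d]] <- sample_dist(spec$descriptors[[d]][[class]], n)
      }
      if (is.null(rule)) {
        data$in_rule <- rep(NA, n)
        return(data)
      }
      target_in <- runif(n) < rate_in
      satisfies <- filter_pass(data, rule)
      # pull records into the rule: resample constrained descriptors inside
      fix_in <- which(target_in & !satisfies)
      for (d in names(rule)) {
        vals <- sample_dist(spec$descriptors[[d]][[class]], length(fix_in),
                            interval = rule[[d]], inside = TRUE)
        if (is.null(vals) && length(fix_in)) {
          abort(sprintf(
            "Planted rule interval for '%s' has no support in class '%s'.",
            d, class))
        }
        data[[d]][fix_in] <- vals
      }
      # push records out of the rule: break one random constrained descriptor
      fix_out <- which(!target_in & satisfies)
      for (i in fix_out) {
        for (d in sample(names(rule))) {
          val <- sample_dist(spec$descriptors[[d]][[class]], 1,
                             interval = rule[[d]], inside = FALSE)
          if (!is.null(val)) {
            data[[d]][i] <- val
            break
          }
        }
      }
      still <- filter_pass(data, rule)
      if (any(still[fix_out])) {
        abort("Planted rule covers the whole support; cannot plant decoys.")
      }
      data$in_rule <- target_in
      data
    }
    actives <- gen_class("active", spec$n_active, 1 - spec$label_noise)
    decoys <- gen_class("decoy", spec$n_decoy, spec$decoy_rule_rate)
    out <- dplyr::bind_rows(
      dplyr::mutate(actives, label = "active"),
      dplyr::mutate(decoys, label = "inactive")
    )
    out$id <- sprintf("syn%05d", seq_len(nrow(out)))
    dplyr::select(out, "id", "label", "in_rule", dplyr::everything())
  })
}

# --- pose sets --------------------------------------------------------------

#' Specification of a synthetic docked-pose population
#'
#' Planted binders receive one polar nitrogen near a carboxylate oxygen of
#' each reference residue (distance drawn from the binder distribution) and
#' a low electrostatic energy; non-binders are placed beyond the non-binder
#' minimum distance with background energies. By construction the binder
#' distance maximum must stay below the non-binder minimum so the planted
#' geometry is separable.
#'
#' @param n_active_compounds,n_reference_compounds Compounds per set (the
#'   docking evaluations used active sets of ~46 against reference sets of
#'   50-137 random compounds).
#' @param p_binder_active,p_binder_reference Probability that a compound of
#'   each set is a planted binder.
#' @param binder_distance,nonbinder_distance Uniform contact-distance ranges
#'   in Angstrom, `c(low, high)`.
#' @param binder_ee,nonbinder_ee Normal electrostatic-energy parameters
#'   `c(mean, sd)` in kcal/mol.
#' @param poses_per_compound Docked poses generated per compound (the
#'   docking protocol kept 16).
#' @param seed Integer seed owned by the spec.
#' @return A `pose_set_spec`.
#' @export
pose_set_spec <- function(n_active_compounds = 46,
                          n_reference_compounds = 137,
                          p_binder_active = 0.2,
                          p_binder_reference = 0.01,
                          binder_distance = c(2.5, 3.8),
                          nonbinder_distance = c(5, 12),
                          binder_ee = c(-4.5, 0.5),
                          nonbinder_ee = c(-0.5, 0.7),
                          poses_per_compound = 16,
                          seed = 1) {
  stopifnot_scalar_number(n_active_compounds, "n_active_compounds", lower = 1,
                          integerish = TRUE)
  stopifnot_scalar_number(n_reference_compounds, "n_reference_compounds",
                          lower = 1, integerish = TRUE)
  stopifnot_scalar_number(p_binder_active, "p_binder_active", lower = 0,
                          upper = 1)
  stopifnot_scalar_number(p_binder_reference, "p_binder_reference", lower = 0,
                          upper = 1)
  stopifnot_scalar_number(poses_per_compound, "poses_per_compound", lower = 1,
                          integerish = TRUE)
  stopifnot_scalar_number(seed, "seed", integerish = TRUE)
  if (binder_distance[2] >= nonbinder_distance[1]) {
    abort("binder_distance high must lie below nonbinder_distance low.")
  }
  structure(
    list(n_active_compounds = as.integer(n_active_compounds),
         n_reference_compounds = as.integer(n_reference_compounds),
         p_binder_active = p_binder_active,
         p_binder_reference = p_binder_reference,
         binder_distance = binder_distance,
         nonbinder_distance = nonbinder_distance,
         binder_ee = binder_ee, nonbinder_ee = nonbinder_ee,
         poses_per_compound = as.integer(poses_per_compound),
         seed = as.integer(seed)),
    class = "pose_set_spec"
  )
}

#' A small synthetic binding-site reference
#'
#' Two carboxylate groups (two oxygens each) standing in for the D3.32 and
#' E5.46 side chains, ~8 Angstrom apart. Synthetic coordinates for testing
#' and simulation; not taken from any receptor model.
#'
#' @return A [reference_site()].
#' @export
synthetic_reference_site <- function() {
  reference_site(list(
    "D3.32" = rbind(c(0, 0, 0), c(1.2, 0.8, 0.3)),
    "E5.46" = rbind(c(8.0, 0.5, 0.2), c(8.9, 1.3, 0.6))
  ))
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Atoms for one pose. Binders put one polar N at the sampled distance from a
# random carboxylate oxygen of each residue; non-binders put their polar
# atoms beyond the sampled clearance from every site oxygen.
pose_atoms <- function(binder, site, spec) {
  all_oxy <- do.call(rbind, unclass(site))
  centroid <- colMeans(all_oxy)
  spread <- max(sqrt(rowSums((all_oxy -
    matrix(centroid, nrow(all_oxy), 3, byrow = TRUE))^2)))
  coords <- list()
  if (binder) {
    for (r in seq_along(site)) {
      oxy <- site[[r]]
      o <- oxy[sample.int(nrow(oxy), 1), ]
      d <- runif(1, spec$binder_distance[1], spec$binder_distance[2])
      coords[[length(coords) + 1L]] <- c(o + d * random_unit_vector(), polar = 1)
    }
  } else {
    for (r in 1:2) {
      d <- runif(1, spec$nonbinder_distance[1], spec$nonbinder_distance[2])
      pos <- centroid + (d + spread) * random_unit_vector()
      coords[[length(coords) + 1L]] <- c(pos, polar = 1)
    }
  }
  # two apolar carbons near the first polar atom
  for (j in 1:2) {
    coords[[length(coords) + 1L]] <-
      c(coords[[1]][1:3] + 1.5 * j * random_unit_vector(), polar = 0)
  }
  m <- do.call(rbind, coords)
  tibble(
    element = ifelse(m[, 4] == 1, "N", "C"),
    x = m[, 1], y = m[, 2], z = m[, 3],
    is_polar_heavy = m[, 4] == 1
  )
}

#' Generate a synthetic docked-pose population
#'
#' For every compound, `poses_per_compound` poses are generated; the pose
#' with the lowest total docked energy (the "best" pose) carries the
#' compound's planted geometry and electrostatic energy, while the remaining
#' poses wander away from the site with background energies.
#'
#' @param spec A [pose_set_spec()].
#' @param site A [reference_site()]; defaults to
#'   [synthetic_reference_site()].
#' @param set `"active"` or `"reference"` — which compound set to generate
#'   (selects the planted binder probability and the id prefix).
#' @return A list: `poses` (a pose tibble as in [read_pose_bundle()]) and
#'   `truth` (tibble `compound_id`, `is_binder`).
#' @export
gen_pose_set <- function(spec, site = synthetic_reference_site(),
                         set = c("active", "reference")) {
  if (!inherits(spec, "pose_set_spec")) abort("`spec` must be a pose_set_spec.")
  set <- match.arg(set)
  n <- if (set == "active") spec$n_active_compounds else
    spec$n_reference_compounds
  p_binder <- if (set == "active") spec$p_binder_active else
    spec$p_binder_reference
  prefix <- if (set == "active") "act" else "ref"
  # offset the reference stream so the two sets are independent draws
  stream_seed <- spec$seed + if (set == "active") 0L else 104729L
  with_seed(stream_seed, {
    rows <- list()
    truth <- logical(n)
    for (i in seq_len(n)) {
      id <- sprintf("%s%04d", prefix, i)
      binder <- runif(1) < p_binder
      truth[i] <- binder
      ee_mean <- if (binder) spec$binder_ee[1] else spec$nonbinder_ee[1]
      ee_sd <- if (binder) spec$binder_ee[2] else spec$nonbinder_ee[2]
      best_rank <- sample.int(spec$poses_per_compound, 1)
      best_energy <- rnorm(1, ee_mean, ee_sd) + rnorm(1, -6, 0.8)
      for (p in seq_len(spec$poses_per_compound)) {
        is_best <- p == best_rank
        ee <- if (is_best) rnorm(1, ee_mean, ee_sd) else
          rnorm(1, spec$nonbinder_ee[1], spec$nonbinder_ee[2])
        docked <- if (is_best) best_energy else
          best_energy + runif(1, 0.1, 3)
        rows[[length(rows) + 1L]] <- tibble(
          compound_id = id, pose_rank = p, ee = ee, docked_energy = docked,
          atoms = list(pose_atoms(binder && is_best, site, spec))
        )
      }
    }
    list(
      poses = dplyr::bind_rows(rows),
      truth = tibble(compound_id = sprintf("%s%04d", prefix, seq_len(n)),
                     is_binder = truth)
    )
  })
}

# --- hard-coded fixtures ----------------------------------------------------

#' Hard-coded fixture molecules
#'
#' A small named set of real structures: JNJ-7777120 (the selective hH4R
#' antagonist used as the reference ligand), protonated histamine, and a few
#' simple molecules exercising descriptor edge cases.
#'
#' @return A tibble with `id`, `smiles`, `label`.
#' @export
fixture_molecules <- function() {
  tibble::tribble(
    ~id,              ~smiles,                                   ~label,
    "jnj7777120",     "CN1CCN(CC1)C(=O)c1cc2cc(Cl)ccc2[nH]1",    "active",
    "histamine_cat",  "[NH3+]CCc1c[nH]cn1",                      "active",
    "methane",        "C",                                       "inactive",
    "benzene",        "c1ccccc1",                                "inactive",
    "acetate",        "CC(=O)[O-]",                              "inactive",
    "imidazole",      "c1c[nH]cn1",                              "inactive"
  )
}

#' Hand-built rule-filter exemplars
#'
#' Ten descriptor vectors with known pass/fail outcomes for each rule filter,
#' covering the inclusive boundaries of the printed rules.
#'
#' @return A tibble with the panel descriptor columns plus logical
#'   `expected_lipinski`, `expected_oprea`, `expected_three_rules`.
#' @export
rule_exemplars <- function() {
  base <- tibble(
    molecular_weight = 300, total_charge = 1, n_nitrogen = 5, n_oxygen = 1,
    n_aromatic_atoms = 6, hbd = 2, hba = 5, logp = 2, n_rings = 2,
    n_rot_bonds = 4, fasa_neg = 0.30
  )
  rows <- list(
    dplyr::mutate(base, expected_lipinski = TRUE, expected_oprea = TRUE,
                  expected_three_rules = TRUE),
    dplyr::mutate(base, total_charge = 0, expected_lipinski = TRUE,
                  expected_oprea = TRUE, expected_three_rules = FALSE),
    dplyr::mutate(base, n_nitrogen = 2, expected_lipinski = TRUE,
                  expected_oprea = TRUE, expected_three_rules = FALSE),
    dplyr::mutate(base, n_nitrogen = 8, expected_lipinski = TRUE,
                  expected_oprea = TRUE, expected_three_rules = FALSE),
    dplyr::mutate(base, n_nitrogen = 7, fasa_neg = 0.42,
                  expected_lipinski = TRUE, expected_oprea = TRUE,
                  expected_three_rules = TRUE),
    dplyr::mutate(base, n_nitrogen = 3, fasa_neg = 0.43,
                  expected_lipinski = TRUE, expected_oprea = TRUE,
                  expected_three_rules = FALSE),
    dplyr::mutate(base, molecular_weight = 500, logp = 5, hbd = 5, hba = 10,
                  expected_lipinski = TRUE, expected_oprea = FALSE,
                  expected_three_rules = TRUE),
    dplyr::mutate(base, molecular_weight = 501, expected_lipinski = FALSE,
                  expected_oprea = FALSE, expected_three_rules = TRUE),
    dplyr::mutate(base, molecular_weight = 450, logp = 4.5, n_rings = 4,
                  n_rot_bonds = 10, hbd = 5, hba = 8,
                  expected_lipinski = TRUE, expected_oprea = TRUE,
                  expected_three_rules = TRUE),
    dplyr::mutate(base, logp = -3.6, expected_lipinski = TRUE,
                  expected_oprea = FALSE, expected_three_rules = TRUE)
  )
  dplyr::bind_rows(rows)
}
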