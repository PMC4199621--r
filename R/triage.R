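# Docking-pose triage: the two consecutive post-docking filters
# (electrostatic-energy cluster membership and carboxylate-contact distance
# scoring), sub-sampled enrichment, and consensus selection.

#' Carboxylate-contact distance score of poses
#'
#' For each pose and each reference residue, a putative interaction is
#' declared when the minimum Euclidean distance between any polar heavy
#' ligand atom (N or O) and any carboxylate oxygen of that residue is
#' strictly below the threshold. The score counts the interacting residues:
#' 0 (no interaction), 1 (one residue), 2 (both).
#'
#' @param poses A pose tibble with an `atoms` list-column (see
#'   [read_pose_bundle()]), or a single per-pose atom tibble.
#' @param site A [reference_site()].
#' @param threshold Distance threshold in Angstrom (default 4; strict `<`).
#' @return For a pose tibble, the tibble with an integer `distance_score`
#'   column; for a single atom tibble, the integer score.
#' @export
distance_score <- function(poses, site, threshold = 4) {
  if (!inherits(site, "reference_site")) {
    abort("`site` must be a reference_site.")
  }
  stopifnot_scalar_number(threshold, "threshold", lower = 0)
  score_one <- function(atoms) {
    polar <- atoms[atoms$is_polar_heavy, , drop = FALSE]
    if (nrow(polar) == 0) return(0L)
    p <- as.matrix(polar[, c("x", "y", "z")])
    sum(vapply(site, function(oxy) {
      d2 <- outer(rowSums(p^2), rowSums(oxy^2), "+") - 2 * p %*% t(oxy)
      sqrt(max(0, min(d2))) < threshold
    }, logical(1)))
  }
  if (is.data.frame(poses) && "atoms" %in% names(poses)) {
    poses$distance_score <- map_int(poses$atoms, score_one)
    poses
  } else if (is.data.frame(poses)) {
    score_one(poses)
  } else {
    abort("`poses` must be a pose tibble or a per-pose atom tibble.")
  }
}

#' Triage docked poses with the two consecutive filters
#'
#' Keeps the best pose per compound, clusters the best-pose electrostatic
#' energies with exact 1-D k-means, scores carboxylate contacts, and applies
#' the conjunction of the two filters (which the docking analysis found to
#' be practically orthogonal): pass iff the pose's energy falls in the
#' allowed lowest cluster(s) and its distance score reaches
#' `min_distance_score`.
#'
#' @param poses A pose tibble ([read_pose_bundle()] / [gen_pose_set()]).
#' @param site A [reference_site()].
#' @param k Number of energy clusters (3 reproduces the observed separation
#'   of docked populations).
#' @param threshold Contact distance threshold, Angstrom.
#' @param ee_mode `"lowest_cluster"` or `"two_lowest_clusters"`.
#' @param min_distance_score Minimum distance score to pass (1 or 2).
#' @param clustering Optional precomputed [kmeans_1d()] clustering (e.g.
#'   boundaries derived on a different pose population); by default derived
#'   from the best poses at hand.
#' @return A verdicts tibble: `compound_id`, `ee`, `ee_cluster` (0 = lowest
#'   energy), `distance_score`, `passed`; the clustering is attached as
#'   attribute `clustering`.
#' @export
pose_triage <- function(poses, site, k = 3, threshold = 4,
                        ee_mode = c("lowest_cluster", "two_lowest_clusters"),
                        min_distance_score = 2, clustering = NULL) {
  ee_mode <- match.arg(ee_mode)
  stopifnot_scalar_number(min_distance_score, "min_distance_score",
                          lower = 0, upper = 2, integerish = TRUE)
  best <- best_pose_per_compound(poses)
  if (is.null(clustering)) clustering <- kmeans_1d(best$ee, k = k)
  best <- distance_score(best, site, threshold)
  verdicts <- tibble(
    compound_id = best$compound_id,
    ee = best$ee,
    ee_cluster = ee_cluster_index(best$ee, clustering),
    distance_score = best$distance_score,
    passed = ee_filter(best$ee, clustering, ee_mode) &
      best$distance_score >= min_distance_score
  )
  attr(verdicts, "clustering") <- clustering
  verdicts
}

#' Apply the combined pose filter to a verdict table
#'
#' Re-derives the pass set from the stored `ee_cluster` and `distance_score`
#' columns under a (possibly different) filter configuration.
#'
#' @param verdicts A verdicts tibble from [pose_triage()].
#' @param ee_mode `"lowest_cluster"` (cluster 0 only) or
#'   `"two_lowest_clusters"` (clusters 0 and 1).
#' @param min_distance_score Minimum distance score.
#' @return The compound ids passing both filters.
#' @export
combined_filter <- function(verdicts,
                            ee_mode = c("lowest_cluster",
                                        "two_lowest_clusters"),
                            min_distance_score = 2) {
  ee_mode <- match.arg(ee_mode)
  check_columns(verdicts, c("compound_id", "ee_cluster", "distance_score"),
                "`verdicts`")
  max_cluster <- if (ee_mode == "lowest_cluster") 0L else 1L
  pass <- verdicts$ee_cluster <= max_cluster &
    verdicts$distance_score >= min_distance_score
  verdicts$compound_id[pass]
}

#' Sub-sampled enrichment of actives over a reference population
#'
#' Mirrors the verification protocol: the reference (random/decoy) verdicts
#' are repeatedly sub-sampled without replacement, the filter pass count is
#' averaged over folds, and the enrichment factor is the active pass
#' percentage divided by the mean reference pass percentage.
#'
#' @param actives,reference Verdict tibbles carrying a logical `passed`
#'   column (see [pose_triage()]), or plain logical vectors.
#' @param folds Number of sub-sampling folds (the docking analyses used 20
#'   and 100).
#' @param subsample_size Compounds drawn per fold (at most the reference
#'   population size); defaults to the full population.
#' @param seed Integer seed for reproducible draws.
#' @return An `enrichment_result` with the pass fractions (percent), the
#'   enrichment factor, and the per-fold pass counts (mean and SD reported
#'   by [glance()]).
#' @export
subsampled_enrichment <- function(actives, reference, folds = 20,
                                  subsample_size = NULL, seed) {
  get_passed <- function(x, name) {
    if (is.data.frame(x)) {
      check_columns(x, "passed", name)
      x$passed
    } else if (is.logical(x)) {
      x
    } else {
      abort(sprintf("%s must be a verdicts tibble or a logical vector.", name))
    }
  }
  active_pass <- get_passed(actives, "`actives`")
  ref_pass <- get_passed(reference, "`reference`")
  stopifnot_scalar_number(folds, "folds", lower = 1, integerish = TRUE)
  if (is.null(subsample_size)) subsample_size <- length(ref_pass)
  stopifnot_scalar_number(subsample_size, "subsample_size", lower = 1,
                          upper = length(ref_pass), integerish = TRUE)
  fold_counts <- with_seed(seed, {
    vapply(seq_len(folds), function(f) {
      sum(ref_pass[sample.int(length(ref_pass), subsample_size)])
    }, numeric(1))
  })
  frac_active <- 100 * mean(active_pass)
  frac_reference <- 100 * mean(fold_counts) / subsample_size
  ef <- if (frac_reference == 0) {
    warn("Mean reference pass rate is 0; enrichment factor is infinite.")
    Inf
  } else {
    frac_active / frac_reference
  }
  structure(
    list(
      frac_active_pass = frac_active,
      frac_reference_pass = frac_reference,
      enrichment_factor = ef,
      folds = tibble(fold = seq_len(folds), n_pass = fold_counts,
                     frac_pass = 100 * fold_counts / subsample_size),
      subsample_size = subsample_size,
      n_active = length(active_pass),
      n_reference = length(ref_pass)
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result: actives %.1f%%, reference %.1f%% (mean of %d folds), EF %.3g>\n",
    x$frac_active_pass, x$frac_reference_pass, nrow(x$folds),
    x$enrichment_factor))
  invisible(x)
}

#' @export
#' @method tidy enrichment_result
tidy.enrichment_result <- function(x, ...) {
  x$folds
}

#' @export
#' @method glance enrichment_result
glance.enrichment_result <- function(x, ...) {
  tibble(
    frac_active_pass = x$frac_active_pass,
    frac_reference_pass = x$frac_reference_pass,
    enrichment_factor = x$enrichment_factor,
    folds = nrow(x$folds),
    fold_mean_pass = mean(x$folds$n_pass),
    fold_sd_pass = sd(x$folds$n_pass)
  )
}

#' Select the consensus library
#'
#' Compounds that pass the docking-pose filters, ordered by their
#' ligand-based MBI rank and truncated to `size` — the intersection of the
#' two screening routes.
#'
#' @param ranked A ranked tibble from [rank_library()] (columns `id`,
#'   `rank`).
#' @param pose_pass Compound ids passing the pose filters (see
#'   [combined_filter()]).
#' @param size Consensus library size (default 11).
#' @return A character vector of compound ids, at most `size` long; a
#'   warning is issued when fewer compounds pass than requested.
#' @export
consensus_select <- function(ranked, pose_pass, size = 11) {
  check_columns(ranked, c("id", "rank"), "`ranked`")
  stopifnot_scalar_number(size, "size", lower = 1, integerish = TRUE)
  passers <- ranked[ranked$id %in% pose_pass, , drop = FALSE]
  passers <- passers[order(passers$rank), , drop = FALSE]
  if (nrow(passers) < size) {
    warn(sprintf("Only %d compound(s) pass both routes; requested %d.",
                 nrow(passers), size))
  }
  head(passers$id, size)
}
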