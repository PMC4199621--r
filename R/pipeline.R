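# End-to-end orchestration of the sequential workflow:
# learn range filters -> MBI-rank the screening library -> focus on the top
# fraction -> triage docked poses -> sub-sampled enrichment -> consensus
# library. All stage inputs here are synthetic (the generators in this
# package); every stage writes its outputs under `out_dir` and the run ends
# with a JSON manifest of inputs, seeds and output checksums.

#' Default pipeline configuration
#'
#' A complete, desk-scale configuration for [run_pipeline()]. Every field
#' can be overridden by supplying a partial configuration; unknown keys are
#' rejected by [validate_config()].
#'
#' @param out_dir Output directory.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(out_dir = tempfile("h4run"), seed = 7) {
  list(
    out_dir = out_dir,
    seed = seed,
    descriptor_set = list(n_active = 200, n_decoy = 2000,
                          label_noise = 0.13, decoy_rule_rate = 0.05),
    split = list(fraction_train = 2 / 3),
    learn = list(bins = 6, sample_size = 300, worst_fraction = 0.1,
                 best_fraction = 0.1, elimination_margin = 0.1,
                 exhaustive_limit = 5000, mcc_floor = 0.6,
                 subset_min = 2, subset_max = 3, max_iterations = 8),
    mbi = list(top_fraction = 0.05),
    poses = list(p_binder_active = 0.2, p_binder_reference = 0.01,
                 n_reference_compounds = 137, poses_per_compound = 16,
                 binder_distance = c(2.5, 3.8), nonbinder_distance = c(5, 12),
                 binder_ee = c(-4.5, 0.5), nonbinder_ee = c(-0.5, 0.7)),
    triage = list(k = 3, threshold = 4, ee_mode = "lowest_cluster",
                  min_distance_score = 2),
    enrichment = list(folds = 100, subsample_size = 137),
    consensus = list(size = 11)
  )
}

# field name -> c(lower, upper, integerish)
PIPELINE_BOUNDS <- list(
  "seed" = c(-Inf, Inf, 1),
  "descriptor_set.n_active" = c(2, Inf, 1),
  "descriptor_set.n_decoy" = c(2, Inf, 1),
  "descriptor_set.label_noise" = c(0, 1, 0),
  "descriptor_set.decoy_rule_rate" = c(0, 1, 0),
  "split.fraction_train" = c(1e-9, 1 - 1e-9, 0),
  "learn.bins" = c(2, Inf, 1),
  "learn.sample_size" = c(1, Inf, 1),
  "learn.worst_fraction" = c(1e-6, 0.5, 0),
  "learn.best_fraction" = c(1e-6, 0.5, 0),
  "learn.elimination_margin" = c(0, 1, 0),
  "learn.exhaustive_limit" = c(1, Inf, 0),
  "learn.mcc_floor" = c(-1, 1, 0),
  "learn.subset_min" = c(1, Inf, 1),
  "learn.subset_max" = c(1, Inf, 1),
  "learn.max_iterations" = c(1, Inf, 1),
  "mbi.top_fraction" = c(1e-9, 1, 0),
  "poses.p_binder_active" = c(0, 1, 0),
  "poses.p_binder_reference" = c(0, 1, 0),
  "poses.n_reference_compounds" = c(1, Inf, 1),
  "poses.poses_per_compound" = c(1, Inf, 1),
  "triage.k" = c(1, Inf, 1),
  "triage.threshold" = c(0, Inf, 0),
  "triage.min_distance_score" = c(0, 2, 1),
  "enrichment.folds" = c(1, Inf, 1),
  "enrichment.subsample_size" = c(1, Inf, 1),
  "consensus.size" = c(1, Inf, 1)
)

#' Validate a pipeline configuration
#'
#' Checks field names, types and bounds of a (possibly partial) pipeline
#' configuration. All problems are collected and reported together.
#'
#' @param config A configuration list, or a path to a JSON file.
#' @return Invisibly `TRUE` when valid; otherwise the character vector of
#'   problems, invisibly, after raising a condition via [rlang::abort()] if
#'   `strict`, or returned visibly when `strict = FALSE`.
#' @param strict Abort on problems (default) or return them.
#' @export
validate_config <- function(config, strict = TRUE) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- default_pipeline_config()
  errors <- character(0)
  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top)) {
    errors <- c(errors, sprintf("Unknown configuration key(s): %s.",
                                paste(unknown_top, collapse = ", ")))
  }
  for (section in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[section]]) && !is.list(config[[section]])) {
      errors <- c(errors, sprintf("Section '%s' must be a list.", section))
      next
    }
    if (!is.list(defaults[[section]])) next
    unknown <- setdiff(names(config[[section]]), names(defaults[[section]]))
    if (length(unknown)) {
      errors <- c(errors, sprintf("Unknown key(s) in '%s': %s.", section,
                                  paste(unknown, collapse = ", ")))
    }
  }
  flat <- function(cfg, prefix = "") {
    out <- list()
    for (nm in names(cfg)) {
      key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      if (is.list(cfg[[nm]])) out <- c(out, flat(cfg[[nm]], key))
      else out[[key]] <- cfg[[nm]]
    }
    out
  }
  values <- flat(config)
  for (key in intersect(names(values), names(PIPELINE_BOUNDS))) {
    b <- PIPELINE_BOUNDS[[key]]
    v <- values[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      errors <- c(errors, sprintf("'%s' must be a single number.", key))
    } else if (v < b[1] || v > b[2]) {
      errors <- c(errors, sprintf("'%s' = %s out of bounds [%s, %s].",
                                  key, v, b[1], b[2]))
    } else if (b[3] == 1 && v != round(v)) {
      errors <- c(errors, sprintf("'%s' must be a whole number.", key))
    }
  }
  if ("triage" %in% names(config) && !is.null(config$triage$ee_mode) &&
      !config$triage$ee_mode %in% c("lowest_cluster", "two_lowest_clusters")) {
    errors <- c(errors,
                "'triage.ee_mode' must be lowest_cluster or two_lowest_clusters.")
  }
  if (length(errors)) {
    if (strict) abort(c("Invalid pipeline configuration.",
                        setNames(errors, rep("x", length(errors)))))
    return(errors)
  }
  invisible(TRUE)
}

merge_config <- function(user, defaults) {
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(user[[nm]]) && is.list(defaults[[nm]])) {
      merge_config(user[[nm]], defaults[[nm]])
    } else {
      user[[nm]]
    }
  }
  defaults
}

#' Run the full synthetic screening pipeline
#'
#' Executes the sequential workflow on synthetic data: generate a labelled
#' descriptor set with a planted rule, split it, learn a filter ensemble by
#' ISE, MBI-rank the held-out screening library, keep the top fraction as
#' the focused set, generate and triage docked poses for the focused set and
#' a random reference set, compute the sub-sampled enrichment factor, and
#' select the consensus library. Each stage writes its outputs to
#' `config$out_dir`; in-progress files carry a `.partial` suffix until the
#' stage completes.
#'
#' @param config A (possibly partial) configuration; see
#'   [default_pipeline_config()]. May also be a path to a JSON file.
#' @return The run manifest (also written as `manifest.json`): stage records
#'   with output paths and MD5 checksums, the effective configuration and
#'   derived seeds.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  validate_config(config)
  cfg <- merge_config(config, default_pipeline_config())
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(descriptors = cfg$seed, split = cfg$seed + 1L,
                learn = cfg$seed + 2L, poses = cfg$seed + 3L,
                enrich = cfg$seed + 4L)
  stages <- list()
  outputs <- character(0)

  run_stage <- function(name, files, fn) {
    message(sprintf("[h4screen] stage %s", name))
    result <- tryCatch(fn(), error = function(e) {
      for (f in files) {
        final <- file.path(cfg$out_dir, f)
        if (file.exists(final)) {
          file.rename(final, paste0(final, ".partial"))
        }
      }
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    paths <- file.path(cfg$out_dir, files)
    stages[[name]] <<- list(outputs = files,
                            md5 = unname(tools::md5sum(paths)))
    outputs <<- c(outputs, paths)
    result
  }

  # 1. synthetic descriptor set
  molecules <- run_stage("descriptors", "descriptors.csv", function() {
    spec <- descriptor_set_spec(
      n_active = cfg$descriptor_set$n_active,
      n_decoy = cfg$descriptor_set$n_decoy,
      label_noise = cfg$descriptor_set$label_noise,
      decoy_rule_rate = cfg$descriptor_set$decoy_rule_rate,
      seed = seeds$descriptors
    )
    d <- gen_descriptor_set(spec)
    readr::write_csv(d, file.path(cfg$out_dir, "descriptors.csv"))
    d
  })

  # 2. stratified split
  split <- run_stage("split", c("train.csv", "test.csv"), function() {
    s <- split_train_test(molecules, cfg$split$fraction_train,
                          seed = seeds$split)
    readr::write_csv(s$train, file.path(cfg$out_dir, "train.csv"))
    readr::write_csv(s$test, file.path(cfg$out_dir, "test.csv"))
    s
  })

  # 3. learn the filter ensemble
  fit <- run_stage("learn", "ensemble.json", function() {
    space <- discretize(split$train, bins = cfg$learn$bins)
    fit <- ise_optimize(
      split$train, space,
      ise_config(sample_size = cfg$learn$sample_size,
                 worst_fraction = cfg$learn$worst_fraction,
                 best_fraction = cfg$learn$best_fraction,
                 elimination_margin = cfg$learn$elimination_margin,
                 exhaustive_limit = cfg$learn$exhaustive_limit,
                 mcc_floor = cfg$learn$mcc_floor,
                 subset_min = cfg$learn$subset_min,
                 subset_max = cfg$learn$subset_max,
                 max_iterations = cfg$learn$max_iterations),
      seed = seeds$learn
    )
    write_ensemble(fit$ensemble, file.path(cfg$out_dir, "ensemble.json"))
    fit
  })

  # 4. MBI-rank the held-out screening library, keep the top fraction
  focused <- run_stage("score", c("ranked.csv", "focused.csv"), function() {
    ranked <- rank_library(split$test, fit$ensemble)
    readr::write_csv(
      ranked[, c("id", "mbi", "n_passed", "rank")],
      file.path(cfg$out_dir, "ranked.csv"))
    n_focus <- max(1L, ceiling(cfg$mbi$top_fraction * nrow(ranked)))
    focused <- head(ranked, n_focus)
    readr::write_csv(
      focused[, c("id", "label", "mbi", "n_passed", "rank")],
      file.path(cfg$out_dir, "focused.csv"))
    focused
  })

  # 5. generate + triage docked poses for focused and reference sets
  verdicts <- run_stage(
    "triage", c("verdicts_focused.csv", "verdicts_reference.csv"), function() {
      site <- synthetic_reference_site()
      pspec <- pose_set_spec(
        n_active_compounds = nrow(focused),
        n_reference_compounds = cfg$poses$n_reference_compounds,
        p_binder_active = cfg$poses$p_binder_active,
        p_binder_reference = cfg$poses$p_binder_reference,
        binder_distance = cfg$poses$binder_distance,
        nonbinder_distance = cfg$poses$nonbinder_distance,
        binder_ee = cfg$poses$binder_ee,
        nonbinder_ee = cfg$poses$nonbinder_ee,
        poses_per_compound = cfg$poses$poses_per_compound,
        seed = seeds$poses
      )
      act <- gen_pose_set(pspec, site, set = "active")
      ref <- gen_pose_set(pspec, site, set = "reference")
      # the active pose set stands for the focused compounds, in rank order
      id_map <- setNames(focused$id,
                         sprintf("act%04d", seq_len(nrow(focused))))
      act$poses$compound_id <- unname(id_map[act$poses$compound_id])
      # boundaries derived on the pooled best-pose population, as in the
      # docking analysis
      pooled <- dplyr::bind_rows(act$poses, ref$poses)
      clustering <- kmeans_1d(best_pose_per_compound(pooled)$ee,
                              k = cfg$triage$k)
      triage_one <- function(poses) {
        pose_triage(poses, site, k = cfg$triage$k,
                    threshold = cfg$triage$threshold,
                    ee_mode = cfg$triage$ee_mode,
                    min_distance_score = cfg$triage$min_distance_score,
                    clustering = clustering)
      }
      v <- list(focused = triage_one(act$poses),
                reference = triage_one(ref$poses),
                clustering = clustering)
      readr::write_csv(v$focused,
                       file.path(cfg$out_dir, "verdicts_focused.csv"))
      readr::write_csv(v$reference,
                       file.path(cfg$out_dir, "verdicts_reference.csv"))
      v
    })

  # 6. sub-sampled enrichment
  enrich <- run_stage("enrich", "enrichment.json", function() {
    er <- subsampled_enrichment(
      verdicts$focused, verdicts$reference,
      folds = cfg$enrichment$folds,
      subsample_size = min(cfg$enrichment$subsample_size,
                           nrow(verdicts$reference)),
      seed = seeds$enrich
    )
    jsonlite::write_json(glance(er), file.path(cfg$out_dir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    er
  })

  # 7. consensus library
  consensus <- run_stage("consensus", "consensus.csv", function() {
    ids <- consensus_select(focused, combined_filter(
      verdicts$focused, ee_mode = cfg$triage$ee_mode,
      min_distance_score = cfg$triage$min_distance_score
    ), size = cfg$consensus$size)
    readr::write_csv(tibble(rank = seq_along(ids), id = ids),
                     file.path(cfg$out_dir, "consensus.csv"))
    ids
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("h4screen")),
    config = cfg,
    seeds = seeds,
    stages = stages,
    enrichment_factor = enrich$enrichment_factor,
    consensus = consensus
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
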