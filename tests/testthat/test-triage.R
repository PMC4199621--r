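# Pose triage: distance scoring, energy filter, combined filter,
# sub-sampled enrichment, consensus selection.

# a clustering stub with prescribed boundaries
stub_clustering <- function(boundaries) {
  k <- length(boundaries) + 1L
  centroids <- if (k == 1) 0 else {
    # any centroids with these midpoints
    c(boundaries[1] - 1, boundaries + c(diff(boundaries) / 2, 1))[1:k]
  }
  structure(list(k = k, centroids = sort(centroids), boundaries = boundaries,
                 assignment = integer(0), sizes = integer(0), sse = 0,
                 values = numeric(0)),
            class = "ee_clustering")
}

test_that("distance scores follow the strict 4-Angstrom contact rule", {
  site <- synthetic_reference_site()
  expect_equal(distance_score(atoms_at_distances(3.2, 3.8), site), 2L)
  expect_equal(distance_score(atoms_at_distances(3.2, 4.5), site), 1L)
  expect_equal(distance_score(atoms_at_distances(4.0, 4.0), site), 0L)
  # a pose with no polar heavy atoms scores 0 even when close
  apolar <- atoms_at_distances(1, 1)
  apolar$is_polar_heavy <- FALSE
  expect_equal(distance_score(apolar, site), 0L)
})

test_that("ee_filter passes by cluster membership under both modes", {
  cl <- stub_clustering(c(-3.16, -1.1))
  expect_true(ee_filter(-5, cl, "lowest_cluster"))
  expect_true(ee_filter(-5, cl, "two_lowest_clusters"))
  expect_false(ee_filter(-2, cl, "lowest_cluster"))
  expect_true(ee_filter(-2, cl, "two_lowest_clusters"))
  expect_false(ee_filter(0, cl, "lowest_cluster"))
  expect_false(ee_filter(0, cl, "two_lowest_clusters"))
})

test_that("distance_score is invariant under rigid motions of pose and site", {
  withr::with_seed(61, {
    site <- synthetic_reference_site()
    for (r in 1:20) {
      atoms <- atoms_at_distances(runif(1, 2, 6), runif(1, 2, 6))
      # random proper rotation via QR of a random matrix
      qr_ <- qr(matrix(rnorm(9), 3))
      R <- qr.Q(qr_)
      if (det(R) < 0) R[, 1] <- -R[, 1]
      t_vec <- rnorm(3, 0, 10)
      rot_atoms <- atoms
      xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R) +
        matrix(t_vec, nrow(atoms), 3, byrow = TRUE)
      rot_atoms$x <- xyz[, 1]; rot_atoms$y <- xyz[, 2]; rot_atoms$z <- xyz[, 3]
      rot_site <- reference_site(lapply(unclass(site), function(m) {
        m %*% t(R) + matrix(t_vec, nrow(m), 3, byrow = TRUE)
      }))
      expect_equal(distance_score(rot_atoms, rot_site),
                   distance_score(atoms, site))
    }
  })
})

test_that("distance_score is monotone non-increasing as the threshold shrinks", {
  site <- synthetic_reference_site()
  withr::with_seed(62, {
    for (r in 1:20) {
      atoms <- atoms_at_distances(runif(1, 1, 8), runif(1, 1, 8))
      thresholds <- sort(runif(5, 0.5, 9), decreasing = TRUE)
      scores <- vapply(thresholds, function(th) {
        distance_score(atoms, site, threshold = th)
      }, integer(1))
      expect_true(all(diff(scores) <= 0))
    }
  })
})

test_that("combined_filter applies the two criteria conjunctively", {
  verdicts <- tibble::tibble(
    compound_id = c("a", "b", "c", "d"),
    ee_cluster = c(0L, 1L, 1L, 2L),
    distance_score = c(2L, 2L, 1L, 2L)
  )
  expect_equal(combined_filter(verdicts, "lowest_cluster", 2), "a")
  expect_equal(combined_filter(verdicts, "two_lowest_clusters", 2),
               c("a", "b"))
  expect_equal(combined_filter(verdicts, "two_lowest_clusters", 1),
               c("a", "b", "c"))
})

test_that("the strict filter's pass set nests inside the permissive one", {
  ps <- gen_pose_set(pose_set_spec(n_active_compounds = 40,
                                   p_binder_active = 0.3, seed = 8))
  v <- pose_triage(ps$poses, synthetic_reference_site(),
                   ee_mode = "lowest_cluster", min_distance_score = 2)
  strict <- combined_filter(v, "lowest_cluster", 2)
  permissive <- combined_filter(v, "two_lowest_clusters", 1)
  expect_true(all(strict %in% permissive))
})

test_that("subsampling the whole population reproduces the plain enrichment factor", {
  actives <- tibble::tibble(passed = c(rep(TRUE, 30), rep(FALSE, 70)))
  reference <- tibble::tibble(passed = c(rep(TRUE, 4), rep(FALSE, 96)))
  er <- subsampled_enrichment(actives, reference, folds = 7, seed = 1)
  expect_equal(er$enrichment_factor, enrichment_factor(30, 4))
  expect_equal(sd(er$folds$n_pass), 0)   # full population, no fold variance
  expect_equal(glance(er)$fold_mean_pass, 4)
})

test_that("sub-sampled enrichment converges to the population EF at many folds", {
  withr::with_seed(71, {
    active_pass <- runif(200) < 0.25
    ref_pass <- runif(1000) < 0.05
  })
  pop_ef <- (100 * mean(active_pass)) / (100 * mean(ref_pass))
  er <- subsampled_enrichment(active_pass, ref_pass, folds = 1000,
                              subsample_size = 137, seed = 2)
  expect_equal(er$enrichment_factor, pop_ef, tolerance = 0.05)
  # reproducible per seed
  er2 <- subsampled_enrichment(active_pass, ref_pass, folds = 1000,
                               subsample_size = 137, seed = 2)
  expect_identical(er$folds, er2$folds)
})

test_that("consensus selection intersects the two routes in MBI order", {
  ranked <- tibble::tibble(id = c("a", "b", "c", "d", "e"), rank = 1:5)
  expect_equal(consensus_select(ranked, c("d", "b", "e"), size = 2),
               c("b", "d"))
  expect_warning(got <- consensus_select(ranked, c("d", "b"), size = 11),
                 "Only 2")
  expect_equal(got, c("b", "d"))
  expect_warning(none <- consensus_select(ranked, character(0), size = 3),
                 "Only 0")
  expect_equal(none, character(0))
  # 30 passers truncate to the 11 best-ranked
  big <- tibble::tibble(id = sprintf("m%02d", 1:40), rank = 1:40)
  sel <- consensus_select(big, big$id[11:40], size = 11)
  expect_equal(sel, sprintf("m%02d", 11:21))
})
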