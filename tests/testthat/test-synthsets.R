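# Synthetic-data generators.

test_that("generators are pure functions of their spec", {
  spec <- descriptor_set_spec(n_active = 100, n_decoy = 100, seed = 12)
  expect_identical(gen_descriptor_set(spec), gen_descriptor_set(spec))
  pspec <- pose_set_spec(n_active_compounds = 5, poses_per_compound = 4,
                         seed = 12)
  p1 <- gen_pose_set(pspec)
  p2 <- gen_pose_set(pspec)
  expect_identical(p1$poses, p2$poses)
  expect_identical(p1$truth, p2$truth)
})

test_that("without noise the planted rule is a perfect classifier", {
  spec <- descriptor_set_spec(n_active = 150, n_decoy = 150,
                              label_noise = 0, decoy_rule_rate = 0, seed = 9)
  d <- gen_descriptor_set(spec)
  f <- evaluate_filter(range_filter(spec$planted_rule), d)
  expect_equal(f$mcc, 1)
  expect_true(all(d$in_rule[d$label == "active"]))
  expect_false(any(d$in_rule[d$label == "inactive"]))
})

test_that("ground-truth flags agree exactly with the planted rule", {
  spec <- descriptor_set_spec(n_active = 300, n_decoy = 300, seed = 4)
  d <- gen_descriptor_set(spec)
  pass <- h4screen:::filter_pass(d, spec$planted_rule)
  expect_identical(pass, d$in_rule)
})

test_that("the default regime reproduces the three-rules MCC of 0.82", {
  mccs <- vapply(1:20, function(s) {
    d <- gen_descriptor_set(descriptor_set_spec(n_active = 1000,
                                                n_decoy = 1000, seed = s))
    evaluate_filter(three_rules_filter(), d)$mcc
  }, numeric(1))
  expect_equal(mean(mccs), 0.82, tolerance = 0.03 / 0.82)
  expect_true(all(abs(mccs - 0.82) < 0.05))
})

test_that("descriptor moments match spec parameters when no rule is planted", {
  spec <- descriptor_set_spec(n_active = 10000, n_decoy = 100,
                              planted_rule = NULL, seed = 77)
  d <- gen_descriptor_set(spec)
  act <- d[d$label == "active", ]
  # unbounded normal descriptor: logP ~ N(2, 1.2)
  se_mean <- 1.2 / sqrt(nrow(act))
  expect_lt(abs(mean(act$logp) - 2), 3 * se_mean)
  # categorical: charge +1 probability 0.80
  se_p <- sqrt(0.8 * 0.2 / nrow(act))
  expect_lt(abs(mean(act$total_charge == 1) - 0.8), 3 * se_p)
})

test_that("planted binders score 2 and non-binders 0 at the 4-Angstrom rule", {
  spec <- pose_set_spec(n_active_compounds = 60, p_binder_active = 0.4,
                        poses_per_compound = 3, seed = 21)
  site <- synthetic_reference_site()
  ps <- gen_pose_set(spec, site)
  best <- distance_score(best_pose_per_compound(ps$poses), site)
  truth <- ps$truth$is_binder[match(best$compound_id, ps$truth$compound_id)]
  expect_equal(best$distance_score == 2L, truth)
  expect_true(all(best$distance_score[!truth] == 0L))
})

test_that("binder and background energies separate around the planted gap", {
  # EE mixture N(-4.5, 0.5) vs N(-0.5, 0.7): the 2-means boundary falls in
  # the gap for essentially every draw
  boundaries <- vapply(1:20, function(s) {
    spec <- pose_set_spec(n_active_compounds = 200, p_binder_active = 0.5,
                          poses_per_compound = 1, seed = s)
    ps <- gen_pose_set(spec)
    kmeans_1d(ps$poses$ee, k = 2)$boundaries
  }, numeric(1))
  expect_gte(mean(boundaries > -3.5 & boundaries < -1.5), 0.95)
})

test_that("infeasible planted rules are fatal", {
  dists <- list(
    x = list(active = list(family = "uniform", min = 0, max = 1),
             decoy = list(family = "uniform", min = 0, max = 1))
  )
  spec <- descriptor_set_spec(n_active = 10, n_decoy = 10,
                              descriptors = dists,
                              planted_rule = list(x = c(5, 6)), seed = 1)
  expect_error(gen_descriptor_set(spec), "no support")
})
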