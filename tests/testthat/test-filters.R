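# MCC, range-filter evaluation, ensembles and their serialization.

test_that("compute_mcc reproduces the worked confusion tables", {
  # class-normalized three-rules table: 87% of actives, 5% of decoys pass
  expect_equal(round(compute_mcc(tp = 87, fn = 13, fp = 5, tn = 95), 2), 0.82)
  expect_equal(compute_mcc(50, 0, 0, 50), 1)
  expect_equal(compute_mcc(0, 50, 50, 0), -1)
  # zero-denominator convention: everything predicted positive
  expect_equal(compute_mcc(50, 0, 50, 0), 0)
  expect_error(compute_mcc(0, 0, 0, 0), "zero")
  expect_error(compute_mcc(0, 0, 5, 5), "positive")
})

test_that("compute_mcc is antisymmetric under class swap", {
  withr::with_seed(11, {
    for (r in 1:100) {
      cnt <- sample(1:50, 4, replace = TRUE)
      m1 <- compute_mcc(cnt[1], cnt[2], cnt[3], cnt[4])
      m2 <- compute_mcc(cnt[3], cnt[4], cnt[1], cnt[2])
      expect_equal(m1, -m2)
    }
  })
})

test_that("range_filter validates its constraints", {
  expect_error(range_filter(list(c(0, 1))), "named")
  expect_error(range_filter(list(x = c(2, 1))), "low <= high")
  expect_error(range_filter(list(x = c(1, 2), x = c(0, 3))), "unique")
  f <- range_filter(list(x = c(0, 1), y = c(-Inf, 5)))
  expect_s3_class(f, "range_filter")
  expect_equal(tidy(f)$descriptor, c("x", "y"))
})

test_that("evaluate_filter computes per-class rates and class-normalized MCC", {
  d <- make_separable_set(n_act = 100, n_inact = 100)
  f <- evaluate_filter(range_filter(list(x = c(2, 4))), d)
  expect_equal(f$stats[["P_A"]], 100)
  expect_equal(f$stats[["P_NA"]], 0)
  expect_equal(f$mcc, 1)
  # degenerate filters
  all_pass <- evaluate_filter(range_filter(list(x = c(-Inf, Inf))), d)
  expect_equal(all_pass$stats[["P_A"]], 100)
  expect_equal(all_pass$stats[["P_NA"]], 100)
  expect_equal(all_pass$mcc, 0)
  none <- evaluate_filter(range_filter(list(x = c(100, 200))), d)
  expect_equal(none$stats[["N_A"]], 100)
  expect_equal(none$stats[["N_NA"]], 100)
  expect_equal(none$mcc, 0)
  expect_error(evaluate_filter(f, d[d$label == "active", ]), "both")
})

test_that("a set built to pass 87%/5% yields the printed MCC 0.82", {
  # deterministic construction: exactly 87 of 100 actives and 5 of 100
  # decoys inside the rule interval
  d <- tibble::tibble(
    label = rep(c("active", "inactive"), each = 100),
    x = c(rep(3, 87), rep(10, 13), rep(3, 5), rep(10, 95))
  )
  f <- evaluate_filter(range_filter(list(x = c(2, 4))), d)
  expect_equal(f$stats[["P_A"]], 87)
  expect_equal(f$stats[["P_NA"]], 5)
  expect_equal(round(f$mcc, 2), 0.82)
})

test_that("widening any interval never decreases the pass rates", {
  d <- make_separable_set(n_act = 80, n_inact = 80, seed = 9)
  base <- evaluate_filter(range_filter(list(x = c(2.5, 3.5))), d)
  withr::with_seed(10, {
    for (r in 1:50) {
      lo <- 2.5 - runif(1, 0, 2)
      hi <- 3.5 + runif(1, 0, 2)
      wider <- evaluate_filter(range_filter(list(x = c(lo, hi))), d)
      expect_gte(wider$stats[["P_A"]], base$stats[["P_A"]])
      expect_gte(wider$stats[["P_NA"]], base$stats[["P_NA"]])
    }
  })
})

test_that("raw-count MCC differs from class-normalized on imbalanced sets", {
  d <- make_separable_set(n_act = 20, n_inact = 200, seed = 2)
  # a filter with some false positives
  f_norm <- evaluate_filter(range_filter(list(x = c(2, 4.5))), d)
  f_raw <- evaluate_filter(range_filter(list(x = c(2, 4.5))), d,
                           mcc_type = "raw")
  expect_false(isTRUE(all.equal(f_norm$mcc, f_raw$mcc)))
})

test_that("ensembles serialize to JSON and back unchanged", {
  d <- make_separable_set()
  f1 <- evaluate_filter(range_filter(list(x = c(2, 4))), d)
  f2 <- evaluate_filter(range_filter(list(x = c(-Inf, 4))), d)
  ens <- filter_ensemble(list(f1, f2))
  expect_equal(ens$n, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(back$n, 2)
  for (i in 1:2) {
    expect_equal(back$filters[[i]]$constraints, ens$filters[[i]]$constraints)
    expect_equal(back$filters[[i]]$stats, ens$filters[[i]]$stats)
    expect_equal(back$filters[[i]]$mcc, ens$filters[[i]]$mcc)
  }
  expect_error(filter_ensemble(list()), "at least one")
  expect_error(filter_ensemble(list(range_filter(list(x = c(0, 1))))),
               "evaluated")
})
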