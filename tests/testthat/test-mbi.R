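# Molecular Bioactivity Index scoring, ranking, enrichment.

# an evaluated filter with prescribed stats, constraining descriptor `d`
stub_filter <- function(d, iv, P_A, P_NA) {
  range_filter(setNames(list(iv), d),
               stats = c(P_A = P_A, P_NA = P_NA,
                         N_A = 100 - P_A, N_NA = 100 - P_NA),
               mcc = 0.7)
}

test_that("MBI matches hand evaluation of the scoring formula", {
  # single filter with efficiency ratio P_A/P_NA = 10; molecule passes
  f <- stub_filter("x", c(0, 5), P_A = 90, P_NA = 9)
  d_pass <- tibble::tibble(id = "m1", x = 3)
  expect_equal(mbi_score(d_pass, filter_ensemble(list(f)))$mbi, 10)
  # single filter with N_NA/N_A = 9; molecule fails
  f2 <- stub_filter("x", c(0, 5), P_A = 90, P_NA = 10)  # N_NA/N_A = 90/10
  d_fail <- tibble::tibble(id = "m1", x = 7)
  expect_equal(mbi_score(d_fail, filter_ensemble(list(f2)))$mbi, -9)
  # two filters: pass one with ratio 8, fail one with fail-ratio 4
  fa <- stub_filter("x", c(0, 5), P_A = 80, P_NA = 10)   # pass ratio 8
  fb <- stub_filter("y", c(0, 1), P_A = 80, P_NA = 20)   # N_NA/N_A = 80/20 = 4
  d2 <- tibble::tibble(id = "m1", x = 3, y = 2)
  expect_equal(mbi_score(d2, filter_ensemble(list(fa, fb)))$mbi, (8 - 4) / 2)
  expect_equal(mbi_score(d2, filter_ensemble(list(fa, fb)))$n_passed, 1L)
})

test_that("the epsilon floor caps ratios when a filter has no false positives", {
  f <- stub_filter("x", c(0, 5), P_A = 90, P_NA = 0)
  d <- tibble::tibble(id = "m1", x = 3)
  expect_equal(mbi_score(d, filter_ensemble(list(f)))$mbi, 90 / 0.5)
})

test_that("rank_library is a deterministic permutation with documented tie-breaks", {
  f1 <- stub_filter("x", c(0, 5), 90, 9)
  f2 <- stub_filter("y", c(0, 5), 80, 10)
  ens <- filter_ensemble(list(f1, f2))
  d <- tibble::tibble(
    id = c("b", "a", "c", "d"),
    x = c(3, 3, 10, 3),
    y = c(3, 3, 10, 10)
  )
  ranked <- rank_library(d, ens)
  expect_setequal(ranked$id, d$id)
  expect_equal(ranked$rank, 1:4)
  # a and b pass everything and tie -> id order
  expect_equal(ranked$id[1:2], c("a", "b"))
  # d passes one filter, c none
  expect_equal(ranked$id[3:4], c("d", "c"))
})

test_that("MBI strictly increases when a single filter flips from fail to pass", {
  withr::with_seed(77, {
    for (r in 1:100) {
      n <- sample(2:6, 1)
      filters <- lapply(seq_len(n), function(i) {
        stub_filter("x", c(0, 1), P_A = runif(1, 40, 99),
                    P_NA = runif(1, 1, 40))
      })
      ens <- filter_ensemble(filters)
      pass <- runif(n) < 0.5
      if (all(pass)) next
      failed <- which(!pass)
      flip <- if (length(failed) == 1) failed else sample(failed, 1)
      pass2 <- pass
      pass2[flip] <- TRUE
      expect_gt(h4screen:::mbi_from_pass(pass2, ens),
                h4screen:::mbi_from_pass(pass, ens))
    }
  })
})

test_that("enrichment factors reproduce the published verification values", {
  expect_equal(signif(enrichment_factor(62.9, 4.3), 3), 14.6)
  expect_equal(signif(enrichment_factor(14.8, 0.9), 3), 16.4)
  expect_equal(signif(enrichment_factor(24.1, 4.4), 3), 5.48)
  expect_equal(signif(enrichment_factor(7.7, 0.7), 3), 11)
  expect_equal(enrichment_factor(37.2, 37.2), 1)
  expect_warning(ef0 <- enrichment_factor(10, 0), "infinite")
  expect_identical(ef0, Inf)
})

test_that("enrichment_factor(a, b) * enrichment_factor(b, a) = 1", {
  withr::with_seed(13, {
    for (r in 1:50) {
      ab <- runif(2, 0.1, 100)
      expect_equal(enrichment_factor(ab[1], ab[2]) *
                     enrichment_factor(ab[2], ab[1]), 1)
    }
  })
})

test_that("enrichment curves behave for perfect, random and inverted rankings", {
  n <- 1000
  n_act <- 100
  labels <- setNames(rep(c("active", "inactive"), c(n_act, n - n_act)),
                     sprintf("m%04d", 1:n))
  perfect <- tibble::tibble(id = names(labels))
  cv <- enrichment_curve(perfect, labels)
  expect_equal(cv$frac_actives[n_act], 1)           # all found at prevalence
  expect_equal(cv$frac_actives[n], 1)
  expect_true(all(diff(cv$frac_actives) >= 0))

  withr::with_seed(55, {
    rnd <- tibble::tibble(id = sample(names(labels)))
  })
  cv_rnd <- enrichment_curve(rnd, labels)
  # random ranking tracks the diagonal within binomial error
  mid <- which.min(abs(cv_rnd$frac_screened - 0.5))
  se <- sqrt(0.5 * 0.5 / n_act)
  expect_lt(abs(cv_rnd$frac_actives[mid] - 0.5), 4 * se)

  inverted <- tibble::tibble(id = rev(names(labels)))
  cv_inv <- enrichment_curve(inverted, labels)
  before_tail <- cv_inv$frac_screened <= (n - n_act) / n
  expect_true(all(cv_inv$frac_actives[before_tail] <=
                    cv_inv$frac_screened[before_tail]))
  expect_error(enrichment_curve(perfect, labels[-1]), "no label")
})

test_that("perfect ranking maximizes the enrichment AUC over all label orders", {
  n <- 8
  n_act <- 3
  ids <- letters[1:n]
  perfect_labels <- rep(c("active", "inactive"), c(n_act, n - n_act))
  best_auc <- enrichment_auc(enrichment_curve(
    tibble::tibble(id = ids), setNames(perfect_labels, ids)))
  # exhaust every distinct arrangement of labels over ranks
  positions <- utils::combn(n, n_act, simplify = FALSE)
  for (pos in positions) {
    lab <- rep("inactive", n)
    lab[pos] <- "active"
    auc <- enrichment_auc(enrichment_curve(
      tibble::tibble(id = ids), setNames(lab, ids)))
    expect_lte(auc, best_auc + 1e-12)
  }
})

test_that("ensemble ranking captures most planted actives in the top decile", {
  train <- gen_descriptor_set(descriptor_set_spec(n_active = 300,
                                                  n_decoy = 3000, seed = 42))
  space <- discretize(train, bins = 6)
  fit <- ise_optimize(
    train, space,
    ise_config(sample_size = 300, subset_min = 2, subset_max = 3,
               exhaustive_limit = 5000, max_iterations = 8),
    seed = 44
  )
  library_set <- gen_descriptor_set(descriptor_set_spec(n_active = 50,
                                                        n_decoy = 950,
                                                        seed = 7))
  ranked <- rank_library(library_set, fit$ensemble)
  top_decile <- head(ranked, ceiling(0.1 * nrow(ranked)))
  recovery <- sum(top_decile$label == "active") /
    sum(ranked$label == "active")
  expect_gte(recovery, 0.8)
})
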