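# Circular fingerprints, Tanimoto similarity, diversity filtering.

test_that("tanimoto obeys its definition on explicit bit sets", {
  fp <- function(bits, w = 16L) structure(as.integer(bits), bit_width = w)
  expect_equal(tanimoto(fp(c(1, 2, 3)), fp(c(1, 2, 3))), 1)
  expect_equal(tanimoto(fp(c(1, 2)), fp(c(5, 6))), 0)
  expect_equal(tanimoto(fp(c(1, 2, 3)), fp(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(fp(integer(0)), fp(integer(0))), 0)
  expect_error(tanimoto(fp(1, w = 16L), fp(1, w = 32L)), "bit width")
})

test_that("tanimoto is symmetric, bounded, and 1 iff identical non-empty sets", {
  fp <- function(bits) structure(sort(unique(as.integer(bits))),
                                 bit_width = 64L)
  withr::with_seed(101, {
    for (r in 1:200) {
      a <- fp(sample(0:63, sample(0:12, 1)))
      b <- fp(sample(0:63, sample(0:12, 1)))
      s <- tanimoto(a, b)
      expect_identical(s, tanimoto(b, a))
      expect_gte(s, 0)
      expect_lte(s, 1)
      if (length(a) || length(b)) {
        expect_equal(s == 1, identical(a, b))
      }
    }
  })
})

test_that("the same structure gives the same fingerprint regardless of atom order", {
  a <- morgan_fingerprint("OCC")     # ethanol, O first
  b <- morgan_fingerprint("CCO")     # ethanol, O last
  expect_identical(a, b)
  expect_equal(tanimoto(a, b), 1)
  other <- morgan_fingerprint("c1ccccc1")
  expect_lt(tanimoto(a, other), 1)
})

test_that("diversity filter removes duplicates and respects S = 1", {
  mols <- tibble::tibble(
    id = c("a", "a_dup", "b"),
    smiles = c("CCO", "OCC", "c1ccccc1")
  )
  kept <- diversity_filter(mols, threshold = 0.7)
  expect_equal(kept$id, c("a", "b"))
  kept_all <- diversity_filter(mols[c(1, 3), ], threshold = 1.0)
  expect_equal(nrow(kept_all), 2)
})

test_that("greedy leader selection matches a hand-simulated pass on a known matrix", {
  n <- 10
  withr::with_seed(7, {
    sim <- matrix(runif(n * n, 0, 0.9), n, n)
    sim <- (sim + t(sim)) / 2
    diag(sim) <- 1
  })
  mols <- tibble::tibble(id = sprintf("m%02d", 1:n), smiles = NA_character_)
  threshold <- 0.6
  # independent greedy pass
  expected <- integer(0)
  for (i in 1:n) {
    if (!length(expected) || all(sim[i, expected] < threshold)) {
      expected <- c(expected, i)
    }
  }
  kept <- diversity_filter(mols, threshold = threshold, similarity = sim)
  expect_equal(kept$id, mols$id[expected])
  # every discarded molecule is dominated by some retained leader
  discarded <- setdiff(1:n, expected)
  for (i in discarded) {
    expect_true(any(sim[i, expected] >= threshold))
  }
})

test_that("appending molecules dominated by retained leaders leaves the output unchanged", {
  n <- 6
  withr::with_seed(21, {
    sim <- matrix(runif(n * n, 0, 0.5), n, n)
    sim <- (sim + t(sim)) / 2
    diag(sim) <- 1
  })
  mols <- tibble::tibble(id = sprintf("m%d", 1:n), smiles = NA_character_)
  kept <- diversity_filter(mols, threshold = 0.6, similarity = sim)
  # append a copy of the first retained leader (similarity 1 to it)
  sim2 <- rbind(cbind(sim, sim[, 1]), c(sim[1, ], 1))
  mols2 <- dplyr::bind_rows(mols, tibble::tibble(id = "extra",
                                                 smiles = NA_character_))
  kept2 <- diversity_filter(mols2, threshold = 0.6, similarity = sim2)
  expect_equal(kept2$id, kept$id)
})
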