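# Iterative Stochastic Elimination over descriptor-range filters.
#
# The search space is combinatorial: a candidate filter picks a subset of
# descriptors and, for each, a (low, high) pair of interval edges from the
# discretized space. ISE repeatedly (1) samples random filters, (2) scores
# them by class-normalized MCC on the training set, (3) compares how often
# each edge value occurs among the worst versus the best scored filters, and
# (4) eliminates edge values over-represented in the worst; when the
# remaining space is small enough it is searched exhaustively. Besides the
# best filter, every distinct filter scoring at least `mcc_floor` is retained
# as an "efficient filter" for the ensemble.

#' ISE tuning parameters
#'
#' @param sample_size Random filters drawn per iteration.
#' @param worst_fraction,best_fraction Fractions of the scored sample that
#'   define the "worst" and "best" groups for the elimination contrast.
#' @param elimination_margin An edge value is eliminated when its frequency
#'   among the worst filters exceeds its frequency among the best by more
#'   than this margin.
#' @param exhaustive_limit When the remaining space holds at most this many
#'   filters it is enumerated exhaustively.
#' @param mcc_floor Minimum MCC for a filter to enter the ensemble of
#'   efficient filters (the learned hH4R filters spanned MCC 0.6-0.87).
#' @param subset_min,subset_max Bounds on the number of descriptors a
#'   candidate filter constrains (capped at the number of usable
#'   descriptors).
#' @param max_iterations Iteration cap; reaching it returns the best filter
#'   found so far without the exhaustive phase.
#' @return A list of class `ise_config`.
#' @export
ise_config <- function(sample_size = 1000, worst_fraction = 0.1,
                       best_fraction = 0.1, elimination_margin = 0.1,
                       exhaustive_limit = 1e5, mcc_floor = 0.6,
                       subset_min = 3, subset_max = 6, max_iterations = 50) {
  stopifnot_scalar_number(sample_size, "sample_size", lower = 1,
                          integerish = TRUE)
  stopifnot_scalar_number(worst_fraction, "worst_fraction", lower = 1e-6,
                          upper = 0.5)
  stopifnot_scalar_number(best_fraction, "best_fraction", lower = 1e-6,
                          upper = 0.5)
  stopifnot_scalar_number(elimination_margin, "elimination_margin",
                          lower = 0, upper = 1)
  stopifnot_scalar_number(exhaustive_limit, "exhaustive_limit", lower = 1)
  stopifnot_scalar_number(mcc_floor, "mcc_floor", lower = -1, upper = 1)
  stopifnot_scalar_number(subset_min, "subset_min", lower = 1,
                          integerish = TRUE)
  stopifnot_scalar_number(subset_max, "subset_max", lower = subset_min,
                          integerish = TRUE)
  stopifnot_scalar_number(max_iterations, "max_iterations", lower = 1,
                          integerish = TRUE)
  structure(
    list(sample_size = as.integer(sample_size),
         worst_fraction = worst_fraction, best_fraction = best_fraction,
         elimination_margin = elimination_margin,
         exhaustive_limit = exhaustive_limit, mcc_floor = mcc_floor,
         subset_min = as.integer(subset_min),
         subset_max = as.integer(subset_max),
         max_iterations = as.integer(max_iterations)),
    class = "ise_config"
  )
}

# --- internal search-space bookkeeping --------------------------------------

# Valid (low, high) edge-index pairs per descriptor given admissible sets.
valid_pairs <- function(low_idx, high_idx) {
  if (!length(low_idx) || !length(high_idx)) {
    return(matrix(integer(0), ncol = 2))
  }
  grid <- expand.grid(low = low_idx, high = high_idx)
  as.matrix(grid[grid$high > grid$low, , drop = FALSE])
}

# Elementary symmetric sums e_1..e_max of `values`; used to count filters.
elementary_symmetric <- function(values, max_order) {
  e <- numeric(max_order + 1)
  e[1] <- 1
  for (v in values) {
    upper <- min(max_order, length(values))
    for (k in rev(seq_len(upper))) {
      e[k + 1] <- e[k + 1] + v * e[k]
    }
  }
  e[-1]
}

# Total filters in the current space for subset sizes smin..smax.
space_size <- function(pair_counts, smin, smax) {
  usable <- pair_counts[pair_counts > 0]
  if (!length(usable)) return(0)
  smax <- min(smax, length(usable))
  if (smax < 1) return(0)
  smin <- min(smin, smax)
  sum(elementary_symmetric(usable, smax)[smin:smax])
}

# Fast per-filter evaluation against a prepared training set.
make_scorer <- function(training) {
  is_active <- training$label == "active"
  n_act <- sum(is_active)
  n_inact <- sum(!is_active)
  if (n_act == 0 || n_inact == 0) {
    abort("Training data must contain both classes.")
  }
  cols <- as.list(training[setdiff(names(training), "label")])
  function(constraints) {
    pass <- TRUE
    for (d in names(constraints)) {
      iv <- constraints[[d]]
      v <- cols[[d]]
      pass <- pass & (v >= iv[1] & v <= iv[2])
    }
    if (isTRUE(pass)) pass <- rep(TRUE, n_act + n_inact)
    p_a <- 100 * sum(pass & is_active) / n_act
    p_na <- 100 * sum(pass & !is_active) / n_inact
    mcc <- compute_mcc(tp = p_a, fn = 100 - p_a, fp = p_na, tn = 100 - p_na)
    list(stats = c(P_A = p_a, P_NA = p_na, N_A = 100 - p_a, N_NA = 100 - p_na),
         mcc = mcc)
  }
}

constraint_signature <- function(constraints) {
  ord <- order(names(constraints))
  paste(vapply(ord, function(k) {
    sprintf("%s:%g:%g", names(constraints)[k],
            constraints[[k]][1], constraints[[k]][2])
  }, character(1)), collapse = ";")
}

#' Learn range filters by Iterative Stochastic Elimination
#'
#' Searches the discretized space of descriptor-range filters for the
#' conjunction maximizing the class-normalized MCC on the training set, and
#' collects the ensemble of distinct "efficient filters" scoring at least
#' `config$mcc_floor`. See [ise_config()] for the algorithm parameters.
#'
#' @param training A labelled descriptor tibble (`label` column plus the
#'   descriptors of `space`).
#' @param space A [discretize()]d space.
#' @param config An [ise_config()].
#' @param seed Integer seed; runs are reproducible for a fixed seed.
#' @return An `ise_result`: `best` (the highest-MCC [range_filter()]),
#'   `ensemble` (a [filter_ensemble()] of efficient filters, always
#'   containing `best`), `trace` (per-iteration tibble) and `exhaustive`
#'   (whether the final phase enumerated the remaining space).
#' @export
ise_optimize <- function(training, space, config = ise_config(), seed) {
  if (!inherits(space, "discretized_space")) {
    abort("`space` must be a discretized_space.")
  }
  if (!inherits(config, "ise_config")) {
    abort("`config` must be an ise_config.")
  }
  descriptors <- setdiff(names(space$cutpoints), space$flagged)
  if (!length(descriptors)) {
    abort("Discretized space is degenerate: no non-constant descriptors.")
  }
  check_columns(training, c("label", descriptors), "`training`")
  scorer <- make_scorer(training[, c("label", descriptors)])
  edges <- space$edges[descriptors]

  low_adm <- map(edges, function(e) seq_len(length(e) - 1L))
  high_adm <- map(edges, function(e) seq(2L, length(e)))

  seen <- new.env(parent = emptyenv())
  best <- NULL
  record <- function(constraints, score) {
    f <- range_filter(constraints, stats = score$stats, mcc = score$mcc)
    if (is.null(best) || f$mcc > best$mcc) best <<- f
    if (f$mcc >= config$mcc_floor) {
      sig <- constraint_signature(constraints)
      if (is.null(seen[[sig]])) seen[[sig]] <- f
    }
    f$mcc
  }
  constraints_from <- function(desc, pair_idx, pairs_by_desc) {
    constraints <- list()
    for (k in seq_along(desc)) {
      d <- desc[k]
      pr <- pairs_by_desc[[d]][pair_idx[k], ]
      constraints[[d]] <- c(edges[[d]][pr[1]], edges[[d]][pr[2]])
    }
    constraints
  }

  trace <- list()
  exhaustive_done <- FALSE

  with_seed(seed, {
    for (iter in seq_len(config$max_iterations)) {
      pairs_by_desc <- map(
        setNames(descriptors, descriptors),
        function(d) valid_pairs(low_adm[[d]], high_adm[[d]])
      )
      pair_counts <- map_dbl(pairs_by_desc, nrow)
      usable <- descriptors[pair_counts > 0]
      if (!length(usable)) {
        abort(c("ISE eliminated the whole search space.",
                i = sprintf("Completed %d iteration(s); see trace.", iter - 1L)))
      }
      size <- space_size(pair_counts, config$subset_min, config$subset_max)

      if (size <= config$exhaustive_limit) {
        smax <- min(config$subset_max, length(usable))
        smin <- min(config$subset_min, smax)
        for (s in smin:smax) {
          subsets <- utils::combn(usable, s, simplify = FALSE)
          for (sub in subsets) {
            counts <- pair_counts[sub]
            if (any(counts == 0)) next
            grid <- do.call(expand.grid, lapply(counts, seq_len))
            for (r in seq_len(nrow(grid))) {
              constraints <- constraints_from(sub, as.integer(grid[r, ]),
                                              pairs_by_desc)
              record(constraints, scorer(constraints))
            }
          }
        }
        exhaustive_done <- TRUE
        trace[[length(trace) + 1L]] <- tibble(
          iteration = iter, phase = "exhaustive", space_size = size,
          n_eliminated = 0L, best_mcc = best$mcc
        )
        break
      }

      # sampling phase
      smax <- min(config$subset_max, length(usable))
      smin <- min(config$subset_min, smax)
      sampled <- vector("list", config$sample_size)
      mccs <- numeric(config$sample_size)
      for (k in seq_len(config$sample_size)) {
        s <- if (smin == smax) smin else sample(smin:smax, 1L)
        desc <- sample(usable, s)
        pair_idx <- vapply(desc, function(d) {
          sample.int(nrow(pairs_by_desc[[d]]), 1L)
        }, integer(1))
        constraints <- constraints_from(desc, pair_idx, pairs_by_desc)
        mccs[k] <- record(constraints, scorer(constraints))
        sampled[[k]] <- list(desc = desc, pair_idx = pair_idx)
      }

      ord <- order(mccs)
      n_worst <- max(1L, ceiling(config$worst_fraction * config$sample_size))
      n_best <- max(1L, ceiling(config$best_fraction * config$sample_size))
      worst <- sampled[ord[seq_len(n_worst)]]
      top <- sampled[ord[seq(length(ord) - n_best + 1L, length(ord))]]

      value_freq <- function(group) {
        tab <- new.env(parent = emptyenv())
        for (f in group) {
          for (k in seq_along(f$desc)) {
            d <- f$desc[k]
            pr <- pairs_by_desc[[d]][f$pair_idx[k], ]
            for (key in c(sprintf("%s|low|%d", d, pr[1]),
                          sprintf("%s|high|%d", d, pr[2]))) {
              tab[[key]] <- (tab[[key]] %||% 0) + 1
            }
          }
        }
        tab
      }
      freq_worst <- value_freq(worst)
      freq_best <- value_freq(top)

      n_elim <- 0L
      for (key in ls(freq_worst)) {
        margin <- freq_worst[[key]] / n_worst -
          (freq_best[[key]] %||% 0) / n_best
        if (margin > config$elimination_margin) {
          parts <- strsplit(key, "|", fixed = TRUE)[[1]]
          d <- parts[1]; side <- parts[2]; v <- as.integer(parts[3])
          if (side == "low" && v %in% low_adm[[d]]) {
            low_adm[[d]] <- setdiff(low_adm[[d]], v)
            n_elim <- n_elim + 1L
          } else if (side == "high" && v %in% high_adm[[d]]) {
            high_adm[[d]] <- setdiff(high_adm[[d]], v)
            n_elim <- n_elim + 1L
          }
        }
      }
      trace[[length(trace) + 1L]] <- tibble(
        iteration = iter, phase = "sample", space_size = size,
        n_eliminated = n_elim, best_mcc = best$mcc
      )
    }
  })

  efficient <- mget(ls(seen), envir = seen)
  sigs <- map_chr(efficient, function(f) constraint_signature(f$constraints))
  best_sig <- constraint_signature(best$constraints)
  if (!(best_sig %in% sigs)) efficient <- c(efficient, list(best))
  ord <- order(map_dbl(efficient, "mcc"), decreasing = TRUE)
  structure(
    list(
      best = best,
      ensemble = filter_ensemble(unname(efficient[ord])),
      trace = dplyr::bind_rows(trace),
      exhaustive = exhaustive_done,
      config = config
    ),
    class = "ise_result"
  )
}

#' @export
print.ise_result <- function(x, ...) {
  cat(sprintf("<ise_result: best MCC %.3f, %d efficient filter(s), %s>\n",
              x$best$mcc, x$ensemble$n,
              if (x$exhaustive) "exhaustive final phase" else "sampling only"))
  print(x$best)
  invisible(x)
}

#' @export
#' @method tidy ise_result
tidy.ise_result <- function(x, ...) {
  tidy(x$ensemble)
}

#' @export
#' @method glance ise_result
glance.ise_result <- function(x, ...) {
  tibble(
    best_mcc = x$best$mcc,
    n_efficient = x$ensemble$n,
    iterations = nrow(x$trace),
    exhaustive = x$exhaustive
  )
}
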