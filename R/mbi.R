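# Molecular Bioactivity Index: ensemble scoring, library ranking, enrichment.
#
# For an ensemble of n filters, each filter i carries per-class percentages
# P_Ai (actives passing), P_NAi (non-actives passing), N_Ai, N_NAi. A
# molecule's MBI is the mean over filters of a signed efficiency ratio:
# passing filter i contributes +P_Ai/P_NAi (the filter's efficiency factor
# for bioactives); failing it contributes -N_NAi/N_Ai (the reciprocal of its
# misidentification factor, penalizing failure of a filter that recognizes
# non-actives well). Denominators are floored at `eps` percentage points so a
# perfect filter on the training set cannot produce an infinite score.

MBI_EPS <- 0.5

# Per-filter pass and fail contributions, given an ensemble.
mbi_weights <- function(ensemble, eps = MBI_EPS) {
  pass_w <- map_dbl(ensemble$filters, function(f) {
    f$stats[["P_A"]] / max(f$stats[["P_NA"]], eps)
  })
  fail_w <- map_dbl(ensemble$filters, function(f) {
    f$stats[["N_NA"]] / max(f$stats[["N_A"]], eps)
  })
  list(pass = pass_w, fail = fail_w)
}

# MBI from a logical pass vector over the ensemble's filters.
mbi_from_pass <- function(pass, ensemble, eps = MBI_EPS) {
  w <- mbi_weights(ensemble, eps)
  sum(ifelse(pass, w$pass, -w$fail)) / ensemble$n
}

#' Score molecules with the Molecular Bioactivity Index
#'
#' @param data A descriptor tibble with an `id` column and the descriptor
#'   columns the ensemble's filters constrain.
#' @param ensemble A [filter_ensemble()] of evaluated filters.
#' @param eps Floor (percentage points) applied to the ratio denominators
#'   `P_NA` and `N_A`.
#' @return `data` with numeric `mbi` and integer `n_passed` columns.
#' @export
#' @examples
#' f <- range_filter(list(x = c(0, 5)),
#'                   stats = c(P_A = 90, P_NA = 9, N_A = 10, N_NA = 91),
#'                   mcc = 0.8)
#' mbi_score(tibble::tibble(id = "m1", x = 3), filter_ensemble(list(f)))
mbi_score <- function(data, ensemble, eps = MBI_EPS) {
  if (!inherits(ensemble, "filter_ensemble")) {
    abort("`ensemble` must be a filter_ensemble.")
  }
  check_columns(data, "id", "`data`")
  w <- mbi_weights(ensemble, eps)
  score <- numeric(nrow(data))
  n_passed <- integer(nrow(data))
  for (i in seq_along(ensemble$filters)) {
    pass <- filter_pass(data, ensemble$filters[[i]]$constraints)
    score <- score + ifelse(pass, w$pass[i], -w$fail[i])
    n_passed <- n_passed + as.integer(pass)
  }
  data$mbi <- score / ensemble$n
  data$n_passed <- n_passed
  data
}

#' Rank a screening library by MBI
#'
#' Scores every molecule against the ensemble and orders the table by
#' descending MBI; ties are broken by descending `n_passed`, then by `id`
#' (lexicographic) so the ranking is deterministic.
#'
#' @inheritParams mbi_score
#' @return The scored tibble ordered by rank, with a `rank` column.
#' @export
rank_library <- function(data, ensemble, eps = MBI_EPS) {
  if (nrow(data) == 0) abort("`data` is empty.")
  scored <- mbi_score(data, ensemble, eps)
  scored <- dplyr::arrange(scored, dplyr::desc(.data$mbi),
                           dplyr::desc(.data$n_passed), .data$id)
  scored$rank <- seq_len(nrow(scored))
  scored
}

#' Enrichment factor
#'
#' The ratio between the fractions of active and reference (random/decoy)
#' compounds surviving a filtering step.
#'
#' @param active_pass Percentage of actives passing, in `[0, 100]`.
#' @param reference_pass Percentage of reference compounds passing.
#' @return `active_pass / reference_pass`; `Inf` (with a warning) when
#'   `reference_pass` is 0.
#' @export
#' @examples
#' enrichment_factor(62.9, 4.3) # ~14.6
enrichment_factor <- function(active_pass, reference_pass) {
  stopifnot_scalar_number(active_pass, "active_pass", lower = 0, upper = 100)
  stopifnot_scalar_number(reference_pass, "reference_pass", lower = 0,
                          upper = 100)
  if (reference_pass == 0) {
    warn("Reference pass rate is 0; enrichment factor is infinite.")
    return(Inf)
  }
  active_pass / reference_pass
}

#' Cumulative enrichment curve of a ranked library
#'
#' @param ranked A ranked tibble (see [rank_library()]) with an `id` column,
#'   in rank order.
#' @param labels A named character vector or a tibble with `id` and `label`
#'   columns mapping every ranked id to `"active"`/`"inactive"`.
#' @return An `enrichment_curve` tibble with columns `frac_screened` and
#'   `frac_actives` (cumulative fraction of actives recovered), one row per
#'   rank; ends at (1, 1).
#' @export
enrichment_curve <- function(ranked, labels) {
  check_columns(ranked, "id", "`ranked`")
  if (is.data.frame(labels)) {
    check_columns(labels, c("id", "label"), "`labels`")
    labels <- setNames(labels$label, labels$id)
  }
  missing <- setdiff(ranked$id, names(labels))
  if (length(missing)) {
    abort(sprintf("%d ranked id(s) have no label.", length(missing)))
  }
  is_active <- unname(labels[ranked$id]) == "active"
  n_act <- sum(is_active)
  if (n_act == 0) abort("No actives among the ranked molecules.")
  out <- tibble(
    frac_screened = seq_len(nrow(ranked)) / nrow(ranked),
    frac_actives = cumsum(is_active) / n_act
  )
  class(out) <- c("enrichment_curve", class(out))
  out
}

#' Area under an enrichment curve
#'
#' Trapezoidal area under `frac_actives` versus `frac_screened`, anchored at
#' the origin; 0.5 for a random ranking, approaching 1 for a perfect one.
#'
#' @param curve An [enrichment_curve()].
#' @return A number in `[0, 1]`.
#' @export
enrichment_auc <- function(curve) {
  x <- c(0, curve$frac_screened)
  y <- c(0, curve$frac_actives)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
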