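# Descriptor-range filters: construction, evaluation, and ensembles.
#
# A range filter is a conjunction of closed per-descriptor intervals. Its
# quality on a labelled set is summarised by four per-class percentages:
#   P_A  — % of actives passing      ("true positive" rate)
#   P_NA — % of non-actives passing  ("false positive" rate)
#   N_A  — % of actives failing      (false negatives, 100 - P_A)
#   N_NA — % of non-actives failing  (true negatives, 100 - P_NA)
# and by the Matthews correlation coefficient computed on the
# class-normalized 2x2 table (rates per 100 per class), which weights both
# classes equally regardless of set imbalance.

#' Matthews correlation coefficient from a 2x2 confusion table
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the usual
#' convention that the result is 0 whenever any factor of the denominator is
#' zero. Counts may be non-integer (e.g. class-normalized rates per 100).
#'
#' @param tp,fn,fp,tn Non-negative cell counts: true positives, false
#'   negatives, false positives, true negatives.
#' @return The MCC, a number in `[-1, 1]`.
#' @export
#' @examples
#' # the three-rules model: 87% of actives and 5% of decoys pass,
#' # on equal classes of 100
#' compute_mcc(tp = 87, fn = 13, fp = 5, tn = 95)
compute_mcc <- function(tp, fn, fp, tn) {
  for (v in list(tp, fn, fp, tn)) {
    stopifnot_scalar_number(v, "count", lower = 0)
  }
  if (tp + fn + fp + tn == 0) {
    abort("All confusion-table counts are zero.")
  }
  if (tp + fn == 0 || tn + fp == 0) {
    abort("Need at least one positive and one negative example.")
  }
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Construct a descriptor range filter
#'
#' @param constraints A named list mapping descriptor names to length-2
#'   numeric vectors `c(low, high)` (closed intervals; `-Inf`/`Inf` allowed).
#' @param stats Optional named numeric vector with elements `P_A`, `P_NA`,
#'   `N_A`, `N_NA` (per-class percentages), normally filled in by
#'   [evaluate_filter()].
#' @param mcc Optional MCC of the filter.
#' @return A `range_filter` object.
#' @export
#' @examples
#' range_filter(list(total_charge = c(1, 1), n_nitrogen = c(3, 7)))
range_filter <- function(constraints, stats = NULL, mcc = NA_real_) {
  if (!is.list(constraints) || is.null(names(constraints)) ||
      any(!nzchar(names(constraints)))) {
    abort("`constraints` must be a named list of c(low, high) intervals.")
  }
  if (anyDuplicated(names(constraints))) {
    abort("Constraint descriptor names must be unique.")
  }
  for (d in names(constraints)) {
    iv <- constraints[[d]]
    if (!is.numeric(iv) || length(iv) != 2 || anyNA(iv) || iv[1] > iv[2]) {
      abort(sprintf("Constraint '%s' must be c(low, high) with low <= high.", d))
    }
  }
  if (!is.null(stats)) {
    need <- c("P_A", "P_NA", "N_A", "N_NA")
    if (!all(need %in% names(stats))) {
      abort("`stats` must contain P_A, P_NA, N_A, N_NA.")
    }
    stats <- stats[need]
  }
  structure(
    list(constraints = constraints, stats = stats, mcc = mcc),
    class = "range_filter"
  )
}

#' @export
print.range_filter <- function(x, ...) {
  cat(sprintf("<range_filter: %d constraint(s)>\n", length(x$constraints)))
  for (d in names(x$constraints)) {
    iv <- x$constraints[[d]]
    cat(sprintf("  %s in [%s, %s]\n", d, format(iv[1]), format(iv[2])))
  }
  if (!is.null(x$stats)) {
    cat(sprintf("  P_A %.1f%%  P_NA %.1f%%  MCC %.3f\n",
                x$stats[["P_A"]], x$stats[["P_NA"]], x$mcc))
  }
  invisible(x)
}

# Logical pass vector of a constraint set over a descriptor table.
filter_pass <- function(data, constraints) {
  pass <- rep(TRUE, nrow(data))
  for (d in names(constraints)) {
    v <- data[[d]]
    if (is.null(v)) {
      abort(sprintf("Descriptor '%s' missing from data.", d))
    }
    iv <- constraints[[d]]
    pass <- pass & !is.na(v) & v >= iv[1] & v <= iv[2]
  }
  pass
}

#' Evaluate a range filter on a labelled descriptor set
#'
#' A molecule passes iff every constrained descriptor lies inside its closed
#' interval. Per-class pass/fail percentages are recorded and the MCC is
#' computed on the class-normalized table (`tp = P_A`, `fn = N_A`,
#' `fp = P_NA`, `tn = N_NA`), which gives both classes equal weight; set
#' `mcc_type = "raw"` to use raw example counts instead.
#'
#' @param filter A [range_filter()].
#' @param data A tibble with a `label` column (`"active"`/`"inactive"`) and
#'   the constrained descriptor columns.
#' @param mcc_type `"class_normalized"` (default) or `"raw"`.
#' @return The filter with `stats` and `mcc` filled in.
#' @export
#' @examples
#' d <- tibble::tibble(label = rep(c("active", "inactive"), each = 4),
#'                     x = c(1, 2, 3, 9, 8, 9, 9, 1))
#' evaluate_filter(range_filter(list(x = c(0, 5))), d)$mcc
evaluate_filter <- function(filter, data,
                            mcc_type = c("class_normalized", "raw")) {
  mcc_type <- match.arg(mcc_type)
  check_columns(data, "label", "`data`")
  is_active <- data$label == "active"
  n_act <- sum(is_active)
  n_inact <- sum(!is_active)
  if (n_act == 0 || n_inact == 0) {
    abort("`data` must contain both active and inactive molecules.")
  }
  pass <- filter_pass(data, filter$constraints)
  p_a <- 100 * sum(pass & is_active) / n_act
  p_na <- 100 * sum(pass & !is_active) / n_inact
  stats <- c(P_A = p_a, P_NA = p_na, N_A = 100 - p_a, N_NA = 100 - p_na)
  mcc <- if (mcc_type == "class_normalized") {
    compute_mcc(tp = p_a, fn = 100 - p_a, fp = p_na, tn = 100 - p_na)
  } else {
    compute_mcc(tp = sum(pass & is_active), fn = sum(!pass & is_active),
                fp = sum(pass & !is_active), tn = sum(!pass & !is_active))
  }
  range_filter(filter$constraints, stats = stats, mcc = mcc)
}

#' @export
#' @method tidy range_filter
tidy.range_filter <- function(x, ...) {
  tibble(
    descriptor = names(x$constraints),
    low = map_dbl(x$constraints, 1),
    high = map_dbl(x$constraints, 2)
  )
}

#' @export
#' @method glance range_filter
glance.range_filter <- function(x, ...) {
  s <- x$stats %||% c(P_A = NA_real_, P_NA = NA_real_,
                      N_A = NA_real_, N_NA = NA_real_)
  tibble(
    n_constraints = length(x$constraints),
    P_A = s[["P_A"]], P_NA = s[["P_NA"]],
    N_A = s[["N_A"]], N_NA = s[["N_NA"]],
    mcc = x$mcc
  )
}

#' Bundle range filters into an ensemble
#'
#' An ensemble of "efficient filters" is the input to the Molecular
#' Bioactivity Index: each member must carry evaluated stats (its per-class
#' pass percentages supply the efficiency ratios).
#'
#' @param filters A list of evaluated [range_filter()] objects.
#' @return A `filter_ensemble` object.
#' @export
filter_ensemble <- function(filters) {
  if (!length(filters)) abort("An ensemble needs at least one filter.")
  for (f in filters) {
    if (!inherits(f, "range_filter")) {
      abort("All ensemble members must be range_filter objects.")
    }
    if (is.null(f$stats) || is.na(f$mcc)) {
      abort("All ensemble members must be evaluated (stats and mcc present).")
    }
  }
  structure(list(filters = filters, n = length(filters)),
            class = "filter_ensemble")
}

#' @export
print.filter_ensemble <- function(x, ...) {
  mccs <- map_dbl(x$filters, "mcc")
  cat(sprintf("<filter_ensemble: %d filter(s), MCC %.3f-%.3f>\n",
              x$n, min(mccs), max(mccs)))
  invisible(x)
}

#' @export
#' @method tidy filter_ensemble
tidy.filter_ensemble <- function(x, ...) {
  dplyr::bind_rows(imap(x$filters, function(f, i) {
    dplyr::mutate(glance(f), filter = i, .before = 1)
  }))
}

#' @export
#' @method glance filter_ensemble
glance.filter_ensemble <- function(x, ...) {
  mccs <- map_dbl(x$filters, "mcc")
  tibble(n = x$n, mcc_min = min(mccs), mcc_max = max(mccs))
}

#' Write / read a filter ensemble as JSON
#'
#' Serialization format: a JSON array of
#' `{"constraints": {name: [low, high]}, "stats": {PA, PNA, NA, NNA},
#' "mcc": x}` objects. Infinite bounds are stored as the strings `"-Inf"` /
#' `"Inf"`.
#'
#' @param ensemble A [filter_ensemble()].
#' @param path Output / input file path.
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble`
#'   returns a `filter_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  entries <- map(ensemble$filters, function(f) {
    list(
      constraints = map(f$constraints, function(iv) {
        ifelse(is.finite(iv), iv, ifelse(iv > 0, "Inf", "-Inf"))
      }),
      stats = list(PA = f$stats[["P_A"]], PNA = f$stats[["P_NA"]],
                   `NA` = f$stats[["N_A"]], NNA = f$stats[["N_NA"]]),
      mcc = f$mcc
    )
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  entries <- jsonlite::read_json(path)
  filters <- map(entries, function(e) {
    constraints <- map(e$constraints, function(iv) {
      as.numeric(unlist(iv))
    })
    range_filter(
      constraints,
      stats = c(P_A = e$stats$PA, P_NA = e$stats$PNA,
                N_A = e$stats$`NA`, N_NA = e$stats$NNA),
      mcc = e$mcc
    )
  })
  filter_ensemble(filters)
}
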