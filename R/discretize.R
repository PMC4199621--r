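# Discretization of descriptor values and one-hot range encoding.

#' Discretize descriptors into candidate range cut-points
#'
#' Builds, per descriptor, the ordered cut-points that delimit the candidate
#' intervals the range-filter optimizer searches over. Cut-points are pooled
#' empirical quantiles (deciles by default — e.g. molecular weight described
#' by ten bins); the inverse-ECDF quantile (type 1) is used so cut-points are
#' always observed data values, hence integer for integer-valued descriptors.
#' A constant descriptor yields a single degenerate interval and is flagged.
#'
#' @param training A descriptor tibble (rows = molecules).
#' @param panel Descriptor names to discretize: a character vector or a
#'   [descriptor_panel()] tibble. Defaults to every panel descriptor present
#'   in `training`.
#' @param bins Number of intervals per descriptor (`>= 2`).
#' @return A `discretized_space`: per-descriptor strictly increasing
#'   cut-points, the implied interval edges (with infinite outer bounds), and
#'   the names of flagged constant descriptors.
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:100)
#' discretize(d, panel = "x", bins = 10)$cutpoints$x
discretize <- function(training, panel = NULL, bins = 10) {
  stopifnot_scalar_number(bins, "bins", lower = 2, integerish = TRUE)
  if (nrow(training) == 0) abort("`training` is empty.")
  if (is.null(panel)) {
    panel <- intersect(descriptor_panel()$name, names(training))
  }
  if (is.data.frame(panel)) panel <- panel$name
  if (!length(panel)) abort("No descriptors to discretize.")
  check_columns(training, panel, "`training`")
  cutpoints <- list()
  flagged <- character(0)
  for (d in panel) {
    v <- training[[d]]
    v <- v[!is.na(v)]
    cuts <- unique(unname(quantile(v, probs = seq_len(bins - 1) / bins,
                                   type = 1)))
    if (length(unique(v)) <= 1 || length(cuts) == 0) {
      flagged <- c(flagged, d)
      cuts <- numeric(0)
    }
    cutpoints[[d]] <- cuts
  }
  if (length(flagged)) {
    warn(sprintf("Constant descriptor(s) collapsed to one interval: %s.",
                 paste(flagged, collapse = ", ")))
  }
  structure(
    list(
      cutpoints = cutpoints,
      edges = map(cutpoints, function(cuts) c(-Inf, cuts, Inf)),
      flagged = flagged,
      bins = as.integer(bins)
    ),
    class = "discretized_space"
  )
}

#' @export
print.discretized_space <- function(x, ...) {
  cat(sprintf("<discretized_space: %d descriptor(s), %d bins requested>\n",
              length(x$cutpoints), x$bins))
  for (d in names(x$cutpoints)) {
    cat(sprintf("  %s: %d interval(s)%s\n", d, length(x$cutpoints[[d]]) + 1L,
                if (d %in% x$flagged) " [degenerate]" else ""))
  }
  invisible(x)
}

# Interval index of values under closed-right binning: interval i is
# (cut[i-1], cut[i]], outer intervals unbounded. A value equal to a cut-point
# falls in the lower interval.
interval_index <- function(values, cuts) {
  if (!length(cuts)) return(rep(1L, length(values)))
  findInterval(values, cuts, left.open = TRUE) + 1L
}

#' One-hot binary range encoding of molecules
#'
#' Encodes each molecule as a bit vector with one bit per
#' (descriptor, interval) pair: for every descriptor exactly one interval bit
#' is set. Bins are closed on the right, so a value exactly on a cut-point is
#' assigned to the lower interval.
#'
#' @param data A descriptor tibble.
#' @param space A [discretize()]d space.
#' @return An integer 0/1 matrix, one row per molecule, with column names
#'   `"<descriptor>:<interval>"`.
#' @export
encode_binary <- function(data, space) {
  if (!inherits(space, "discretized_space")) {
    abort("`space` must be a discretized_space.")
  }
  check_columns(data, names(space$cutpoints), "`data`")
  blocks <- imap(space$cutpoints, function(cuts, d) {
    idx <- interval_index(data[[d]], cuts)
    m <- matrix(0L, nrow = nrow(data), ncol = length(cuts) + 1L)
    m[cbind(seq_len(nrow(data)), idx)] <- 1L
    colnames(m) <- sprintf("%s:%d", d, seq_len(ncol(m)))
    m
  })
  do.call(cbind, unname(blocks))
}
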