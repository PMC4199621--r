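#' Stratified train/test split
#'
#' Randomly partitions a labelled molecule table into training and test sets
#' independently within each class, so class proportions are preserved. With
#' 78 actives and 9000 decoys at `fraction_train = 2/3` this reproduces the
#' 52/26 and 6000/3000 splits used for model construction.
#'
#' @param data A tibble with a `label` column.
#' @param fraction_train Fraction of each class assigned to training,
#'   strictly between 0 and 1. Per class, `round(fraction_train * n)` rows go
#'   to training.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A list with tibbles `train` and `test`; their union is `data`
#'   (rows possibly reordered within class), their intersection empty.
#' @export
#' @examples
#' mols <- tibble::tibble(id = as.character(1:9),
#'                        label = rep(c("active", "inactive"), c(3, 6)))
#' split_train_test(mols, 2 / 3, seed = 1)
split_train_test <- function(data, fraction_train = 2 / 3, seed) {
  check_columns(data, "label", "`data`")
  stopifnot_scalar_number(fraction_train, "fraction_train",
                          lower = 1e-12, upper = 1 - 1e-12)
  classes <- split(seq_len(nrow(data)), data$label)
  small <- names(classes)[lengths(classes) < 2]
  if (length(small)) {
    abort(sprintf("Class(es) with fewer than 2 members: %s.",
                  paste(small, collapse = ", ")))
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(classes, function(idx) {
      n_train <- round(fraction_train * length(idx))
      sample(idx, n_train)
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(
    train = data[train_idx, , drop = FALSE],
    test = data[setdiff(seq_len(nrow(data)), train_idx), , drop = FALSE]
  )
}
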