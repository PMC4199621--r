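# Rule-based drug-likeness / lead-likeness / three-rules filters.

RULE_DEFINITIONS <- list(
  # Lipinski rule of five (drug-likeness), all bounds inclusive.
  lipinski = list(
    hbd = c(-Inf, 5), hba = c(-Inf, 10),
    molecular_weight = c(-Inf, 500), logp = c(-Inf, 5)
  ),
  # Oprea lead-likeness.
  oprea = list(
    molecular_weight = c(-Inf, 450), logp = c(-3.5, 4.5),
    n_rings = c(-Inf, 4), n_rot_bonds = c(-Inf, 10),
    hbd = c(-Inf, 5), hba = c(-Inf, 8)
  ),
  # The three-rules hH4R antagonist model: net charge exactly +1,
  # 3 <= nitrogen count <= 7, fractional negative VdW surface area <= 0.42.
  three_rules = list(
    total_charge = c(1, 1), n_nitrogen = c(3, 7), fasa_neg = c(-Inf, 0.42)
  )
)

#' Rule-based molecule filters
#'
#' Evaluates one of the built-in property-rule conjunctions on each row of a
#' descriptor table. All bounds are inclusive, as the rules are printed:
#'
#' * `lipinski` (drug-likeness): HBD <= 5, HBA <= 10, MW <= 500, logP <= 5.
#' * `oprea` (lead-likeness): MW <= 450, -3.5 <= logP <= 4.5, rings <= 4,
#'   rotatable bonds <= 10, HBD <= 5, HBA <= 8.
#' * `three_rules` (hH4R antagonist model): total charge = +1,
#'   3 <= N atoms <= 7, fractional negative VdW surface area <= 0.42.
#'
#' @param data A tibble carrying the descriptor columns the rule needs
#'   (see [compute_descriptors()]).
#' @param rule `"lipinski"`, `"oprea"` or `"three_rules"`.
#' @return `data` with a logical column `passes_<rule>`.
#' @export
#' @examples
#' d <- tibble::tibble(total_charge = c(1, 0), n_nitrogen = 5, fasa_neg = 0.3)
#' rule_filter(d, "three_rules")$passes_three_rules
rule_filter <- function(data, rule = c("lipinski", "oprea", "three_rules")) {
  rule <- match.arg(rule)
  spec <- RULE_DEFINITIONS[[rule]]
  check_columns(data, names(spec), sprintf("`data` (rule '%s')", rule))
  pass <- rep(TRUE, nrow(data))
  for (d in names(spec)) {
    v <- data[[d]]
    if (any(is.na(v))) {
      abort(sprintf("Descriptor '%s' has missing values; rule '%s' needs it.",
                    d, rule))
    }
    pass <- pass & v >= spec[[d]][1] & v <= spec[[d]][2]
  }
  data[[paste0("passes_", rule)]] <- pass
  data
}

#' The three-rules model as a range filter
#'
#' Returns the printed three-rules hH4R antagonist model as a [range_filter()]
#' object, so it can be evaluated and combined like any learned filter.
#'
#' @return A `range_filter`.
#' @export
three_rules_filter <- function() {
  range_filter(RULE_DEFINITIONS$three_rules)
}
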