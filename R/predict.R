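# Property evaluation: Y = sum_i a_i A_i + sum_j b_j B_j + C with a hard
# eligibility gate.  A molecule is predictable only when every one of its
# atom groups is present in the table and valid (supported by at least
# three training molecules); ineligible molecules get a structured verdict
# and no number.

#' Check whether group counts are predictable against a table
#'
#' @param counts a `group_counts` object (see [perceive()]).
#' @param table a `parameter_table`.
#' @return list with `missing` (signature keys absent from the table) and
#'   `invalid` (present but supported by fewer than three molecules).
#'   Both empty iff the molecule is eligible.
#' @export
check_eligibility <- function(counts, table) {
  keys <- as.character(names(counts$counts))
  if (table$uses_special)
    keys <- c(keys, names(counts$special)[counts$special > 0])
  present <- keys %in% table$entries$key
  missing <- keys[!present]
  valid <- table$entries$valid[match(keys[present], table$entries$key)]
  invalid <- keys[present][!valid]
  list(missing = missing, invalid = invalid)
}

#' Predict a descriptor value for a molecule
#'
#' Evaluates the group-additivity sum for one molecule (or pre-perceived
#' group counts) against a parameter table.  Values are in decimal-log
#' units: log10 of the liquid viscosity in cP at 293.15 K, or log10 of the
#' activity coefficient at infinite dilution in water at 298.15 K.
#' Ineligible molecules return a verdict with the offending signatures and
#' `value = NA`, never a numeric guess.
#'
#' @param x a [molgraph] or a `group_counts` object.
#' @param table a `parameter_table`, e.g. from [load_packaged()].
#' @param h_acceptor enable the intramolecular hydrogen-bond term when
#'   perceiving (off by default).
#' @return object of class `ga_prediction`: list with `id`, `descriptor`,
#'   `eligible`, `value` (log units; `NA` when ineligible), `linear`
#'   (10^value), `missing`, `invalid` and `breakdown` (data frame of
#'   signature, count, contribution, product, including the special terms
#'   and the constant).
#' @export
predict_property <- function(x, table, h_acceptor = FALSE) {
  counts <- if (inherits(x, "molgraph")) perceive(x, h_acceptor = h_acceptor) else x
  stopifnot(inherits(counts, "group_counts"), inherits(table, "parameter_table"))
  gate <- check_eligibility(counts, table)
  eligible <- length(gate$missing) == 0 && length(gate$invalid) == 0

  keys <- names(counts$counts)
  cnt <- unname(counts$counts)
  if (table$uses_special) {
    sp <- counts$special[counts$special > 0]
    keys <- c(keys, names(sp))
    cnt <- c(cnt, unname(sp))
  }
  contrib <- table$entries$contribution[match(keys, table$entries$key)]
  breakdown <- data.frame(signature = keys, count = cnt,
                          contribution = contrib, product = cnt * contrib)
  if (table$uses_constant)
    breakdown <- rbind(breakdown,
                       data.frame(signature = "CONST", count = 1,
                                  contribution = table$constant,
                                  product = table$constant))
  value <- if (eligible) sum(breakdown$product) else NA_real_
  structure(list(id = counts$id, descriptor = table$descriptor,
                 eligible = eligible, value = value,
                 linear = if (eligible) 10^value else NA_real_,
                 missing = gate$missing, invalid = gate$invalid,
                 breakdown = breakdown),
            class = "ga_prediction")
}

#' @export
print.ga_prediction <- function(x, ...) {
  if (x$eligible) {
    cat(sprintf("<prediction> %s: %s = %.4f (linear %.4g)\n",
                x$id, x$descriptor, x$value, x$linear))
  } else {
    cat(sprintf("<prediction> %s: not eligible for %s\n", x$id, x$descriptor))
    if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ", "), "\n")
    if (length(x$invalid)) cat("  invalid:", paste(x$invalid, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname predict_property
#' @param object a `parameter_table`.
#' @param newdata a [molgraph] or `group_counts`.
#' @param ... passed to [predict_property()].
#' @export
predict.parameter_table <- function(object, newdata, ...) {
  predict_property(newdata, object, ...)
}
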