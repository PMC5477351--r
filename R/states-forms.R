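# ---- property-attribute interoperable representation --------------------
# An abnormal state can be written three ways:
#   quantitative <O, SO?, A, Vqt+unit>   e.g. <blood, -, pressure, 180 mmHg>
#   qualitative  <O, SO?, A, Vql>        e.g. <blood, -, pressure, high>
#   property     <P, Vp>                 e.g. <hypertension, true>
# A rule table carries the (user-supplied) cut-points and pairings that make
# the three forms interconvertible. No thresholds are built in.

#' Quantitative, qualitative and property forms of an abnormal state
#'
#' Constructors for the three interoperable representations. `sub_object`
#' captures the focused constituent of a mixture, as in hyperglycemia
#' `<blood (O), glucose (SO), concentration (A), high (V)>`.
#'
#' @param object,sub_object,attribute Descriptor strings (`sub_object`
#'   optional).
#' @param magnitude Finite numeric measurement.
#' @param unit Non-empty unit string; units are matched exactly, there is
#'   no conversion engine.
#' @return An object of class `quantitative_form`, `qualitative_form` or
#'   `property_form`.
#' @export
quantitative_form <- function(object, attribute, magnitude, unit,
                              sub_object = NA) {
  magnitude <- as.numeric(magnitude)
  if (!is.finite(magnitude)) rf_stop("magnitude must be finite")
  if (!is.character(unit) || !nzchar(unit)) rf_stop("unit must be nonempty")
  structure(list(object = object, sub_object = chr1_or_na(sub_object, "sub_object"),
                 attribute = attribute, magnitude = magnitude, unit = unit),
            class = c("quantitative_form", "rf_form"))
}

#' @rdname quantitative_form
#' @param qualitative_value Category label, e.g. `"high"`.
#' @export
qualitative_form <- function(object, attribute, qualitative_value,
                             sub_object = NA) {
  structure(list(object = object, sub_object = chr1_or_na(sub_object, "sub_object"),
                 attribute = attribute,
                 qualitative_value = qualitative_value),
            class = c("qualitative_form", "rf_form"))
}

#' @rdname quantitative_form
#' @param property Property name, e.g. `"hypertension"`.
#' @param property_value Boolean-like property value, default `TRUE`.
#' @export
property_form <- function(property, property_value = TRUE) {
  if (!is.character(property) || !nzchar(property))
    rf_stop("property must be nonempty")
  structure(list(property = property, property_value = isTRUE(property_value)),
            class = c("property_form", "rf_form"))
}

#' @export
print.rf_form <- function(x, ...) {
  cls <- class(x)[1]
  if (cls == "quantitative_form")
    cat(sprintf("<%s, %s%s, %g %s>\n", x$object,
                if (is.na(x$sub_object)) "" else paste0(x$sub_object, ", "),
                x$attribute, x$magnitude, x$unit))
  else if (cls == "qualitative_form")
    cat(sprintf("<%s, %s%s, %s>\n", x$object,
                if (is.na(x$sub_object)) "" else paste0(x$sub_object, ", "),
                x$attribute, x$qualitative_value))
  else
    cat(sprintf("<%s, %s>\n", x$property, tolower(x$property_value)))
  invisible(x)
}

#' Build a conversion rule table
#'
#' `quant_rules` holds quantization intervals: for one
#' (object, sub_object, attribute, unit) key, ordered rows
#' `[lower, upper) -> qualitative_value`; intervals under one key must be
#' disjoint. `prop_rules` pairs qualitative tuples with property forms,
#' bijectively in each direction.
#'
#' @param quant_rules Data.frame with columns `object`, `sub_object`,
#'   `attribute`, `unit`, `lower`, `upper`, `qualitative_value`. Use
#'   `-Inf`/`Inf` for open ends and `NA` sub-objects.
#' @param prop_rules Data.frame with columns `object`, `sub_object`,
#'   `attribute`, `qualitative_value`, `property`, `property_value`.
#' @return A `rule_table`.
#' @export
rule_table <- function(quant_rules = NULL, prop_rules = NULL) {
  if (is.null(quant_rules))
    quant_rules <- data.frame(object = character(), sub_object = character(),
                              attribute = character(), unit = character(),
                              lower = numeric(), upper = numeric(),
                              qualitative_value = character(),
                              stringsAsFactors = FALSE)
  if (is.null(prop_rules))
    prop_rules <- data.frame(object = character(), sub_object = character(),
                             attribute = character(),
                             qualitative_value = character(),
                             property = character(), property_value = logical(),
                             stringsAsFactors = FALSE)
  qkey <- paste(quant_rules$object, quant_rules$sub_object,
                quant_rules$attribute, quant_rules$unit, sep = "\r")
  for (k in unique(qkey)) {
    iv <- quant_rules[qkey == k, , drop = FALSE]
    iv <- iv[order(iv$lower), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$lower[-1] < iv$upper[-nrow(iv)]))
      rf_stop(sprintf("overlapping quantization intervals for key '%s'",
                      gsub("\r", "/", k)))
  }
  fwd <- paste(prop_rules$object, prop_rules$sub_object, prop_rules$attribute,
               prop_rules$qualitative_value, sep = "\r")
  bwd <- paste(prop_rules$property, prop_rules$property_value, sep = "\r")
  if (anyDuplicated(fwd) || anyDuplicated(bwd))
    rf_stop("property rules must be bijective in each direction")
  structure(list(quant_rules = quant_rules, prop_rules = prop_rules),
            class = "rule_table")
}

#' @export
print.rule_table <- function(x, ...) {
  cat(sprintf("<rule_table> %d quantization interval(s), %d property pairing(s)\n",
              nrow(x$quant_rules), nrow(x$prop_rules)))
  invisible(x)
}

na_key <- function(x) ifelse(is.na(x), "", as.character(x))

#' Convert a quantitative form to its qualitative category
#'
#' Looks up the quantization rule matching the form's object, sub-object,
#' attribute and unit, and returns the qualitative value of the interval
#' `[lower, upper)` containing the magnitude.
#'
#' @param q A `quantitative_form`.
#' @param rules A `rule_table`.
#' @return A `qualitative_form`.
#' @export
quantize <- function(q, rules) {
  stopifnot(inherits(q, "quantitative_form"), inherits(rules, "rule_table"))
  r <- rules$quant_rules
  same_state <- na_key(r$object) == na_key(q$object) &
    na_key(r$sub_object) == na_key(q$sub_object) &
    na_key(r$attribute) == na_key(q$attribute)
  if (!any(same_state))
    rf_stop(sprintf("no quantization rule for <%s, %s, %s>", q$object,
                    na_key(q$sub_object), q$attribute),
            "riverflow_missing_rule")
  hit <- same_state & r$unit == q$unit
  if (!any(hit))
    rf_stop(sprintf("unit mismatch: rule table has no '%s' entry for <%s, %s>",
                    q$unit, q$object, q$attribute), "riverflow_unit_error")
  iv <- r[hit, , drop = FALSE]
  inside <- q$magnitude >= iv$lower & q$magnitude < iv$upper
  if (!any(inside))
    rf_stop(sprintf("magnitude %g %s falls in no interval of the rule",
                    q$magnitude, q$unit), "riverflow_out_of_range")
  qualitative_form(q$object, q$attribute, iv$qualitative_value[inside][1],
                   q$sub_object)
}

#' Map a qualitative form to its property form
#'
#' @param ql A `qualitative_form`.
#' @param rules A `rule_table`.
#' @return A `property_form`.
#' @export
to_property <- function(ql, rules) {
  stopifnot(inherits(ql, "qualitative_form"), inherits(rules, "rule_table"))
  r <- rules$prop_rules
  hit <- na_key(r$object) == na_key(ql$object) &
    na_key(r$sub_object) == na_key(ql$sub_object) &
    na_key(r$attribute) == na_key(ql$attribute) &
    r$qualitative_value == ql$qualitative_value
  if (!any(hit))
    rf_stop(sprintf("no property rule for <%s, %s, %s, %s>", ql$object,
                    na_key(ql$sub_object), ql$attribute, ql$qualitative_value),
            "riverflow_missing_rule")
  property_form(r$property[hit][1], r$property_value[hit][1])
}

#' Map a property form back to its qualitative form
#'
#' Exact inverse of [to_property()] under the same table:
#' `to_qualitative(to_property(x), rules)` is `x` for every tabled `x`.
#'
#' @param p A `property_form`.
#' @param rules A `rule_table`.
#' @return A `qualitative_form`.
#' @export
to_qualitative <- function(p, rules) {
  stopifnot(inherits(p, "property_form"), inherits(rules, "rule_table"))
  r <- rules$prop_rules
  hit <- r$property == p$property & r$property_value == p$property_value
  if (!any(hit))
    rf_stop(sprintf("no property rule for <%s, %s>", p$property,
                    tolower(p$property_value)), "riverflow_missing_rule")
  qualitative_form(r$object[hit][1], r$attribute[hit][1],
                   r$qualitative_value[hit][1],
                   if (is.na(r$sub_object[hit][1])) NA else r$sub_object[hit][1])
}

normalize_form <- function(x, rules) {
  if (inherits(x, "quantitative_form")) x <- quantize(x, rules)
  if (inherits(x, "qualitative_form")) x <- to_property(x, rules)
  if (!inherits(x, "property_form")) rf_stop("not an abnormal-state form")
  x
}

#' Are two forms the same abnormal state?
#'
#' Normalizes both arguments to property form (quantitative forms are
#' quantized first) and compares. This is the interoperability between
#' clinical test data and the abnormal states used in disease definitions:
#' `<blood, pressure, 180 mmHg>` and `<hypertension, true>` are the same
#' state under a table mapping high blood pressure to hypertension.
#'
#' @param a,b Forms of any of the three kinds.
#' @param rules A `rule_table`.
#' @return `TRUE` or `FALSE`. Missing-rule errors propagate.
#' @export
interoperable <- function(a, b, rules) {
  pa <- normalize_form(a, rules)
  pb <- normalize_form(b, rules)
  identical(pa$property, pb$property) &&
    identical(pa$property_value, pb$property_value)
}

#' Read / write a rule table as TSV
#'
#' One table with a `kind` column: `interval` rows populate the
#' quantization rules (columns `unit`, `lower`, `upper`,
#' `qualitative_value`), `property` rows the property pairings (columns
#' `qualitative_value`, `property`, `property_value`).
#'
#' @param path TSV file path.
#' @return [read_rule_table()] returns a `rule_table`;
#'   [write_rule_table()] returns `path` invisibly.
#' @export
read_rule_table <- function(path) {
  df <- read_tsv_chr(path)
  iv <- df[df$kind == "interval", , drop = FALSE]
  pr <- df[df$kind == "property", , drop = FALSE]
  rule_table(
    quant_rules = data.frame(
      object = iv$object, sub_object = blank_na(iv$sub_object),
      attribute = iv$attribute, unit = iv$unit,
      lower = as.numeric(iv$lower), upper = as.numeric(iv$upper),
      qualitative_value = iv$qualitative_value, stringsAsFactors = FALSE),
    prop_rules = data.frame(
      object = pr$object, sub_object = blank_na(pr$sub_object),
      attribute = pr$attribute, qualitative_value = pr$qualitative_value,
      property = pr$property,
      property_value = tolower(pr$property_value) %in% c("true", "1", "yes"),
      stringsAsFactors = FALSE))
}

#' @rdname read_rule_table
#' @param rules A `rule_table`.
#' @export
write_rule_table <- function(rules, path) {
  iv <- rules$quant_rules
  pr <- rules$prop_rules
  df <- data.frame(
    kind = c(rep("interval", nrow(iv)), rep("property", nrow(pr))),
    object = c(iv$object, pr$object),
    sub_object = na_blank(c(iv$sub_object, pr$sub_object)),
    attribute = c(iv$attribute, pr$attribute),
    unit = c(iv$unit, rep("", nrow(pr))),
    lower = c(as.character(iv$lower), rep("", nrow(pr))),
    upper = c(as.character(iv$upper), rep("", nrow(pr))),
    qualitative_value = c(iv$qualitative_value, pr$qualitative_value),
    property = c(rep("", nrow(iv)), pr$property),
    property_value = c(rep("", nrow(iv)), tolower(pr$property_value)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
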