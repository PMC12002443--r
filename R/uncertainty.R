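# Uncertainty-tuple encodings for in vitro measurements.
#
# Intrinsic hepatic clearance (Clint) may be stored as a 4-tuple string
# "median,l95,u95,p" where the first three are Bayesian posterior quantiles
# and the last is the p-value for systematic (no observed) clearance.
# Fraction unbound in plasma (fup) uses the analogous 3-tuple without the
# p-value.  A bare number is a point estimate.

#' Construct an uncertain value
#'
#' @param point Central (median) estimate.
#' @param l95,u95 Optional lower/upper 95th-percentile bounds.
#' @param p_no_effect Optional probability that no effect (e.g. no hepatic
#'   clearance) was observed, in `[0, 1]`.
#' @return An object of class `uncertain_value`.
#' @export
uncertain_value <- function(point, l95 = NA_real_, u95 = NA_real_,
                            p_no_effect = NA_real_) {
  stopifnot(is_scalar_number(point))
  if (!is.na(l95) && !is.na(u95) && l95 > u95)
    abort(sprintf("invalid uncertainty bounds: l95 (%g) > u95 (%g)", l95, u95),
          class = "pbtksim_validation_error")
  if (!is.na(l95) && l95 > point)
    abort(sprintf("invalid uncertainty bounds: l95 (%g) > point (%g)", l95, point),
          class = "pbtksim_validation_error")
  if (!is.na(u95) && u95 < point)
    abort(sprintf("invalid uncertainty bounds: u95 (%g) < point (%g)", u95, point),
          class = "pbtksim_validation_error")
  if (!is.na(p_no_effect) && (p_no_effect < 0 || p_no_effect > 1))
    abort("p_no_effect must be in [0, 1]", class = "pbtksim_validation_error")
  structure(list(point = point, l95 = l95, u95 = u95,
                 p_no_effect = p_no_effect),
            class = "uncertain_value")
}

#' @export
print.uncertain_value <- function(x, ...) {
  cat(format_uncertainty_tuple(x), "\n")
  invisible(x)
}

#' Parse a comma-separated uncertainty tuple
#'
#' `kind = "clint"` accepts 1 or 4 values (median, l95, u95, p-no-clearance);
#' `kind = "fup"` accepts 1 or 3 values (median, l95, u95).  The median comes
#' first, followed by the lower and upper 95th percentiles.
#'
#' @param s String such as `"13,9.2,16.2,0.0012"`, or a bare number.
#' @param kind `"clint"` or `"fup"`.
#' @return An [uncertain_value()].
#' @export
parse_uncertainty_tuple <- function(s, kind = c("clint", "fup")) {
  kind <- match.arg(kind)
  if (inherits(s, "uncertain_value")) return(s)
  if (is.numeric(s) && length(s) == 1L) {
    vals <- s
  } else {
    parts <- trimws(strsplit(as.character(s), ",", fixed = TRUE)[[1]])
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals))
      abort(sprintf("non-numeric component in uncertainty tuple '%s'", s),
            class = "pbtksim_parse_error")
  }
  expect_n <- if (kind == "clint") c(1L, 4L) else c(1L, 3L)
  if (!length(vals) %in% expect_n)
    abort(sprintf(
      "uncertainty tuple '%s' has %d values; kind '%s' takes %s",
      paste(vals, collapse = ","), length(vals), kind,
      paste(expect_n, collapse = " or ")), class = "pbtksim_parse_error")
  uv <- if (length(vals) == 1L) {
    uncertain_value(vals[1])
  } else if (length(vals) == 3L) {
    uncertain_value(vals[1], vals[2], vals[3])
  } else {
    uncertain_value(vals[1], vals[2], vals[3], p_no_effect = vals[4])
  }
  if (kind == "clint" && uv$point < 0)
    abort("intrinsic clearance must be non-negative",
          class = "pbtksim_validation_error")
  if (kind == "fup" && (uv$point < 0 || uv$point > 1))
    abort("fraction unbound must lie in [0, 1]",
          class = "pbtksim_validation_error")
  uv
}

#' Format an uncertain value back to its tuple string
#'
#' Inverse of [parse_uncertainty_tuple()]: `parse(format(uv))` recovers `uv`.
#'
#' @param uv An [uncertain_value()].
#' @return A string encoding.
#' @export
format_uncertainty_tuple <- function(uv) {
  stopifnot(inherits(uv, "uncertain_value"))
  fmt <- function(v) sprintf("%.17g", v)
  if (is.na(uv$l95) && is.na(uv$u95)) return(fmt(uv$point))
  base <- paste(fmt(uv$point), fmt(uv$l95), fmt(uv$u95), sep = ",")
  if (is.na(uv$p_no_effect)) base else paste(base, fmt(uv$p_no_effect), sep = ",")
}
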