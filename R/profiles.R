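#' Read an age profile (possibly age-banded) from CSV
#'
#' Wage and consumption statistics are typically published on age bands
#' ("20-24") rather than single ages. This reader expands banded values to a
#' unit age grid, either by constant fill within the band (default) or by
#' linear interpolation between band midpoints. Ages outside the observed
#' range are extrapolated by `extrapolate`: `"zero"` (suitable for income —
#' no earnings outside working ages) or `"last"` (suitable for consumption —
#' carry the last observed value).
#'
#' @param path CSV path.
#' @param value_col Name of the value column.
#' @param age_col Name of the age column. Entries may be integers (band lower
#'   bounds or single ages) or strings like `"20-24"`.
#' @param ages Target unit age grid (default `0:110`).
#' @param method `"constant"` (fill within band) or `"midpoint"` (linear
#'   interpolation between band midpoints).
#' @param extrapolate `"zero"` or `"last"`.
#' @return A tibble with columns `age`, `value` on the full grid.
#' @export
read_age_profile <- function(path, value_col, age_col = "age",
                             ages = 0:110,
                             method = c("constant", "midpoint"),
                             extrapolate = c("zero", "last")) {
  method <- match.arg(method)
  extrapolate <- match.arg(extrapolate)
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(c(age_col, value_col), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "qalyvsl_format_error")
  }
  expand_bands(df[[age_col]], df[[value_col]], ages = ages,
               method = method, extrapolate = extrapolate)
}

# parse "20-24" / "20" age labels into (lo, hi) bounds
parse_age_bands <- function(x) {
  x <- as.character(x)
  lo <- suppressWarnings(as.numeric(sub("\\s*[-–].*$", "", x)))
  hi <- suppressWarnings(as.numeric(sub("^.*[-–]\\s*", "", x)))
  if (any(is.na(lo)) || any(is.na(hi))) {
    abort("unparseable age band labels", class = "qalyvsl_format_error")
  }
  list(lo = lo, hi = hi)
}

expand_bands <- function(age_labels, values, ages, method, extrapolate) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("profile values must be finite and non-negative",
          class = "qalyvsl_validation_error")
  }
  b <- parse_age_bands(age_labels)
  if (any(diff(b$lo) <= 0)) {
    abort("age bands must be in increasing order", class = "qalyvsl_format_error")
  }
  out <- rep(NA_real_, length(ages))
  if (method == "constant") {
    for (i in seq_along(values)) {
      out[ages >= b$lo[i] & ages <= b$hi[i]] <- values[i]
    }
    # bands given as lower bounds only: fill forward to the next band
    for (i in seq_along(values)) {
      upper <- if (i < length(values)) b$lo[i + 1] - 1 else b$hi[i]
      out[ages >= b$lo[i] & ages <= upper & is.na(out)] <- values[i]
    }
  } else {
    mid <- (b$lo + b$hi) / 2
    inside <- ages >= min(mid) & ages <= max(mid)
    out[inside] <- approx(mid, values, xout = ages[inside])$y
  }
  observed_lo <- min(b$lo)
  observed_hi <- max(b$hi)
  below <- ages < observed_lo
  above <- ages > observed_hi
  if (extrapolate == "zero") {
    out[below | above] <- 0
    out[is.na(out)] <- 0
  } else {
    out[below] <- values[1]
    out[above] <- values[length(values)]
    # midpoint mode leaves edges inside the observed range: carry nearest
    out[is.na(out) & ages <= (observed_lo + observed_hi) / 2] <- values[1]
    out[is.na(out)] <- values[length(values)]
  }
  tibble::tibble(age = as.numeric(ages), value = out)
}

#' Assemble an economic profile of full income and full consumption
#'
#' Full income \eqn{y^F(t)} and full consumption \eqn{c^F(t)} are
#' Murphy–Topel-style constructs that bundle market income/consumption with
#' the value of non-market time. Both are carried per age in a single tibble;
#' the default currency unit is million JPY per year.
#'
#' @param income Tibble `(age, value)` for full income, or a numeric vector
#'   on `ages`.
#' @param consumption Tibble `(age, value)` for full consumption, or a
#'   numeric vector on `ages`.
#' @param ages Unit age grid; defaults to the income grid.
#' @param currency_unit Label stored as an attribute.
#' @return Tibble of class `economic_profile` with columns `age`,
#'   `full_income`, `full_consumption`.
#' @export
economic_profile <- function(income, consumption, ages = NULL,
                             currency_unit = "million JPY") {
  if (is.data.frame(income)) {
    ages <- ages %||% income$age
    income <- income$value[match(ages, income$age)]
  }
  if (is.data.frame(consumption)) {
    consumption <- consumption$value[match(ages, consumption$age)]
  }
  stopifnot(length(income) == length(ages),
            length(consumption) == length(ages))
  if (any(!is.finite(income)) || any(!is.finite(consumption)) ||
      any(income < 0) || any(consumption < 0)) {
    abort("profiles must be finite and non-negative on the full grid",
          class = "qalyvsl_validation_error")
  }
  out <- tibble::tibble(age = as.numeric(ages),
                        full_income = as.numeric(income),
                        full_consumption = as.numeric(consumption))
  structure(out, class = c("economic_profile", class(tibble::tibble()))) |>
    set_attr("currency_unit", currency_unit)
}

#' Population counts by age
#'
#' @param age Integer ages.
#' @param count Persons at each age; non-negative with at least one positive.
#' @return Tibble of class `population_distribution`.
#' @export
population_distribution <- function(age, count) {
  count <- as.numeric(count)
  if (any(!is.finite(count)) || any(count < 0) || sum(count) <= 0) {
    abort("population counts must be non-negative with a positive total",
          class = "qalyvsl_validation_error")
  }
  out <- tibble::tibble(age = as.numeric(age), count = count)
  structure(out, class = c("population_distribution", class(tibble::tibble())))
}
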