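#' Construct a period life table
#'
#' A life table carries the number-living column `lx` on a unit age grid
#' starting at 0. It can be built from survivor counts `lx` directly or from
#' one-year death probabilities `qx`, in which case `lx` is derived by the
#' usual recursion \eqn{l(x+1) = l(x)\,(1 - q(x))} from a radix of 1.
#' Survivorship at the terminal age (the last age in the table) is treated as
#' the end of the table: conditional survival beyond it is 0.
#'
#' @param age Integer ages, strictly increasing. Gaps are filled by linear
#'   interpolation of `lx` so the result is always on a unit grid.
#' @param lx Survivor counts (any radix, non-increasing, non-negative).
#'   Exactly one of `lx`, `qx` must be supplied.
#' @param qx One-year death probabilities in `[0, 1]`.
#' @return A tibble of class `life_table` with columns `age` and `lx`
#'   (normalised to radix 1) and attribute `terminal_age`.
#' @examples
#' lt <- life_table(age = 0:3, lx = c(100000, 99500, 99400, 99350))
#' survival_prob(lt, t = 2, a = 0)
#' @export
life_table <- function(age, lx = NULL, qx = NULL) {
  if (is.null(lx) == is.null(qx)) {
    abort("supply exactly one of `lx` or `qx`", class = "qalyvsl_format_error")
  }
  age <- as.numeric(age)
  if (length(age) < 2 || any(diff(age) <= 0)) {
    abort("`age` must be strictly increasing with at least two entries",
          class = "qalyvsl_validation_error")
  }
  if (!is.null(qx)) {
    qx <- as.numeric(qx)
    if (any(!is.finite(qx)) || any(qx < 0 | qx > 1)) {
      abort("`qx` must lie in [0, 1]", class = "qalyvsl_validation_error")
    }
    if (any(diff(age) != 1)) {
      abort("`qx` input requires a unit age grid", class = "qalyvsl_format_error")
    }
    lx <- cumprod(c(1, 1 - qx[-length(qx)]))
  }
  lx <- as.numeric(lx)
  if (any(!is.finite(lx)) || any(lx < 0)) {
    abort("`lx` must be finite and non-negative", class = "qalyvsl_validation_error")
  }
  bad <- which(diff(lx) > 0)
  if (length(bad) > 0) {
    abort(
      paste0("survivor counts increase at age(s) ",
             paste(age[bad + 1], collapse = ", ")),
      class = "qalyvsl_validation_error"
    )
  }
  # expand to a unit grid by linear interpolation of lx
  grid <- seq(age[1], age[length(age)], by = 1)
  lx_grid <- approx(age, lx, xout = grid, method = "linear")$y
  out <- tibble::tibble(age = grid, lx = lx_grid / lx_grid[1])
  structure(out,
            class = c("life_table", class(tibble::tibble()))) |>
    set_attr("terminal_age", grid[length(grid)])
}

set_attr <- function(x, name, value) {
  attr(x, name) <- value
  x
}

#' Read a life table from CSV
#'
#' The `dialect` list maps file columns onto the life-table fields:
#' `age_col` (default `"age"`), and either `lx_col` or `qx_col` (default
#' `lx_col = "lx"`). Columns are read with [readr::read_csv()].
#'
#' @param path Path to a CSV file.
#' @param dialect Named list with `age_col` and one of `lx_col`, `qx_col`.
#' @return A [life_table].
#' @export
read_life_table <- function(path, dialect = list()) {
  dialect <- modifyList(list(age_col = "age", lx_col = NULL, qx_col = NULL),
                        dialect)
  if (is.null(dialect$lx_col) && is.null(dialect$qx_col)) dialect$lx_col <- "lx"
  # parse numbers via base strtod (correctly rounded) so tables written by
  # write_curve_csv round-trip bit-exactly
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  df[] <- lapply(df, as.numeric)
  need <- c(dialect$age_col, dialect$lx_col, dialect$qx_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "qalyvsl_format_error")
  }
  if (!is.null(dialect$lx_col)) {
    life_table(age = df[[dialect$age_col]], lx = df[[dialect$lx_col]])
  } else {
    life_table(age = df[[dialect$age_col]], qx = df[[dialect$qx_col]])
  }
}

#' Write a life table (or any age-value curve) as tidy CSV
#'
#' Numeric columns are written with 17 significant digits so that re-reading
#' reproduces the doubles bit-exactly.
#'
#' @param x A `life_table`, or any data frame of derived curves.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  df <- tibble::as_tibble(x)
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else col
  })
  readr::write_csv(df, path)
  invisible(path)
}

#' Conditional survival probability from a life table
#'
#' Returns \eqn{S(t, a) = l(t) / l(a)}, the probability that a person alive
#' at age `a` is still alive at age `t`, with linear interpolation of `lx`
#' between integer ages. Beyond the table's terminal age survival is 0, and
#' if `l(a) = 0` the result is 0 by convention.
#'
#' @param table A [life_table].
#' @param t Target age(s), each `>= a`.
#' @param a Conditioning age (scalar).
#' @return Numeric vector of probabilities, same length as `t`.
#' @export
survival_prob <- function(table, t, a) {
  stopifnot(inherits(table, "life_table"))
  if (length(a) != 1 || any(t < a)) {
    abort("require scalar `a` and t >= a", class = "qalyvsl_domain_error")
  }
  la <- lx_at(table, a)
  if (la <= 0) return(rep(0, length(t)))
  pmin(1, pmax(0, lx_at(table, t) / la))
}

# lx with linear interpolation; 0 outside [0, terminal_age]
lx_at <- function(table, x) {
  term <- attr(table, "terminal_age")
  y <- approx(table$age, table$lx, xout = pmin(x, term), rule = 2)$y
  y[x > term] <- 0
  y
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table> terminal age ", attr(x, "terminal_age"), "\n", sep = "")
  NextMethod()
}
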