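#' Population life tables
#'
#' A `lifetable` stores annual all-cause mortality hazard rates of a general
#' population, indexed by attained age (integer years), calendar year and sex.
#' It supplies the expected (population) hazard \eqn{\lambda_P} used to split
#' a cancer cohort's overall hazard into excess and other-cause components,
#' and the expected survival \eqn{ES(T) = \exp(-\Lambda_P(T))}.
#'
#' Rates are treated as piecewise constant within integer age x calendar-year
#' cells: a patient diagnosed at age `a` in year `y` experiences, at
#' follow-up time `t`, the rate stored at age `floor(a + t)` and year
#' `floor(y + t)`. Lookups outside the declared ranges are clamped to the
#' nearest table boundary (cancer-registry predictions routinely run past
#' the table edge); clamped lookups are counted and reported once per call
#' via a warning.
#'
#' @name lifetable
NULL

new_lifetable <- function(rates, ages, years, sexes) {
  stopifnot(is.list(rates), length(rates) == length(sexes))
  structure(
    list(rates = rates, ages = ages, years = years, sexes = sexes),
    class = "lifetable"
  )
}

#' Read a population life table from a long-format CSV
#'
#' Expects columns `age`, `year`, `sex`, `value`. Values may be annual
#' mortality hazard rates (per person-year) or annual death probabilities
#' `q`; probabilities are converted to rates as \eqn{-\log(1 - q)}.
#'
#' @param path path to a CSV file.
#' @param value_kind `"rate"` or `"annual_probability"`.
#' @return a `lifetable` object.
#' @export
read_lifetable <- function(path, value_kind = c("rate", "annual_probability")) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("life table file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("age", "year", "sex", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("life table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("age", "year", "sex")]))
    stop("duplicate (age, year, sex) entries in life table")
  if (value_kind == "annual_probability") {
    if (any(df$value >= 1 | df$value < 0))
      stop("annual probabilities must lie in [0, 1); q >= 1 implies an infinite rate")
    df$value <- -log1p(-df$value)
  }
  if (any(df$value < 0)) stop("negative mortality rates in life table")
  lifetable_from_frame(df)
}

lifetable_from_frame <- function(df) {
  ages <- sort(unique(df$age))
  years <- sort(unique(df$year))
  sexes <- sort(unique(as.character(df$sex)))
  if (!all(diff(ages) == 1L) || !all(diff(years) == 1L))
    stop("life table grid must cover consecutive integer ages and years")
  rates <- lapply(sexes, function(s) {
    sub <- df[df$sex == s, ]
    if (nrow(sub) != length(ages) * length(years))
      stop("life table grid not rectangular for sex '", s, "'")
    m <- matrix(NA_real_, length(ages), length(years),
                dimnames = list(ages, years))
    m[cbind(match(sub$age, ages), match(sub$year, years))] <- sub$value
    m
  })
  names(rates) <- sexes
  new_lifetable(rates, ages, years, sexes)
}

#' Build a synthetic Gompertz life table
#'
#' Rates follow \eqn{\lambda_P(a) = r_0 e^{g a}} at age `a`, constant across
#' calendar years. Used as a stand-in for national life tables in tests and
#' simulations.
#'
#' @param r0 hazard rate at age 0 (per person-year), > 0 (0 allowed for the
#'   degenerate no-mortality table used in oracles).
#' @param g Gompertz log-slope per year of age, >= 0.
#' @param ages,years integer vectors defining the grid.
#' @param sexes sex levels to replicate the rates over.
#' @return a `lifetable` object.
#' @export
make_synthetic_lifetable <- function(r0, g, ages = 0:99, years = 2007:2019,
                                     sexes = "female") {
  stopifnot(r0 >= 0, g >= 0)
  col <- r0 * exp(g * ages)
  m <- matrix(col, length(ages), length(years),
              dimnames = list(ages, years))
  rates <- rep(list(m), length(sexes))
  names(rates) <- sexes
  new_lifetable(rates, ages, years, sexes)
}

#' @export
print.lifetable <- function(x, ...) {
  cat("Population life table\n")
  cat("  ages ", min(x$ages), "-", max(x$ages),
      ", years ", min(x$years), "-", max(x$years),
      ", sexes: ", paste(x$sexes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

clamp_index <- function(value, range) {
  pmin(pmax(value, range[1]), range[length(range)])
}

#' Expected (population) hazard for a patient at follow-up time t
#'
#' Returns \eqn{\lambda_P} at attained age `floor(age_dx + t)` and calendar
#' year `floor(year_dx + t)`, clamped to the table ranges. Vectorised over
#' `t` (and over `age_dx`/`year_dx` if of matching length).
#'
#' @param table a `lifetable`.
#' @param age_dx age at diagnosis in years (continuous).
#' @param year_dx calendar year of diagnosis.
#' @param t years since diagnosis, >= 0.
#' @param sex sex level present in the table.
#' @return hazard rate(s) per person-year.
#' @export
expected_hazard <- function(table, age_dx, year_dx, t, sex = "female") {
  stopifnot(inherits(table, "lifetable"), all(t >= 0))
  sex <- as.character(sex)
  if (!sex %in% table$sexes)
    stop("sex '", sex, "' not present in life table")
  age <- floor(age_dx + t)
  yr <- floor(year_dx + t)
  n_clamped <- sum(age < min(table$ages) | age > max(table$ages) |
                     yr < min(table$years) | yr > max(table$years))
  if (n_clamped > 0)
    warning(n_clamped, " lookup(s) outside life-table range; clamped to boundary")
  age <- clamp_index(age, range(table$ages))
  yr <- clamp_index(yr, range(table$years))
  m <- table$rates[[sex]]
  out <- m[cbind(age - min(table$ages) + 1L, yr - min(table$years) + 1L)]
  structure(out, n_clamped = n_clamped)
}

#' Expected survival of an individual under population mortality
#'
#' Accumulates the population cumulative hazard \eqn{\Lambda_P} by
#' piecewise-constant integration of [expected_hazard()] over the grid and
#' returns \eqn{ES = \exp(-\Lambda_P)}.
#'
#' @param table a `lifetable`.
#' @param age_dx,year_dx age and calendar year at diagnosis.
#' @param grid increasing time grid starting at 0 (years since diagnosis).
#' @param sex sex level present in the table.
#' @return an `expected_curve`: data frame with columns `time`, `cum_hazard`,
#'   `es`.
#' @export
expected_survival_individual <- function(table, age_dx, year_dx, grid,
                                         sex = "female") {
  check_grid(grid)
  cum <- cumulative_expected_hazard(table, age_dx, year_dx, grid, sex)
  structure(
    data.frame(time = grid, cum_hazard = cum, es = exp(-cum)),
    class = c("expected_curve", "data.frame")
  )
}

check_grid <- function(grid) {
  if (length(grid) < 2 || grid[1] != 0 || any(diff(grid) <= 0))
    stop("grid must start at 0 and be strictly increasing")
  invisible(grid)
}

# Lambda_P on the grid: left-endpoint rule is exact here because the hazard
# is piecewise constant on integer age/year cells; intervals are assumed not
# to straddle a cell boundary by more than the step (monthly default).
cumulative_expected_hazard <- function(table, age_dx, year_dx, grid, sex) {
  starts <- grid[-length(grid)]
  haz <- suppressWarnings(
    as.numeric(expected_hazard(table, age_dx, year_dx, starts, sex))
  )
  c(0, cumsum(haz * diff(grid)))
}

#' Expected survival of a cohort (Ederer II cohort method)
#'
#' \eqn{ES(T)} is the mean over patients of the individual expected-survival
#' curves; every patient contributes to the common horizon (no censoring of
#' the expected curve).
#'
#' @param table a `lifetable`.
#' @param cohort a `cohort` (see [read_cohort()]).
#' @param grid increasing time grid starting at 0.
#' @return an `expected_curve` data frame with columns `time`, `cum_hazard`
#'   (implied \eqn{-\log ES}), `es`.
#' @export
expected_survival_cohort <- function(table, cohort, grid) {
  check_grid(grid)
  if (nrow(cohort) == 0) stop("cohort is empty")
  curves <- vapply(
    seq_len(nrow(cohort)),
    function(i) exp(-cumulative_expected_hazard(
      table, cohort$age_dx[i], cohort$year_dx[i], grid,
      as.character(cohort$sex[i])
    )),
    numeric(length(grid))
  )
  es <- rowMeans(curves)
  structure(
    data.frame(time = grid, cum_hazard = -log(es), es = es),
    class = c("expected_curve", "data.frame")
  )
}
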