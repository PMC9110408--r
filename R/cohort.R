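#' Cohort input, validation and adherence classification
#'
#' A `cohort` is a validated data frame with one row per patient and the
#' canonical columns `id`, `age_dx`, `sex`, `year_dx`, `stage`, `her2`,
#' `er`, `pr`, `adherence_rate`, `followup_years`, `dead` (plus, for
#' simulated cohorts, `true_cause`, which the estimators never read).
#' Follow-up is measured in years as a real number; no date arithmetic
#' happens inside the estimators.
#'
#' @name cohort
NULL

COHORT_COLUMNS <- c("id", "age_dx", "sex", "year_dx", "stage", "her2",
                    "er", "pr", "adherence_rate", "followup_years", "dead")

STAGE_LEVELS <- c("I", "II", "III", "IV")

normalize_stage <- function(x) {
  x <- toupper(trimws(as.character(x)))
  arabic <- c("1" = "I", "2" = "II", "3" = "III", "4" = "IV")
  x[x %in% names(arabic)] <- arabic[x[x %in% names(arabic)]]
  x[!x %in% STAGE_LEVELS] <- NA_character_
  factor(x, levels = STAGE_LEVELS)
}

normalize_posneg <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("pos", "positive", "+", "1", "yes")] <- "pos"
  x[x %in% c("neg", "negative", "-", "0", "no")] <- "neg"
  x[!x %in% c("pos", "neg")] <- NA_character_
  factor(x, levels = c("neg", "pos"))
}

new_cohort <- function(df, provenance = character()) {
  structure(df, class = c("cohort", "data.frame"), provenance = provenance)
}

#' Read and validate a cohort CSV
#'
#' One header row; canonical columns as in [cohort]; UTF-8 with "." decimal
#' separator. `schema` maps canonical names to the file's column names when
#' they differ, e.g. `c(age_dx = "age_at_diagnosis")`.
#'
#' Rows whose required fields do not parse (non-numeric age or follow-up,
#' negative follow-up, adherence outside [0,1]) abort with row-level
#' diagnostics rather than being silently dropped.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector, canonical -> file column.
#' @return a `cohort`.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- stats::setNames(COHORT_COLUMNS, COHORT_COLUMNS)
  if (!is.null(schema)) cols[names(schema)] <- schema
  missing_cols <- cols[!cols %in% names(raw)]
  if (length(missing_cols))
    stop("cohort file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- stats::setNames(raw[, cols, drop = FALSE], names(cols))
  as_cohort(df, provenance = paste0("read from ", path))
}

#' Coerce a data frame to a validated cohort
#'
#' @param df data frame with the canonical cohort columns.
#' @param provenance free-text note recorded on the object.
#' @return a `cohort`.
#' @export
as_cohort <- function(df, provenance = "constructed in R") {
  miss <- setdiff(COHORT_COLUMNS, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("patient ids are not unique")
  num_field <- function(x, name, allow_na = FALSE) {
    out <- suppressWarnings(as.numeric(x))
    bad <- is.na(out) & !(allow_na & (is.na(x) | x == ""))
    if (any(bad))
      stop("non-numeric ", name, " in row(s): ",
           paste(utils::head(which(bad), 10), collapse = ", "))
    out
  }
  df$age_dx <- num_field(df$age_dx, "age_dx")
  df$year_dx <- num_field(df$year_dx, "year_dx")
  df$followup_years <- num_field(df$followup_years, "followup_years")
  df$adherence_rate <- num_field(df$adherence_rate, "adherence_rate",
                                 allow_na = TRUE)
  if (any(df$followup_years < 0))
    stop("negative followup_years in row(s): ",
         paste(which(df$followup_years < 0), collapse = ", "))
  bad_adh <- !is.na(df$adherence_rate) &
    (df$adherence_rate < 0 | df$adherence_rate > 1)
  if (any(bad_adh))
    stop("adherence_rate outside [0, 1] in row(s): ",
         paste(which(bad_adh), collapse = ", "))
  if (any(!is.finite(df$age_dx + df$followup_years)))
    stop("non-finite age_dx + followup_years")
  df$sex <- factor(tolower(as.character(df$sex)), levels = c("female", "male"))
  df$stage <- normalize_stage(df$stage)
  df$her2 <- normalize_posneg(df$her2)
  df$er <- normalize_posneg(df$er)
  df$pr <- normalize_posneg(df$pr)
  dead_raw <- tolower(trimws(as.character(df$dead)))
  df$dead <- ifelse(dead_raw %in% c("1", "true", "yes"), TRUE,
                    ifelse(dead_raw %in% c("0", "false", "no"), FALSE, NA))
  if (any(is.na(df$dead))) stop("vital status (dead) must be 0/1 or TRUE/FALSE")
  new_cohort(as.data.frame(df, stringsAsFactors = FALSE), provenance)
}

#' Refill history of endocrine-therapy prescriptions
#'
#' Day 0 is the first prescription refill. `intervals` is a two-column
#' matrix (start_day, end_day) of periods covered by filled prescriptions;
#' `end_of_observation_day` is min(5 years, day of death/recurrence).
#'
#' @param intervals numeric matrix or two-column data frame of covered
#'   (start, end) days.
#' @param end_of_observation_day positive number of days observed.
#' @return a `refill_history`.
#' @export
refill_history <- function(intervals, end_of_observation_day) {
  intervals <- as.matrix(intervals)
  if (length(intervals) && ncol(intervals) != 2)
    stop("intervals must have two columns (start_day, end_day)")
  if (end_of_observation_day <= 0)
    stop("end_of_observation_day must be positive")
  structure(list(intervals = intervals,
                 end_of_observation_day = end_of_observation_day),
            class = "refill_history")
}

merge_intervals <- function(m) {
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      k <- nrow(out)
      if (m[i, 1] <= out[k, 2]) {
        out[k, 2] <- max(out[k, 2], m[i, 2])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  out
}

#' Adherence rate as proportion of days covered
#'
#' Proportion of days covered by a filled prescription over the treatment
#' period. A gap of more than `gap_days` days between consecutive coverage
#' intervals counts as discontinuation of therapy: coverage is truncated at
#' the start of the first such gap (persistence interpretation). Switching
#' between drugs is continuation, so intervals need not be labelled by drug.
#'
#' @param history a [refill_history()].
#' @param gap_days discontinuation threshold; "more than two months"
#'   operationalised as > 61 days.
#' @return proportion in [0, 1].
#' @export
compute_adherence_rate <- function(history, gap_days = 61) {
  stopifnot(inherits(history, "refill_history"))
  m <- history$intervals
  end <- history$end_of_observation_day
  if (!length(m) || nrow(m) == 0) {
    warning("empty refill history; adherence rate 0")
    return(0)
  }
  if (any(m[, 2] > end) || any(m[, 1] < 0)) {
    warning("refill intervals clipped to [0, end_of_observation_day]")
    m[, 1] <- pmax(m[, 1], 0)
    m[, 2] <- pmin(m[, 2], end)
    m <- m[m[, 2] > m[, 1], , drop = FALSE]
    if (nrow(m) == 0) {
      warning("no coverage within the observation window; adherence rate 0")
      return(0)
    }
  }
  m <- merge_intervals(m)
  covered <- m[1, 2] - m[1, 1]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      if (m[i, 1] - m[i - 1, 2] > gap_days) break  # discontinued at the gap
      covered <- covered + (m[i, 2] - m[i, 1])
    }
  }
  covered / end
}

#' Classify an adherence rate
#'
#' Adherent strictly above the 80% proportion-of-days-covered cutoff;
#' a rate of exactly 0.80 is non-adherent.
#'
#' @param rate proportion in [0, 1] (vectorised).
#' @param cutoff classification cutoff, default 0.8.
#' @return factor with levels `non_adherent`, `adherent`.
#' @export
classify_adherence <- function(rate, cutoff = 0.8) {
  if (any(rate < 0 | rate > 1, na.rm = TRUE))
    stop("adherence rate must lie in [0, 1]")
  factor(ifelse(rate > cutoff, "adherent", "non_adherent"),
         levels = c("non_adherent", "adherent"))
}

#' Apply the study inclusion criteria
#'
#' Sequentially removes: estrogen-receptor-negative patients; stage IV or
#' missing stage; age at diagnosis >= 85; missing adherence rate. These are
#' the selection rules for a hormone receptor-positive, stage I-III,
#' endocrine-therapy-eligible study population.
#'
#' @param cohort a `cohort`.
#' @return list with elements `cohort` (filtered) and `log` (data frame
#'   with columns `rule`, `n_removed`, `n_remaining`, in application order).
#' @export
apply_inclusion_criteria <- function(cohort) {
  rules <- list(
    er_negative = function(d) !is.na(d$er) & d$er == "pos",
    stage_iv_or_missing = function(d) !is.na(d$stage) & d$stage %in% c("I", "II", "III"),
    age_85_or_over = function(d) d$age_dx < 85,
    missing_adherence = function(d) !is.na(d$adherence_rate)
  )
  log <- data.frame(rule = character(), n_removed = integer(),
                    n_remaining = integer(), stringsAsFactors = FALSE)
  d <- cohort
  for (nm in names(rules)) {
    keep <- rules[[nm]](d)
    log <- rbind(log, data.frame(rule = nm, n_removed = sum(!keep),
                                 n_remaining = sum(keep)))
    d <- d[keep, , drop = FALSE]
  }
  if (nrow(d) == 0) warning("no patients remain after inclusion criteria")
  d$stage <- droplevels(d$stage)
  prov <- c(attr(cohort, "provenance"),
            sprintf("inclusion criteria applied: %d -> %d",
                    nrow(cohort), nrow(d)))
  list(cohort = new_cohort(d, prov), log = log)
}

#' Write an exclusion log as JSON
#'
#' @param log the `log` component of [apply_inclusion_criteria()].
#' @param path output path.
#' @export
write_exclusion_log <- function(log, path) {
  jsonlite::write_json(log, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Baseline characteristics table by group
#'
#' Per-level counts and percentages for categorical fields and mean (SD)
#' for continuous fields, compared across the levels of `by` with
#' chi-square tests (categorical) and two-sample t-tests (continuous),
#' flagged at alpha = 0.05.
#'
#' @param cohort a `cohort`.
#' @param by name of a categorical cohort column to group by.
#' @param vars columns to summarise; defaults to the standard clinical set.
#' @return data frame with one row per variable/level: columns `variable`,
#'   `level`, one count/mean column per group, `p_value`, `significant`.
#' @export
summarize_cohort <- function(cohort, by,
                             vars = c("age_dx", "stage", "her2", "pr",
                                      "adherence_rate", "dead")) {
  g <- cohort[[by]]
  if (is.null(g)) stop("unknown grouping variable: ", by)
  g <- droplevels(factor(g))
  if (any(table(g) == 0)) message("dropping group level(s) with zero observations")
  vars <- setdiff(vars, by)
  rows <- list()
  for (v in vars) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      ms <- tapply(x, g, function(z) sprintf("%.1f (%.1f)",
                                             mean(z, na.rm = TRUE),
                                             stats::sd(z, na.rm = TRUE)))
      p <- if (nlevels(g) == 2)
        stats::t.test(x ~ g)$p.value
      else
        stats::oneway.test(x ~ g)$p.value
      row <- data.frame(variable = v, level = "mean (SD)",
                        t(ms), p_value = p, check.names = FALSE)
      rows[[length(rows) + 1]] <- row
    } else {
      x <- droplevels(factor(x))
      tab <- table(x, g)
      p <- if (all(dim(tab) >= 2)) stats::chisq.test(tab)$p.value else NA_real_
      pct <- prop.table(tab, margin = 2) * 100
      cells <- matrix(sprintf("%d (%.1f%%)", tab, pct), nrow = nrow(tab),
                      dimnames = dimnames(tab))
      for (lv in rownames(cells)) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = lv, t(cells[lv, ]),
          p_value = if (lv == rownames(cells)[1]) p else NA_real_,
          check.names = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  rownames(out) <- NULL
  out
}

#' Write a cohort in the canonical CSV dialect
#'
#' @param cohort a `cohort`.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$dead <- as.integer(df$dead)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
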