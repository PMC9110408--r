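#' Survival indicators from the excess-hazard decomposition
#'
#' Given an all-cause (overall) hazard \eqn{\lambda_O} for a patient profile
#' and the population (expected) hazard \eqn{\lambda_P} from a life table,
#' the excess hazard attributed to the cancer is
#' \eqn{\lambda_X = \lambda_O - \lambda_P}. From these the package derives:
#' relative survival \eqn{RS(T) = OS(T)/ES(T)}; conditional five-year
#' relative survival \eqn{RS5(T) = RS(T+5)/RS(T)}; excess mortality
#' \eqn{EM(T) = (1 - RS5(T)) \times 100} (percent); and the crude
#' probabilities of death due to the cancer (\eqn{P_{BC}}) and due to other
#' causes (\eqn{P_{OC}}) in the presence of the competing cause.
#'
#' Crude probabilities accumulate over grid intervals with a left-endpoint
#' (product-limit style) rule whose discretisation is matched to the
#' survival decrement, so that \eqn{OS + P_{BC} + P_{OC} = 1} holds at
#' every grid point by construction.
#'
#' @name indicators
NULL

#' Relative survival
#'
#' Pointwise ratio \eqn{RS = OS/ES} on a common grid. Values above 1
#' (negative excess hazard) are permitted and counted in a warning.
#'
#' @param os data frame with columns `time`, `os`.
#' @param es data frame with columns `time`, `es`.
#' @return data frame with columns `time`, `rs`.
#' @export
relative_survival <- function(os, es) {
  if (nrow(os) != nrow(es) || any(abs(os$time - es$time) > 1e-9))
    stop("OS and ES curves are on different time grids")
  if (any(es$es <= 0)) stop("expected survival must be positive")
  rs <- os$os / es$es
  n_above <- sum(rs > 1 + 1e-12)
  if (n_above > 0)
    warning("relative survival exceeds 1 at ", n_above,
            " grid point(s) (negative excess hazard)")
  data.frame(time = os$time, rs = rs)
}

#' Conditional five-year relative survival
#'
#' \eqn{RS5(T) = RS(T+5)/RS(T)}: the patient's additional five-year
#' survival, conditional on having survived T years, relative to the
#' general population. Reported only for T with T + 5 inside the curve's
#' horizon; never extrapolated.
#'
#' @param rs data frame with columns `time`, `rs`.
#' @param window conditioning window in years (5 by convention).
#' @return data frame with columns `time`, `rs5`, covering the T for which
#'   T + `window` lies on the grid.
#' @export
conditional_rs5 <- function(rs, window = 5) {
  horizon <- max(rs$time)
  if (horizon < window)
    stop("curve horizon (", horizon, ") shorter than the ", window,
         "-year conditioning window")
  shifted <- match_times(rs$time + window, rs$time)
  keep <- !is.na(shifted)
  data.frame(time = rs$time[keep], rs5 = rs$rs[shifted[keep]] / rs$rs[keep])
}

match_times <- function(wanted, grid, tol = 1e-8) {
  idx <- findInterval(wanted + tol, grid)
  idx[idx == 0] <- NA_integer_
  ok <- !is.na(idx) & abs(grid[pmax(idx, 1)] - wanted) <= tol
  idx[!ok] <- NA_integer_
  idx
}

#' Excess mortality (percent)
#'
#' \eqn{EM(T) = (1 - RS5(T)) \times 100}: the percent excess risk of death,
#' over the following five years, of a patient who has survived T years,
#' compared with the general population.
#'
#' @param rs5 data frame with columns `time`, `rs5` (or a numeric vector of
#'   RS5 values).
#' @return same shape with `em` replacing (or added to) `rs5`.
#' @export
excess_mortality <- function(rs5) {
  if (is.numeric(rs5)) return((1 - rs5) * 100)
  data.frame(time = rs5$time, em = (1 - rs5$rs5) * 100)
}

#' Crude probabilities of death from cumulative hazards
#'
#' Low-level accumulator. Over each grid interval, with `OS` the
#' discretised overall survival at the interval start,
#' \deqn{\Delta P_{OC} = OS \cdot \Delta\Lambda_P, \quad
#'       \Delta P_{BC} = OS \cdot (\Delta\Lambda_O - \Delta\Lambda_P), \quad
#'       \Delta OS = -OS \cdot \Delta\Lambda_O,}
#' so \eqn{OS + P_{BC} + P_{OC} = 1} exactly at every grid point.
#' Negative excess-hazard increments are retained by default (the crude
#' cancer-death probability may then locally decrease); set
#' `clamp_negative_excess = TRUE` to floor them at zero.
#'
#' @param grid increasing time grid starting at 0.
#' @param cumhaz_obs cumulative overall hazard \eqn{\Lambda_O} on the grid
#'   (nondecreasing, 0 at 0).
#' @param cumhaz_pop cumulative population hazard \eqn{\Lambda_P} on the
#'   grid.
#' @param clamp_negative_excess floor negative excess increments at zero.
#' @return data frame with columns `time`, `os`, `p_bc`, `p_oc`.
#' @export
crude_probability_curves <- function(grid, cumhaz_obs, cumhaz_pop,
                                     clamp_negative_excess = FALSE) {
  check_grid(grid)
  stopifnot(length(cumhaz_obs) == length(grid),
            length(cumhaz_pop) == length(grid))
  d_obs <- diff(cumhaz_obs)
  d_pop <- diff(cumhaz_pop)
  if (any(d_obs < -1e-12))
    stop("overall cumulative hazard must be nondecreasing")
  d_exc <- d_obs - d_pop
  if (clamp_negative_excess) {
    d_exc <- pmax(d_exc, 0)
    d_obs <- d_exc + d_pop
  }
  n <- length(grid)
  os <- numeric(n); p_bc <- numeric(n); p_oc <- numeric(n)
  os[1] <- 1
  for (i in seq_len(n - 1)) {
    p_bc[i + 1] <- p_bc[i] + os[i] * d_exc[i]
    p_oc[i + 1] <- p_oc[i] + os[i] * d_pop[i]
    os[i + 1] <- os[i] * (1 - d_obs[i])
  }
  if (any(os < 0))
    warning("discretised survival went negative; refine the grid")
  data.frame(time = grid, os = os, p_bc = p_bc, p_oc = p_oc)
}

#' Full indicator set for one patient profile
#'
#' Assembles overall survival from a fitted Cox model, expected survival
#' from the life table, and the derived indicators (RS, RS5, EM, crude
#' probabilities of death) on a common grid.
#'
#' @param fit a `cox_fit`.
#' @param lifetable a `lifetable`.
#' @param profile list with `age`, `stage`, `her2`, `adherent`, and
#'   optionally `year_dx` (default 2008) and `sex` (default `"female"`).
#' @param horizon prediction horizon in years (default 10, the cohort's
#'   follow-up).
#' @param step grid step in years (default monthly).
#' @param clamp_negative_excess see [crude_probability_curves()].
#' @return an `indicator_curves` data frame with columns `time`, `os`,
#'   `es`, `rs`, `rs5`, `em`, `p_bc`, `p_oc` (`rs5`/`em` are `NA` beyond
#'   `horizon - 5`), and attributes `profile` and `horizon`.
#' @export
predict_profile <- function(fit, lifetable, profile, horizon = 10,
                            step = 1 / 12, clamp_negative_excess = FALSE) {
  profile <- complete_profile(profile)
  grid <- seq(0, horizon, by = step)
  cum_o <- cumhaz_profile(fit, profile, grid)
  cum_p <- cumulative_expected_hazard(lifetable, profile$age,
                                      profile$year_dx, grid, profile$sex)
  assemble_indicators(grid, cum_o, cum_p, profile, horizon,
                      clamp_negative_excess)
}

complete_profile <- function(profile) {
  if (is.null(profile$year_dx)) profile$year_dx <- 2008
  if (is.null(profile$sex)) profile$sex <- "female"
  profile
}

assemble_indicators <- function(grid, cum_o, cum_p, profile, horizon,
                                clamp_negative_excess = FALSE) {
  cp <- crude_probability_curves(grid, cum_o, cum_p, clamp_negative_excess)
  # ES uses the same product-limit discretisation as OS, so RS is exactly 1
  # whenever the overall and population hazards coincide on the grid
  es <- cumprod(c(1, 1 - diff(cum_p)))
  rs <- suppressWarnings(
    relative_survival(data.frame(time = grid, os = cp$os),
                      data.frame(time = grid, es = es))
  )
  out <- data.frame(time = grid, os = cp$os, es = es, rs = rs$rs,
                    rs5 = NA_real_, em = NA_real_,
                    p_bc = cp$p_bc, p_oc = cp$p_oc)
  if (horizon >= 5) {
    r5 <- conditional_rs5(rs)
    idx <- match_times(r5$time, grid)
    out$rs5[idx] <- r5$rs5
    out$em[idx] <- (1 - r5$rs5) * 100
  }
  structure(out, class = c("indicator_curves", "data.frame"),
            profile = profile, horizon = horizon)
}

#' Check the structural invariants of an indicator-curve set
#'
#' Verifies OS(0) = ES(0) = RS(0) = 1, zero crude probabilities at 0,
#' conservation OS + P_BC + P_OC = 1 at every grid point, nondecreasing
#' other-cause probability, and that RS5 is only reported up to
#' horizon - 5.
#'
#' @param ic an `indicator_curves` object.
#' @param tol conservation tolerance.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_indicator_curves <- function(ic, tol = 1e-9) {
  h <- attr(ic, "horizon")
  ok <- function(cond, msg) if (!cond) stop("indicator invariant violated: ", msg)
  ok(abs(ic$os[1] - 1) < tol && abs(ic$es[1] - 1) < tol &&
       abs(ic$rs[1] - 1) < tol, "OS(0) = ES(0) = RS(0) = 1")
  ok(abs(ic$p_bc[1]) < tol && abs(ic$p_oc[1]) < tol,
     "P_BC(0) = P_OC(0) = 0")
  ok(max(abs(ic$os + ic$p_bc + ic$p_oc - 1)) < tol,
     "OS + P_BC + P_OC = 1")
  ok(all(diff(ic$p_oc) >= -tol), "P_OC nondecreasing")
  ok(all(is.na(ic$rs5[ic$time > h - 5 + 1e-9])),
     "RS5 undefined beyond horizon - 5")
  invisible(TRUE)
}

#' Adherent versus non-adherent comparison for a profile
#'
#' Runs [predict_profile()] for both adherence arms of a base profile and
#' reports the crude cancer-death probabilities at the horizon, their
#' difference (non-adherent minus adherent), the fold-change in overall
#' survival, the relative reduction in the cancer-death probability, and
#' annual overall-survival percentages for bar-graph display.
#'
#' @param fit a `cox_fit`.
#' @param lifetable a `lifetable`.
#' @param profile_base profile without the `adherent` field.
#' @param horizon,step as in [predict_profile()].
#' @return list with `adherent`, `non_adherent` (indicator curves),
#'   `p_bc_adherent`, `p_bc_non_adherent`, `difference`,
#'   `os_fold_change`, `pbc_relative_reduction`, `bars`.
#' @export
compare_adherence <- function(fit, lifetable, profile_base, horizon = 10,
                              step = 1 / 12) {
  pa <- c(profile_base, list(adherent = TRUE))
  pn <- c(profile_base, list(adherent = FALSE))
  ic_a <- predict_profile(fit, lifetable, pa, horizon, step)
  ic_n <- predict_profile(fit, lifetable, pn, horizon, step)
  at_end <- nrow(ic_a)
  years <- 1:horizon
  ia <- match_times(years, ic_a$time)
  bars <- rbind(
    data.frame(time = years, arm = "adherent",
               percent_survival = round(100 * ic_a$os[ia], 1)),
    data.frame(time = years, arm = "non_adherent",
               percent_survival = round(100 * ic_n$os[ia], 1))
  )
  list(
    adherent = ic_a,
    non_adherent = ic_n,
    p_bc_adherent = ic_a$p_bc[at_end],
    p_bc_non_adherent = ic_n$p_bc[at_end],
    difference = pbc_difference(ic_n$p_bc[at_end], ic_a$p_bc[at_end]),
    os_fold_change = fold_change(ic_a$os[at_end], ic_n$os[at_end]),
    pbc_relative_reduction = relative_reduction(ic_a$p_bc[at_end],
                                                ic_n$p_bc[at_end]),
    bars = bars
  )
}

#' Reporting arithmetic helpers
#'
#' Small, exact report-layer computations: the crude-probability difference
#' between arms (non-adherent minus adherent), the fold-change in survival
#' between two arms, the relative reduction of a risk versus a reference,
#' and the percent risk reduction implied by a hazard ratio.
#'
#' @param p_non,p_adh crude probabilities (or percentages) per arm.
#' @param a,b survival values; the fold-change is `a / b`.
#' @param x,ref risk in the index and reference arm.
#' @param hr a hazard ratio.
#' @name report_arithmetic
NULL

#' @rdname report_arithmetic
#' @export
pbc_difference <- function(p_non, p_adh) p_non - p_adh

#' @rdname report_arithmetic
#' @export
fold_change <- function(a, b) a / b

#' @rdname report_arithmetic
#' @export
relative_reduction <- function(x, ref) 1 - x / ref

#' @rdname report_arithmetic
#' @export
risk_reduction_pct <- function(hr) (1 - hr) * 100

#' Per-stage adherent vs non-adherent crude-probability table
#'
#' For each stage, the crude cancer-death probability at the horizon in
#' each adherence arm, pooled over the cohort's empirical age distribution
#' (or evaluated at a fixed reference age), and their difference.
#' Percentages are reported on the 0-100 scale.
#'
#' @param fit a `cox_fit`.
#' @param lifetable a `lifetable`.
#' @param cohort cohort supplying the age distribution (and per-arm Ns).
#' @param horizon years (default 10).
#' @param her2 HER2 level for the evaluated profiles.
#' @param fixed_age if non-`NULL`, evaluate at this age instead of pooling.
#' @param step grid step.
#' @return data frame with one row per stage: `stage`, `n_adherent`,
#'   `n_non_adherent`, `p_bc_adherent`, `p_bc_non_adherent`, `difference`.
#' @export
stage_comparison_table <- function(fit, lifetable, cohort, horizon = 10,
                                   her2 = "neg", fixed_age = NULL,
                                   step = 1 / 12) {
  data <- as.data.frame(cohort)
  adh <- classify_adherence(data$adherence_rate)
  rows <- lapply(c("I", "II", "III"), function(st) {
    in_stage <- data$stage == st
    ages <- if (is.null(fixed_age)) data$age_dx[in_stage] else fixed_age
    years <- if (is.null(fixed_age)) data$year_dx[in_stage] else 2008
    if (length(years) == 1) years <- rep(years, length(ages))
    pbc_arm <- function(adherent) {
      vals <- vapply(seq_along(ages), function(i) {
        ic <- predict_profile(fit, lifetable,
                              list(age = ages[i], stage = st, her2 = her2,
                                   adherent = adherent, year_dx = years[i]),
                              horizon, step)
        ic$p_bc[nrow(ic)]
      }, numeric(1))
      mean(vals)
    }
    pa <- 100 * pbc_arm(TRUE)
    pn <- 100 * pbc_arm(FALSE)
    data.frame(stage = st,
               n_adherent = sum(in_stage & adh == "adherent"),
               n_non_adherent = sum(in_stage & adh == "non_adherent"),
               p_bc_adherent = pa, p_bc_non_adherent = pn,
               difference = pbc_difference(pn, pa))
  })
  do.call(rbind, rows)
}

#' Nonparametric bootstrap percentile confidence interval
#'
#' Resamples patients with replacement, recomputes a statistic per
#' replicate, and returns the 2.5/97.5 percentile interval. Replicates in
#' which the statistic fails (e.g. a model refit does not converge) are
#' dropped and counted; more than 10% failures is an error.
#'
#' @param cohort a `cohort`.
#' @param statistic function taking a resampled `cohort` and returning a
#'   numeric scalar (or fixed-length vector).
#' @param B number of bootstrap replicates (>= 100).
#' @param seed RNG seed; a fixed seed makes the interval bit-reproducible.
#' @param conf confidence level.
#' @return list with `estimate` (statistic on the original cohort), `lo`,
#'   `hi`, `B`, `n_failed`.
#' @export
bootstrap_ci <- function(cohort, statistic, B = 1000, seed = 1,
                         conf = 0.95) {
  if (B < 100) stop("B must be at least 100")
  est <- statistic(cohort)
  n <- nrow(cohort)
  set.seed(seed)
  reps <- vector("list", B)
  n_failed <- 0
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- as.data.frame(cohort)[idx, , drop = FALSE]
    boot$id <- sprintf("boot%06d", seq_len(n))
    boot <- new_cohort(boot, provenance = "bootstrap resample")
    reps[[b]] <- tryCatch(statistic(boot), error = function(e) {
      n_failed <<- n_failed + 1
      NULL
    })
  }
  if (n_failed > 0.1 * B)
    stop("more than 10% of bootstrap replicates failed (", n_failed,
         " of ", B, ")")
  mat <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  alpha <- (1 - conf) / 2
  list(estimate = est,
       lo = apply(mat, 2, stats::quantile, probs = alpha, names = FALSE),
       hi = apply(mat, 2, stats::quantile, probs = 1 - alpha, names = FALSE),
       B = B, n_failed = n_failed)
}

#' Age trend of the crude cancer-death probability
#'
#' \eqn{P_{BC}} at fixed times (5 and 10 years by default) as a function of
#' age at diagnosis, per adherence arm, for one stage.
#'
#' @param fit a `cox_fit`.
#' @param lifetable a `lifetable`.
#' @param stage stage level.
#' @param ages ages at diagnosis to evaluate.
#' @param at_T evaluation times in years.
#' @param her2 HER2 level.
#' @param step grid step.
#' @return data frame with columns `age`, `arm`, `t`, `p_bc`.
#' @export
pbc_age_trend <- function(fit, lifetable, stage, ages, at_T = c(5, 10),
                          her2 = "neg", step = 1 / 12) {
  horizon <- max(at_T)
  rows <- list()
  for (arm in c("adherent", "non_adherent")) {
    for (a in ages) {
      ic <- predict_profile(fit, lifetable,
                            list(age = a, stage = stage, her2 = her2,
                                 adherent = arm == "adherent"),
                            horizon, step)
      idx <- match_times(at_T, ic$time)
      rows[[length(rows) + 1]] <-
        data.frame(age = a, arm = arm, t = at_T, p_bc = ic$p_bc[idx])
    }
  }
  do.call(rbind, rows)
}

#' Write indicator curves as CSV
#'
#' Columns `T`, `OS`, `ES`, `RS`, `RS5`, `EM`, `P_BC`, `P_OC`, full
#' precision.
#'
#' @param ic an `indicator_curves` object.
#' @param path output path.
#' @export
write_indicator_curves <- function(ic, path) {
  out <- data.frame(T = ic$time, OS = ic$os, ES = ic$es, RS = ic$rs,
                    RS5 = ic$rs5, EM = ic$em, P_BC = ic$p_bc,
                    P_OC = ic$p_oc)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
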