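#' All-cause proportional-hazards model designs
#'
#' Four Cox model designs for all-cause mortality in a hormone
#' receptor-positive cohort, differing in the coding of age at diagnosis
#' and of endocrine-therapy adherence:
#' \describe{
#'   \item{C1}{age categorical (<=49, 50-59, 60-74, 75-84), adherence
#'     constant}
#'   \item{C2}{age log-linear (one linear term in the log hazard),
#'     adherence constant}
#'   \item{C3}{age via restricted cubic splines, adherence constant}
#'   \item{C4}{age via restricted cubic splines, adherence time-varying
#'     with a cut at 5 years of follow-up (episode splitting)}
#' }
#' All designs adjust for stage (reference I) and HER2 status (reference
#' negative); adherence reference is non-adherent.
#'
#' @param design_id one of `"C1"`, `"C2"`, `"C3"`, `"C4"`.
#' @param n_knots spline knot count for C3/C4.
#' @param tv_cutoff follow-up time (years) at which the C4 adherence
#'   effect is allowed to change.
#' @return a `design_spec` list.
#' @export
cox_design <- function(design_id = c("C3", "C1", "C2", "C4"), n_knots = 3,
                       tv_cutoff = 5) {
  design_id <- match.arg(design_id)
  structure(list(
    design_id = design_id,
    age_coding = switch(design_id, C1 = "categorical", C2 = "log_linear",
                        "restricted_cubic_spline"),
    adherence_coding = if (design_id == "C4") "time_varying" else "constant",
    n_knots = n_knots,
    tv_cutoff = tv_cutoff
  ), class = "design_spec")
}

AGE_BREAKS <- c(20, 50, 60, 75, 85)
AGE_LABELS <- c("<=49", "50-59", "60-74", "75-84")

age_category <- function(age) {
  cut(age, breaks = AGE_BREAKS, labels = AGE_LABELS, right = FALSE,
      include.lowest = TRUE)
}

# Design matrix for the age/stage/her2(/constant adherence) part.
# Returns X plus metadata needed to rebuild a profile row at predict time.
age_stage_matrix <- function(data, design, knots = NULL) {
  if (design$age_coding == "categorical") {
    ac <- age_category(data$age_dx)
    Xa <- stats::model.matrix(~ ac)[, -1, drop = FALSE]
    colnames(Xa) <- paste0("age", AGE_LABELS[-1])
    knots <- NULL
  } else if (design$age_coding == "log_linear") {
    Xa <- matrix(data$age_dx, ncol = 1, dimnames = list(NULL, "age"))
    knots <- NULL
  } else {
    B <- rcs_basis(data$age_dx, knots = knots, n_knots = design$n_knots)
    knots <- attr(B, "knots")
    Xa <- B
    colnames(Xa) <- paste0("age_", colnames(B))
  }
  Xs <- cbind(stageII = as.numeric(data$stage == "II"),
              stageIII = as.numeric(data$stage == "III"))
  Xh <- cbind(her2pos = as.numeric(data$her2 == "pos"))
  term_map <- c(stats::setNames(rep("age", ncol(Xa)), colnames(Xa)),
                stageII = "stage", stageIII = "stage", her2pos = "her2")
  list(X = cbind(Xa, Xs, Xh), knots = knots, term_map = term_map)
}

#' Fit an all-cause Cox model to a cohort
#'
#' Maximises the Cox partial likelihood with Breslow tie handling via
#' [survival::coxph()] and stores the Breslow baseline cumulative hazard
#' (at covariate vector 0), coefficient covariance, log partial likelihood
#' and AIC. For design C4, each record is episode-split at the cutoff so
#' the adherence effect enters as two coefficients (`adherence_early` for
#' follow-up <= cutoff, `adherence_late` beyond).
#'
#' Patients are classified adherent/non-adherent from `adherence_rate`
#' with [classify_adherence()].
#'
#' @param cohort a `cohort` with at least one death.
#' @param design a [cox_design()] or a design id string.
#' @param ties tie-handling method, `"breslow"` (default) or `"efron"`.
#' @return a `cox_fit` object.
#' @export
fit_cox <- function(cohort, design = "C3", ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (is.character(design)) design <- cox_design(design)
  data <- as.data.frame(cohort)
  if (sum(data$dead) < 1) stop("no events in cohort")
  if (any(is.na(data$stage)) || any(is.na(data$her2)) ||
      any(is.na(data$adherence_rate)))
    stop("cohort has missing stage/her2/adherence; apply inclusion criteria first")
  data$adherent <- as.numeric(classify_adherence(data$adherence_rate) == "adherent")
  asm <- age_stage_matrix(data, design)
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 100)

  # covariates with no variation (e.g. a single-stage toy cohort) carry no
  # information for the partial likelihood and are dropped from the design
  drop_constant <- function(X, term_map) {
    keep <- apply(X, 2, function(col) stats::var(col) > 0)
    list(X = X[, keep, drop = FALSE], term_map = term_map[colnames(X)[keep]])
  }

  if (design$adherence_coding == "constant") {
    dc <- drop_constant(cbind(asm$X, adherent = data$adherent),
                        c(asm$term_map, adherent = "adherence"))
    X <- dc$X
    term_map <- dc$term_map
    sdat <- data.frame(time = data$followup_years, dead = data$dead)
    fit <- survival::coxph(survival::Surv(time, dead) ~ X, data = sdat,
                           ties = ties, control = ctrl, x = TRUE)
  } else {
    sdat <- data.frame(time = data$followup_years,
                       dead = as.integer(data$dead), adherent = data$adherent,
                       row = seq_len(nrow(data)))
    sp <- survival::survSplit(Surv(time, dead) ~ .,
                              data = sdat, cut = design$tv_cutoff,
                              episode = "episode")
    Xbase <- asm$X[sp$row, , drop = FALSE]
    dc <- drop_constant(cbind(Xbase,
                              adherence_early = sp$adherent * (sp$episode == 1),
                              adherence_late = sp$adherent * (sp$episode == 2)),
                        c(asm$term_map, adherence_early = "adherence",
                          adherence_late = "adherence"))
    X <- dc$X
    term_map <- dc$term_map
    fit <- survival::coxph(survival::Surv(tstart, time, dead) ~ X, data = sp,
                           ties = ties, control = ctrl, x = TRUE)
  }
  if (!is.null(fit$info) && isTRUE(grepl("infinite", fit$info)))
    stop("possible separation (monotone likelihood); simplify the design")
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  if (any(!is.finite(beta)))
    stop("Cox fit did not converge to finite coefficients ",
         "(possible separation / monotone likelihood)")
  V <- stats::vcov(fit)
  dimnames(V) <- list(names(beta), names(beta))
  bh <- survival::basehaz(fit, centered = FALSE)
  loglik <- fit$loglik[2]
  structure(list(
    design = design,
    beta = beta,
    vcov = V,
    baseline_cumhaz = data.frame(time = bh$time, hazard = bh$hazard),
    loglik = loglik,
    loglik_null = fit$loglik[1],
    aic = 2 * length(beta) - 2 * loglik,
    n = nrow(data),
    n_events = sum(data$dead),
    knots = asm$knots,
    term_map = term_map,
    age_range = range(data$age_dx),
    max_time = max(data$followup_years),
    fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox all-cause mortality model (design ", x$design$design_id, ")\n",
      sep = "")
  cat("  n = ", x$n, ", events = ", x$n_events,
      ", AIC = ", format(x$aic, digits = 6), "\n", sep = "")
  print(hazard_ratio_table(x), row.names = FALSE)
  invisible(x)
}

#' Hazard-ratio table with Wald 95% confidence intervals
#'
#' @param fit a `cox_fit`.
#' @param z normal quantile for the interval (1.96 for 95%).
#' @return data frame with columns `term`, `covariate`, `hr`, `lo`, `hi`.
#' @export
hazard_ratio_table <- function(fit, z = stats::qnorm(0.975)) {
  se <- sqrt(diag(fit$vcov))
  data.frame(
    term = names(fit$beta),
    covariate = unname(fit$term_map[names(fit$beta)]),
    hr = exp(fit$beta),
    lo = exp(fit$beta - z * se),
    hi = exp(fit$beta + z * se),
    row.names = NULL
  )
}

# Covariate row for a patient profile under a fit's design.
# profile: list(age, stage, her2 ("neg"/"pos"), adherent (logical))
profile_row <- function(fit, profile) {
  need <- c("age", "stage", "her2", "adherent")
  miss <- need[!need %in% names(profile)]
  if (length(miss))
    stop("profile missing covariate(s): ", paste(miss, collapse = ", "))
  design <- fit$design
  if (design$age_coding == "categorical") {
    lev <- as.character(age_category(profile$age))
    xa <- as.numeric(AGE_LABELS[-1] == lev)
    names(xa) <- paste0("age", AGE_LABELS[-1])
  } else if (design$age_coding == "log_linear") {
    xa <- c(age = profile$age)
  } else {
    B <- rcs_basis(profile$age, knots = fit$knots)
    xa <- stats::setNames(as.numeric(B), paste0("age_", colnames(B)))
  }
  x <- c(xa,
         stageII = as.numeric(profile$stage == "II"),
         stageIII = as.numeric(profile$stage == "III"),
         her2pos = as.numeric(profile$her2 == "pos"))
  adh <- as.numeric(isTRUE(profile$adherent) ||
                      identical(profile$adherent, "adherent") ||
                      identical(profile$adherent, 1))
  if (design$adherence_coding == "constant") {
    x <- c(x, adherent = adh)
  } else {
    x <- c(x, adherence_early = adh, adherence_late = adh)
  }
  x[names(fit$beta)]
}

# Baseline cumulative hazard evaluated on a grid (right-continuous step
# function; flat extension beyond the last event time).
baseline_at <- function(fit, times) {
  bh <- fit$baseline_cumhaz
  if (any(times > fit$max_time))
    warning("prediction beyond last follow-up time; baseline hazard ",
            "extended flat")
  stats::approx(c(0, bh$time), c(0, bh$hazard), xout = times,
                method = "constant", f = 0, rule = 2)$y
}

# Profile cumulative overall hazard Lambda_O(t) on a grid. For C4 the
# adherence effect switches at the cutoff, so the baseline is accumulated
# separately on each side.
cumhaz_profile <- function(fit, profile, grid) {
  x <- profile_row(fit, profile)
  if (fit$design$adherence_coding == "constant") {
    lp <- sum(x * fit$beta)
    return(baseline_at(fit, grid) * exp(lp))
  }
  cutoff <- fit$design$tv_cutoff
  x_early <- x; x_early["adherence_late"] <- 0
  x_late <- x; x_late["adherence_early"] <- 0
  lp_e <- sum(x_early * fit$beta)
  lp_l <- sum(x_late * fit$beta)
  b <- baseline_at(fit, grid)
  b_cut <- baseline_at(fit, cutoff)
  ifelse(grid <= cutoff,
         b * exp(lp_e),
         b_cut * exp(lp_e) + (b - b_cut) * exp(lp_l))
}

#' Predicted overall (all-cause) survival for a covariate profile
#'
#' \eqn{OS(T) = \exp(-\Lambda_0(T) e^{x\beta})} with the Breslow baseline
#' cumulative hazard step-interpolated on the grid (flat beyond the last
#' event time, with a warning).
#'
#' @param fit a `cox_fit`.
#' @param profile list with `age`, `stage` (`"I"`/`"II"`/`"III"`), `her2`
#'   (`"neg"`/`"pos"`), `adherent` (logical).
#' @param grid increasing time grid starting at 0 (years).
#' @return data frame with columns `time`, `cum_hazard`, `os`.
#' @export
predict_overall_survival <- function(fit, profile, grid) {
  check_grid(grid)
  ch <- cumhaz_profile(fit, profile, grid)
  data.frame(time = grid, cum_hazard = ch, os = exp(-ch))
}

#' Proportional-hazards diagnostic from scaled Schoenfeld residuals
#'
#' Scaled Schoenfeld residuals for one model term, shifted by the fitted
#' constant log hazard ratio so they estimate a time-varying coefficient
#' \eqn{\beta(t)}; smoothed by locally weighted regression (degree-1 loess)
#' with a pointwise 95% band. The effect is flagged proportional when the
#' band overlaps the constant \eqn{\hat\beta} everywhere.
#'
#' @param fit a `cox_fit` carrying its in-session [survival::coxph] fit.
#' @param term coefficient name, e.g. `"adherent"`.
#' @param smoother_fraction loess span as a fraction of events.
#' @return list with `data` (data frame: `time`, `residual`, `smooth`,
#'   `lower`, `upper`), `beta_constant`, and logical `proportional`.
#' @export
schoenfeld_diagnostic <- function(fit, term, smoother_fraction = 0.75) {
  if (is.null(fit$fit)) stop("diagnostics need the in-session fit (not a deserialized one)")
  if (!term %in% names(fit$beta)) stop("unknown term: ", term)
  if (fit$n_events < 10) stop("too few events (< 10) for a residual diagnostic")
  sr <- stats::residuals(fit$fit, type = "scaledsch")
  colnames(sr) <- names(fit$beta)
  times <- as.numeric(rownames(sr))
  if (is.null(times) || anyNA(times)) times <- sort(fit$fit$y[fit$fit$y[, ncol(fit$fit$y)] == 1, ncol(fit$fit$y) - 1])
  # scaled Schoenfeld residuals from survival already include the
  # coefficient, so they estimate beta(t) directly
  beta <- fit$beta[term]
  y <- sr[, term]
  ord <- order(times)
  lo <- stats::loess(y[ord] ~ times[ord], span = smoother_fraction, degree = 1)
  pr <- stats::predict(lo, se = TRUE)
  d <- data.frame(time = times[ord], residual = y[ord], smooth = pr$fit,
                  lower = pr$fit - 1.96 * pr$se.fit,
                  upper = pr$fit + 1.96 * pr$se.fit)
  # the displayed band is pointwise; the flag asks whether the constant
  # effect is rejected ANYWHERE, so it uses a simultaneous critical value,
  # Bonferroni-sized by the smoother's equivalent number of parameters
  # (the smooth has only ~enp independent excursions, not one per event)
  z_sim <- stats::qnorm(1 - 0.025 / max(lo$enp, 1))
  proportional <- all(abs(pr$fit - beta) <= z_sim * pr$se.fit)
  list(data = d, beta_constant = unname(beta), proportional = proportional)
}

#' Ratio of early to late adherence effects in the time-varying model
#'
#' For a C4 fit, the early (follow-up at or below the cutoff) and late
#' hazard ratios for adherence, and the ratio
#' \eqn{\exp(\beta_{early} - \beta_{late})} with a delta-method 95% CI.
#'
#' @param fit a `cox_fit` of design C4.
#' @return list with `hr_early`, `hr_late`, `ratio`, `lo`, `hi`.
#' @export
time_varying_ratio_test <- function(fit) {
  nms <- c("adherence_early", "adherence_late")
  if (!all(nms %in% names(fit$beta)))
    stop("fit lacks the two time-varying adherence coefficients")
  b <- fit$beta[nms]
  V <- fit$vcov[nms, nms]
  diff <- b[1] - b[2]
  se <- sqrt(V[1, 1] + V[2, 2] - 2 * V[1, 2])
  z <- stats::qnorm(0.975)
  list(hr_early = unname(exp(b[1])), hr_late = unname(exp(b[2])),
       ratio = unname(exp(diff)),
       lo = unname(exp(diff - z * se)), hi = unname(exp(diff + z * se)))
}

#' Rank fitted models by AIC
#'
#' @param ... `cox_fit` objects fitted to the same data.
#' @return data frame sorted ascending by AIC with the minimiser flagged.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "cox_fit"))
    fits <- fits[[1]]
  ev <- vapply(fits, function(f) f$n_events, numeric(1))
  if (length(unique(ev)) != 1)
    stop("models have different event counts; not fitted to the same data")
  tab <- data.frame(
    design = vapply(fits, function(f) f$design$design_id, character(1)),
    k = vapply(fits, function(f) length(f$beta), numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1))
  )
  tab <- tab[order(tab$aic), , drop = FALSE]
  tab$selected <- seq_len(nrow(tab)) == 1
  rownames(tab) <- NULL
  tab
}

#' Age-adjusted survival curves stratified by a categorical variable
#'
#' Fits a stratified Cox model with age (restricted cubic spline) as the
#' only covariate, then directly adjusts: each stratum's curve is the
#' average over the whole cohort's age distribution of the predicted
#' stratum-specific survival.
#'
#' @param cohort a `cohort`.
#' @param stratify_var name of a categorical cohort column (or
#'   `"adherence"` for the classified adherence groups).
#' @param grid time grid (default monthly to 10 years).
#' @param n_knots spline knots for the age adjustment.
#' @return long data frame with columns `stratum`, `time`, `survival`.
#' @export
adjusted_survival_curves <- function(cohort, stratify_var,
                                     grid = seq(0, 10, by = 1 / 12),
                                     n_knots = 3) {
  data <- as.data.frame(cohort)
  g <- if (stratify_var == "adherence")
    classify_adherence(data$adherence_rate)
  else droplevels(factor(data[[stratify_var]]))
  B <- rcs_basis(data$age_dx, n_knots = n_knots)
  knots <- attr(B, "knots")
  sdat <- data.frame(time = data$followup_years, dead = data$dead, g = g)
  fit <- survival::coxph(survival::Surv(time, dead) ~ B + strata(g),
                         data = sdat, ties = "breslow")
  bh <- survival::basehaz(fit, centered = FALSE)
  lp <- as.numeric(B %*% stats::coef(fit))
  out <- lapply(levels(g), function(lev) {
    sub <- bh[bh$strata == lev, ]
    if (!nrow(sub) || max(sub$hazard) == 0) {
      warning("stratum '", lev, "' has no events; curve flat at 1")
      H <- rep(0, length(grid))
    } else {
      H <- stats::approx(c(0, sub$time), c(0, sub$hazard), xout = grid,
                         method = "constant", f = 0, rule = 2)$y
    }
    surv <- vapply(H, function(h) mean(exp(-h * exp(lp))), numeric(1))
    data.frame(stratum = lev, time = grid, survival = surv)
  })
  do.call(rbind, out)
}

#' Nomogram points table
#'
#' Rescales each covariate's contribution to the linear predictor so the
#' covariate with the widest contribution range spans 100 points;
#' categorical covariates get points per level, the continuous age effect
#' is tabulated over the observed age range. The mapping back from total
#' points to the linear predictor is `lp = total_points / scale + offset`.
#'
#' @param fit a `cox_fit` (constant-adherence designs).
#' @param age_grid ages to tabulate for a continuous age effect.
#' @return list with `points` (data frame: `covariate`, `level`, `points`),
#'   `scale` (points per unit log hazard), `offset`.
#' @export
nomogram_points <- function(fit, age_grid = NULL) {
  contribs <- list()
  tm <- fit$term_map
  for (cov in unique(tm)) {
    terms <- names(tm)[tm == cov]
    if (cov == "age" && fit$design$age_coding != "categorical") {
      if (is.null(age_grid))
        age_grid <- seq(ceiling(fit$age_range[1]), floor(fit$age_range[2]))
      Xa <- if (fit$design$age_coding == "log_linear")
        matrix(age_grid, ncol = 1)
      else rcs_basis(age_grid, knots = fit$knots)
      vals <- as.numeric(Xa %*% fit$beta[terms])
      contribs[[cov]] <- stats::setNames(vals, as.character(age_grid))
    } else {
      levels <- switch(cov,
                       age = AGE_LABELS,
                       stage = c("I", "II", "III"),
                       her2 = c("neg", "pos"),
                       adherence = c("non_adherent", "adherent"))
      vals <- c(0, fit$beta[terms])
      contribs[[cov]] <- stats::setNames(vals, levels)
    }
  }
  ranges <- vapply(contribs, function(v) diff(range(v)), numeric(1))
  scale <- 100 / max(ranges)
  offset <- sum(vapply(contribs, min, numeric(1)))
  points <- do.call(rbind, lapply(names(contribs), function(cov) {
    v <- contribs[[cov]]
    data.frame(covariate = cov, level = names(v),
               points = (v - min(v)) * scale, row.names = NULL)
  }))
  list(points = points, scale = scale, offset = offset)
}

#' Serialize a fitted model to JSON
#'
#' Stores everything needed to reproduce predictions bit-for-bit:
#' coefficients, covariance, spline knots, Breslow baseline cumulative
#' hazard, AIC and the design id.
#'
#' @param fit a `cox_fit`.
#' @param path output path.
#' @export
write_fit <- function(fit, path) {
  obj <- list(
    design_id = fit$design$design_id,
    n_knots = fit$design$n_knots,
    tv_cutoff = fit$design$tv_cutoff,
    beta = as.list(fit$beta),
    vcov = unname(as.matrix(fit$vcov)),
    baseline_cumhaz = fit$baseline_cumhaz,
    knots = fit$knots,
    term_map = as.list(fit$term_map),
    loglik = fit$loglik,
    aic = fit$aic,
    n = fit$n,
    n_events = fit$n_events,
    age_range = fit$age_range,
    max_time = fit$max_time
  )
  # 17 significant digits round-trip IEEE doubles exactly, so predictions
  # from a deserialized fit are bit-identical
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' Read a serialized fit
#'
#' @param path path written by [write_fit()].
#' @return a `cox_fit` usable for prediction (not for residual
#'   diagnostics, which need the in-session fit).
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(obj$beta)
  V <- matrix(unlist(obj$vcov), nrow = length(beta),
              dimnames = list(names(beta), names(beta)))
  structure(list(
    design = cox_design(obj$design_id, n_knots = obj$n_knots,
                        tv_cutoff = obj$tv_cutoff),
    beta = beta,
    vcov = V,
    baseline_cumhaz = as.data.frame(obj$baseline_cumhaz),
    loglik = obj$loglik,
    aic = obj$aic,
    n = obj$n,
    n_events = obj$n_events,
    knots = obj$knots,
    term_map = unlist(obj$term_map),
    age_range = obj$age_range,
    max_time = obj$max_time,
    fit = NULL
  ), class = "cox_fit")
}
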