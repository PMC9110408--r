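# Fixtures built in code: small cohorts, toy Cox fits with known
# parameters, and temp CSVs.

make_cohort_df <- function(n, age = NULL, stage = NULL, her2 = NULL,
                           adherence = NULL, followup = NULL, dead = NULL,
                           year = 2008) {
  data.frame(
    id = sprintf("p%03d", seq_len(n)),
    age_dx = if (is.null(age)) seq(45, 75, length.out = n) else age,
    sex = "female",
    year_dx = year,
    stage = if (is.null(stage)) rep_len(c("I", "II", "III"), n) else stage,
    her2 = if (is.null(her2)) rep_len(c("neg", "pos"), n) else her2,
    er = "pos",
    pr = "pos",
    adherence_rate = if (is.null(adherence)) rep_len(c(0.9, 0.5), n) else adherence,
    followup_years = if (is.null(followup)) seq(1, 10, length.out = n) else followup,
    dead = if (is.null(dead)) rep_len(c(TRUE, FALSE), n) else dead,
    stringsAsFactors = FALSE
  )
}

write_temp_cohort <- function(df) {
  path <- tempfile(fileext = ".csv")
  df$dead <- as.integer(df$dead)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Two-group exponential survival cohort: group coded through stage II vs I,
# true all-cause hazard rate_base * ratio^(stage II), admin censoring.
simulate_two_group <- function(n, rate_base, ratio, seed, cens = 12) {
  set.seed(seed)
  grp <- runif(n) < 0.5
  tt <- rexp(n, rate_base * ifelse(grp, ratio, 1))
  make_cohort_df(n,
                 age = runif(n, 40, 80),
                 stage = ifelse(grp, "II", "I"),
                 her2 = "neg", adherence = 0.9,
                 followup = pmin(tt, cens), dead = tt <= cens)
}

# A cox_fit-like object with fully controlled coefficients and a linear
# baseline cumulative hazard rate0 * t, age log-linear design, for tests
# that need exact hazards rather than estimated ones.
make_toy_fit <- function(beta = c(age = 0, stageII = 0, stageIII = 0,
                                  her2pos = 0, adherent = 0),
                         rate0 = 0.05, max_time = 15) {
  # baseline knots generated by the same seq() expression as the monthly
  # prediction grid, so step interpolation is float-exact at grid points
  times <- seq(0, max_time, by = 1 / 12)[-1]
  V <- diag(1e-4, length(beta), length(beta))
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(
    design = cox_design("C2"),
    beta = beta,
    vcov = V,
    baseline_cumhaz = data.frame(time = times, hazard = rate0 * times),
    loglik = -1, loglik_null = -1,
    aic = 2 * length(beta) + 2,
    n = 100, n_events = 50,
    knots = NULL,
    term_map = c(age = "age", stageII = "stage", stageIII = "stage",
                 her2pos = "her2", adherent = "adherence"),
    age_range = c(30, 85),
    max_time = max_time,
    fit = NULL
  ), class = "cox_fit")
}

flat_lifetable <- function(rate, ages = 0:99, years = 2000:2030) {
  make_synthetic_lifetable(r0 = rate, g = 0, ages = ages, years = years)
}
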