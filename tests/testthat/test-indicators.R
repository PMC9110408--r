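monthly <- seq(0, 10, by = 1 / 12)

test_that("relative survival is the pointwise OS/ES ratio", {
  os <- data.frame(time = monthly, os = exp(-0.06 * monthly))
  es <- data.frame(time = monthly, es = exp(-0.01 * monthly))
  rs <- relative_survival(os, es)
  expect_equal(rs$rs[rs$time == 10], exp(-0.5), tolerance = 1e-12)
  expect_equal(relative_survival(os, data.frame(time = monthly,
                                                es = os$os))$rs,
               rep(1, length(monthly)))
  expect_warning(relative_survival(es |> setNames(c("time", "os")),
                                   os |> setNames(c("time", "es"))),
                 "exceeds 1")
  expect_error(relative_survival(os, es[-1, ]), "grids")
})

test_that("conditional five-year relative survival shifts the RS curve", {
  rs <- data.frame(time = monthly, rs = exp(-0.02 * monthly))
  r5 <- conditional_rs5(rs)
  expect_equal(r5$rs5[r5$time == 3], exp(-0.1), tolerance = 1e-12)
  # defined exactly for T <= horizon - 5
  expect_equal(max(r5$time), 5)
  # statistical cure: RS constant after T0 gives RS5 = 1 there
  rs2 <- data.frame(time = monthly,
                    rs = pmax(exp(-0.05 * pmin(monthly, 2)), 0))
  r52 <- conditional_rs5(rs2)
  expect_equal(r52$rs5[r52$time >= 2], rep(1, sum(r52$time >= 2)))
  expect_error(conditional_rs5(data.frame(time = 0:4, rs = 1)), "horizon")
})

test_that("excess mortality is (1 - RS5) x 100", {
  expect_equal(excess_mortality(0.752), 24.8)
  expect_equal(excess_mortality(1), 0)
  expect_equal(excess_mortality(0.95), 5)
  df <- excess_mortality(data.frame(time = 0:2, rs5 = c(1, 0.9, 0.8)))
  expect_equal(df$em, c(0, 10, 20), tolerance = 1e-12)
})

test_that("crude probabilities match the competing-exponentials closed form", {
  lam_x <- 0.05; lam_p <- 0.01; lam <- lam_x + lam_p
  cp <- crude_probability_curves(monthly, lam * monthly, lam_p * monthly)
  pbc_true <- lam_x / lam * (1 - exp(-lam * 10))
  poc_true <- lam_p / lam * (1 - exp(-lam * 10))
  expect_lt(abs(cp$p_bc[cp$time == 10] - pbc_true), 1e-3)
  expect_lt(abs(cp$p_oc[cp$time == 10] - poc_true), 1e-3)
  expect_equal(pbc_true, 0.3760, tolerance = 1e-4)
  expect_equal(poc_true, 0.0752, tolerance = 1e-4)
})

test_that("degenerate hazard channels reduce to the marginal curves", {
  # zero excess: P_BC = 0 and P_OC = 1 - ES (discretised)
  cp <- crude_probability_curves(monthly, 0.02 * monthly, 0.02 * monthly)
  expect_equal(cp$p_bc, rep(0, length(monthly)), tolerance = 1e-14)
  expect_equal(cp$p_oc, 1 - cp$os, tolerance = 1e-12)
  # zero population hazard: P_OC = 0 and P_BC = 1 - OS
  cp2 <- crude_probability_curves(monthly, 0.05 * monthly, 0 * monthly)
  expect_equal(cp2$p_oc, rep(0, length(monthly)))
  expect_equal(cp2$p_bc, 1 - cp2$os, tolerance = 1e-12)
  expect_error(crude_probability_curves(monthly, -0.01 * monthly,
                                        0 * monthly), "nondecreasing")
})

test_that("conservation holds to 1e-9 for random hazard pairs", {
  set.seed(99)
  for (i in 1:20) {
    a <- runif(1, 0.01, 0.2); b <- runif(1, 0.01, 0.2)
    cp <- crude_probability_curves(monthly, (a + b) * monthly, b * monthly)
    expect_lt(max(abs(cp$os + cp$p_bc + cp$p_oc - 1)), 1e-9)
  }
})

test_that("halving the grid step changes P_BC(10) by less than 5e-4", {
  half <- seq(0, 10, by = 1 / 24)
  cp1 <- crude_probability_curves(monthly, 0.06 * monthly, 0.01 * monthly)
  cp2 <- crude_probability_curves(half, 0.06 * half, 0.01 * half)
  expect_lt(abs(cp1$p_bc[cp1$time == 10] - cp2$p_bc[cp2$time == 10]), 5e-4)
})

test_that("a zero-excess fit yields RS = 1 and P_BC = 0 throughout", {
  f <- make_toy_fit(rate0 = 0.02)
  lt <- flat_lifetable(0.02)
  ic <- predict_profile(f, lt, list(age = 60, stage = "I", her2 = "neg",
                                    adherent = TRUE))
  expect_equal(ic$rs, rep(1, nrow(ic)), tolerance = 1e-9)
  expect_equal(ic$p_bc, rep(0, nrow(ic)), tolerance = 1e-12)
  expect_equal(ic$rs5[!is.na(ic$rs5)],
               rep(1, sum(!is.na(ic$rs5))), tolerance = 1e-9)
  validate_indicator_curves(ic)
})

test_that("profile indicator curves satisfy the structural invariants", {
  cfg <- sim_config(n = 800, seed = 23)
  co <- simulate_cohort(cfg)
  f <- fit_cox(co, "C3")
  lt <- sim_lifetable(cfg)
  set.seed(1)
  for (i in 1:20) {
    p <- list(age = runif(1, 30, 83),
              stage = sample(c("I", "II", "III"), 1),
              her2 = sample(c("neg", "pos"), 1),
              adherent = runif(1) < 0.5)
    ic <- suppressWarnings(predict_profile(f, lt, p))
    expect_no_error(validate_indicator_curves(ic))
    # RS5 identity against the stored RS curve
    idx <- which(!is.na(ic$rs5))
    shift <- match(round(ic$time[idx] + 5, 9), round(ic$time, 9))
    expect_equal(ic$rs5[idx], ic$rs[shift] / ic$rs[idx], tolerance = 1e-12)
  }
})

test_that("RS from a profile equals exp(-(Lambda_O - Lambda_P)) up to
           discretisation", {
  f <- make_toy_fit(beta = c(age = 0, stageII = 0.7, stageIII = 1.6,
                             her2pos = 0, adherent = -0.5), rate0 = 0.03)
  lt <- flat_lifetable(0.01)
  p <- list(age = 60, stage = "II", her2 = "neg", adherent = FALSE)
  ic <- predict_profile(f, lt, p)
  lam_o <- 0.03 * exp(0.7)
  expect_equal(ic$rs[ic$time == 10], exp(-(lam_o - 0.01) * 10),
               tolerance = 5e-3)
})

test_that("adherence comparison reports difference, fold change, bars", {
  f <- make_toy_fit(beta = c(age = 0, stageII = 0, stageIII = 1.2,
                             her2pos = 0, adherent = -0.56), rate0 = 0.04)
  lt <- flat_lifetable(0.005)
  cmp <- compare_adherence(f, lt, list(age = 60, stage = "III",
                                       her2 = "neg"))
  expect_gt(cmp$p_bc_non_adherent, cmp$p_bc_adherent)
  expect_equal(cmp$difference,
               cmp$p_bc_non_adherent - cmp$p_bc_adherent)
  expect_equal(cmp$os_fold_change,
               tail(cmp$adherent$os, 1) / tail(cmp$non_adherent$os, 1))
  expect_equal(nrow(cmp$bars), 20)
  expect_true(all(cmp$bars$percent_survival >= 0 &
                    cmp$bars$percent_survival <= 100))
  # a null adherence effect gives identical arms
  f0 <- make_toy_fit(rate0 = 0.04)
  cmp0 <- compare_adherence(f0, lt, list(age = 60, stage = "I",
                                         her2 = "neg"))
  expect_equal(cmp0$difference, 0)
  expect_equal(cmp0$os_fold_change, 1)
})

test_that("the reporting helpers reproduce the published arithmetic", {
  expect_equal(pbc_difference(8.81, 2.20), 6.61)
  expect_equal(round(fold_change(73.5, 58), 2), 1.27)
  expect_equal(risk_reduction_pct(0.58), 42)
  expect_equal(100 * relative_reduction(21, 37.7), 44.3, tolerance = 0.05)
})

test_that("P_BC age trend responds only to the hazard that varies", {
  # age-increasing population hazard with no age effect in the excess
  # hazard: in the generator truth, P_OC rises steeply with age at
  # diagnosis while P_BC stays nearly flat
  cfg <- sim_config(seed = 1, lifetable_r0 = 1e-5, lifetable_g = 0.09,
                    baseline_excess = list(dist = "exponential",
                                           rate = 0.0182),
                    beta = c(stageII = 0, stageIII = 0, adherent = -0.5,
                             her2pos = 0, age = 0))
  ages <- c(50, 60, 70, 80)
  truths <- lapply(ages, function(a)
    true_indicators(cfg, list(age = a, stage = "I", her2 = "neg",
                              adherent = TRUE)))
  pbc10 <- vapply(truths, function(tr) tr$p_bc[tr$time == 10], numeric(1))
  poc10 <- vapply(truths, function(tr) tr$p_oc[tr$time == 10], numeric(1))
  expect_true(all(diff(poc10) > 0))
  expect_gt(diff(range(poc10)), 0.1)
  expect_lt(diff(range(pbc10)), 0.02)

  # fitted-model age trend: non-adherent arm dominates pointwise when the
  # adherence log-HR is negative, all else equal
  f <- make_toy_fit(beta = c(age = 0, stageII = 0, stageIII = 0,
                             her2pos = 0, adherent = -0.5), rate0 = 0.03)
  lt <- make_synthetic_lifetable(1e-5, 0.09, years = 1990:2030)
  tr <- pbc_age_trend(f, lt, stage = "I", ages = c(50, 60, 70))
  wide <- merge(tr[tr$arm == "adherent", ], tr[tr$arm == "non_adherent", ],
                by = c("age", "t"))
  expect_true(all(wide$p_bc.y >= wide$p_bc.x))
})

test_that("zero-excess fits give a flat zero P_BC age trend", {
  f <- make_toy_fit(rate0 = 0.02)
  lt <- flat_lifetable(0.02)
  tr <- pbc_age_trend(f, lt, stage = "I", ages = c(45, 60, 75))
  expect_equal(tr$p_bc, rep(0, nrow(tr)), tolerance = 1e-12)
})

test_that("bootstrap on the sample mean matches a direct percentile
           bootstrap with the same seed", {
  co <- as_cohort(make_cohort_df(50))
  stat <- function(c) mean(c$age_dx)
  ci <- bootstrap_ci(co, stat, B = 200, seed = 7)
  set.seed(7)
  draws <- replicate(200, mean(co$age_dx[sample.int(50, 50, TRUE)]))
  expect_equal(ci$lo, quantile(draws, 0.025, names = FALSE))
  expect_equal(ci$hi, quantile(draws, 0.975, names = FALSE))
  expect_equal(ci$estimate, mean(co$age_dx))
  # a cohort of identical patients gives a zero-width interval
  df <- make_cohort_df(30, age = 60, stage = "II", her2 = "neg",
                       adherence = 0.9, followup = 5, dead = FALSE)
  ci0 <- bootstrap_ci(as_cohort(df), stat, B = 100, seed = 1)
  expect_equal(ci0$lo, ci0$hi)
  expect_equal(ci0$lo, 60)
  expect_error(bootstrap_ci(co, stat, B = 50), "at least 100")
})

test_that("bootstrap CI for the null P_BC difference covers zero at the
           nominal rate", {
  lt <- flat_lifetable(0.004)
  stat <- function(co) {
    f <- fit_cox(co, "C2")
    cmp <- compare_adherence(f, lt, list(age = 60, stage = "I",
                                         her2 = "neg"), step = 1 / 4)
    cmp$difference
  }
  covered <- vapply(1:40, function(s) {
    cfg <- sim_config(n = 300, seed = 5000 + s,
                      beta = c(stageII = log(2), stageIII = log(4),
                               adherent = 0, her2pos = 0, age = 0.04),
                      baseline_excess = list(dist = "exponential",
                                             rate = 0.03),
                      lifetable_r0 = 0.004, lifetable_g = 0)
    co <- simulate_cohort(cfg)
    ci <- bootstrap_ci(co, stat, B = 100, seed = s)
    ci$lo[1] <= 0 && 0 <= ci$hi[1]
  }, logical(1))
  # binomial(40, 0.95) lower 0.5% quantile is 35
  expect_gte(sum(covered), 35)
})

test_that("stage comparison table pools ages and orders by stage", {
  cfg <- sim_config(n = 400, seed = 77)
  co <- simulate_cohort(cfg)
  f <- fit_cox(co, "C3")
  lt <- sim_lifetable(cfg)
  tab <- stage_comparison_table(f, lt, co)
  expect_equal(tab$stage, c("I", "II", "III"))
  expect_equal(tab$difference, tab$p_bc_non_adherent - tab$p_bc_adherent)
  expect_true(all(diff(tab$p_bc_non_adherent) > 0))
  expect_equal(sum(tab$n_adherent) + sum(tab$n_non_adherent), nrow(co))
  # fixed-age evaluation matches a direct profile prediction
  tab60 <- stage_comparison_table(f, lt, co, fixed_age = 60)
  ic <- predict_profile(f, lt, list(age = 60, stage = "II", her2 = "neg",
                                    adherent = TRUE))
  expect_equal(tab60$p_bc_adherent[2], 100 * ic$p_bc[nrow(ic)],
               tolerance = 1e-9)
})

test_that("indicator curves serialize to the documented CSV schema", {
  f <- make_toy_fit(rate0 = 0.03)
  ic <- predict_profile(f, flat_lifetable(0.01),
                        list(age = 60, stage = "I", her2 = "neg",
                             adherent = TRUE))
  path <- tempfile(fileext = ".csv")
  write_indicator_curves(ic, path)
  back <- read.csv(path)
  expect_equal(names(back),
               c("T", "OS", "ES", "RS", "RS5", "EM", "P_BC", "P_OC"))
  expect_equal(back$OS, ic$os)
  expect_equal(sum(!is.na(back$RS5)), sum(ic$time <= 5))
})
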