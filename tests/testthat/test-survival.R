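test_that("Kaplan-Meier estimate matches hand product-limit computation", {
  # no events: survival stays at 1
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # n = 4, deaths at 1 and 2
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(km$surv[km$time == 1], 0.75)
  expect_equal(km$surv[km$time == 2], 0.5)

  # tie convention: the death at t = 1 precedes the censoring at t = 1
  km2 <- km_estimate(c(1, 1), c(1, 0))
  expect_equal(km2$surv[km2$time == 1], 0.5)

  # without censoring, S at each event time equals 1 - ECDF
  set.seed(2)
  tt <- rexp(40)
  km3 <- km_estimate(tt, rep(1, 40))
  expect_equal(km3$surv, 1 - ecdf(tt)(km3$time))

  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank test matches the hand risk-table oracle", {
  # identical groups: chi-square 0, p 1
  tm <- c(1, 2, 3, 1, 2, 3); ev <- c(1, 1, 0, 1, 1, 0)
  gp <- c(0, 0, 0, 1, 1, 1)
  lr0 <- logrank_test(tm, ev, gp)
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # toy: group 0 deaths at (1,2), group 1 deaths at (3,4)
  tm <- 1:4; ev <- rep(1, 4); gp <- c(0, 0, 1, 1)
  lr <- logrank_test(tm, ev, gp)
  expect_equal(lr$chi_square, oracle_logrank_chisq(tm, ev, gp),
               tolerance = 1e-10)

  # a larger case against the oracle, and row-permutation invariance
  set.seed(9)
  tm <- round(rexp(30, 0.1), 3); ev <- rbinom(30, 1, 0.8); gp <- rbinom(30, 1, 0.5)
  lr1 <- logrank_test(tm, ev, gp)
  expect_equal(lr1$chi_square, oracle_logrank_chisq(tm, ev, gp),
               tolerance = 1e-8)
  idx <- sample(30)
  expect_equal(logrank_test(tm[idx], ev[idx], gp[idx])$chi_square,
               lr1$chi_square, tolerance = 1e-12)

  expect_error(logrank_test(tm, ev, rep(1, 30)), "two")
})

test_that("Cox fit maximizes the hand-written partial likelihood", {
  # n = 4, times 1..4, all events, x = (1,0,1,0); no ties, so the partial
  # likelihood has a closed form over the nested risk sets (the alternating
  # covariate keeps the maximizer finite)
  neg_pl <- function(b) {
    -((b - log(2 * exp(b) + 2)) + (0 - log(exp(b) + 2)) +
        (b - log(exp(b) + 1)) + 0)
  }
  b_opt <- optimize(neg_pl, c(-10, 10), tol = 1e-10)$minimum
  fit <- cox_fit(1:4, rep(1, 4), data.frame(x = c(1, 0, 1, 0)))
  expect_equal(unname(coef(fit)["x"]), b_opt, tolerance = 1e-6)
  expect_equal(fit$lr_chisq, 2 * (neg_pl(0) - neg_pl(b_opt)), tolerance = 1e-6)
  # CI brackets the HR
  co <- fit$coefficients
  expect_true(co$ci_lo <= co$hr && co$hr <= co$ci_hi)
})

test_that("Cox fit guards degenerate inputs and flags monotone likelihood", {
  expect_error(cox_fit(1:4, rep(0, 4), data.frame(x = c(1, 1, 0, 0))), "event")
  expect_error(cox_fit(1:4, rep(1, 4), data.frame(x = rep(1, 4))), "constant")
  # complete separation: the risk group dies strictly first
  fit <- cox_fit(c(1, 2, 10, 11, 12, 13), c(1, 1, 1, 1, 0, 0),
                 data.frame(x = c(1, 1, 0, 0, 0, 0)))
  expect_false(fit$converged)
})

test_that("duplicating every patient is invariant under Breslow, close under Efron", {
  set.seed(14)
  n <- 25
  d <- data.frame(time = round(rexp(n, 0.1), 2), event = rbinom(n, 1, 0.8),
                  x = rbinom(n, 1, 0.4))
  d2 <- rbind(d, d)
  b1 <- coef(cox_fit(d$time, d$event, d["x"], ties = "breslow"))
  b2 <- coef(cox_fit(d2$time, d2$event, d2["x"], ties = "breslow"))
  expect_equal(b1, b2, tolerance = 1e-8)
  e1 <- coef(cox_fit(d$time, d$event, d["x"], ties = "efron"))
  e2 <- coef(cox_fit(d2$time, d2$event, d2["x"], ties = "efron"))
  expect_lt(abs(e1 - e2), 0.05)
})

test_that("log-rank chi-square equals the Cox score test without ties", {
  set.seed(33)
  n <- 40
  tm <- rexp(n, 0.1)  # continuous: no ties
  ev <- rbinom(n, 1, 0.8)
  gp <- rbinom(n, 1, 0.5)
  lr <- logrank_test(tm, ev, gp)
  fit <- cox_fit(tm, ev, data.frame(g = gp))
  sc <- unname(summary(fit$model)$sctest["test"])
  expect_equal(lr$chi_square, sc, tolerance = 1e-6)
})

test_that("univariate Cox CI covers an independent covariate's null HR", {
  set.seed(55)
  cover <- 0
  n_sim <- 200
  for (i in 1:n_sim) {
    n <- 60
    x <- rbinom(n, 1, 0.5)
    tm <- rexp(n, 0.05)           # independent of x
    cs <- rexp(n, 0.02)
    time <- pmin(tm, cs); ev <- as.integer(tm <= cs)
    if (sum(ev) < 2 || length(unique(x)) < 2) next
    fit <- cox_fit(time, ev, data.frame(x = x))
    co <- fit$coefficients
    if (co$ci_lo <= 1 && 1 <= co$ci_hi) cover <- cover + 1
  }
  expect_gte(cover / n_sim, 0.90)
})

test_that("administrative censoring never increases events and truncates follow-up", {
  set.seed(6)
  tm <- rexp(100, 0.008); ev <- rbinom(100, 1, 0.9)
  cen <- censor_at_horizon(tm, ev, 120)
  expect_lte(sum(cen$event), sum(ev))
  expect_true(all(cen$time <= 120))
  expect_true(all(cen$event[cen$time < 120] == ev[cen$time < 120]))
})

test_that("stepwise AIC keeps the base model and resists duplicates", {
  set.seed(71)
  n <- 120
  stage <- rbinom(n, 1, 0.4)
  mk <- rbinom(n, 1, 0.3)
  tm <- rexp(n, 0.01 * exp(1.0 * stage + 0.8 * mk))
  ev <- rep(1, n)

  # no candidates: final model is the base model
  sw0 <- stepwise_aic(tm, ev, base = data.frame(marker = mk, stage = stage))
  expect_equal(sort(sw0$fit$coefficients$term), c("marker", "stage"))
  expect_length(sw0$selected, 0)

  # a duplicated candidate can enter at most once
  age <- rnorm(n)
  sw1 <- stepwise_aic(tm, ev, base = data.frame(marker = mk, stage = stage),
                      candidates = data.frame(age1 = age, age2 = age))
  expect_lte(length(sw1$selected), 1)

  # candidates independent of outcome mostly stay out; a null candidate
  # enters when its LR chi-square exceeds the AIC penalty of 2, i.e. with
  # probability ~0.157 each, so ~0.71 of replicates keep the bare base model
  picked <- 0
  for (i in 1:40) {
    cand <- data.frame(age = rnorm(n), alcohol = rbinom(n, 1, 0.5))
    sw <- stepwise_aic(tm, ev, base = data.frame(marker = mk, stage = stage),
                       candidates = cand)
    if (length(sw$selected) > 0) picked <- picked + 1
  }
  expect_lte(picked / 40, 0.55)
})
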