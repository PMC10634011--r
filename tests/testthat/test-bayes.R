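fast_mcmc <- list(chains = 2, warmup = 500, iter = 1500)

test_that("ROPE half-width is a tenth of the outcome SD", {
  y <- c(0, 10)  # SD = sqrt(50) -> not round; use a constructed SD-10 set
  y10 <- c(40, 50, 60)  # sd = 10
  expect_equal(rope_halfwidth(y10)$halfwidth, 1)
  expect_equal(rope_halfwidth(y10)$interval, c(-1, 1))
  expect_error(rope_halfwidth(rep(5, 4)), "zero variance")
  expect_error(rope_halfwidth(3), "at least 2")
})

test_that("complete-case filtering reproduces the printed inclusion rule", {
  donors <- psp_donors()
  expect_equal(nrow(donors), 32)
  cc <- complete_records(donors, quiet = TRUE)
  expect_equal(nrow(cc), 28)
  # the printed intercept prior location/scale derive from these records
  expect_equal(median(cc$pspr_total), 53.5)
  expect_equal(round(mad(cc$pspr_total), 1), 12.6)
})

test_that("posterior recovers a known slope and matches least squares", {
  set.seed(21)
  d <- data.frame(x = rnorm(200))
  d$y <- 2 + 3 * d$x + rnorm(200)
  fit <- do.call(fit_bayes_lm,
                 c(list(d, y ~ x, priors = prior_spec(coef_sd = 100),
                        seed = 2, quiet = TRUE), fast_mcmc))
  expect_true(fit$converged)
  ls <- unname(coef(lm(y ~ x, d))["x"])
  expect_lt(abs(median(fit$draws[, "x"]) - 3), 0.25)
  expect_lt(abs(median(fit$draws[, "x"]) - ls), 0.1)
})

test_that("with an essentially flat prior the posterior mean is least squares", {
  set.seed(22)
  d <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
  d$y <- 1 + 2 * d$x1 - 1.5 * d$x2 + rnorm(200)
  fit <- fit_bayes_lm(d, y ~ x1 + x2, priors = prior_spec(coef_sd = 1e6),
                      chains = 2, warmup = 1000, iter = 4000, seed = 3,
                      quiet = TRUE)
  ls <- coef(lm(y ~ x1 + x2, d))
  for (tm in c("x1", "x2")) {
    expect_lt(abs(mean(fit$draws[, tm]) - ls[tm]) / abs(ls[tm]), 0.01)
  }
})

test_that("credible intervals contain zero for zero-signal data", {
  set.seed(23)
  hits <- 0
  for (rep in 1:20) {
    d <- data.frame(x = rnorm(40))
    d$y <- 5 + rnorm(40)
    fit <- do.call(fit_bayes_lm,
                   c(list(d, y ~ x, seed = rep, quiet = TRUE),
                     list(chains = 2, warmup = 300, iter = 800)))
    q <- quantile(fit$draws[, "x"], c(0.025, 0.975))
    if (q[1] <= 0 && 0 <= q[2]) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("posterior summaries match a sort-based quantile oracle", {
  set.seed(24)
  draws <- cbind(`(Intercept)` = rnorm(4000, 50, 5),
                 x = rnorm(4000, 0.3, 0.2),
                 sigma = abs(rnorm(4000, 10, 1)))
  fake <- structure(list(draws = draws, rhat = c(b0c = 1, `beta[1]` = 1,
                                                 sigma = 1),
                         y = rnorm(10)),
                    class = "bayes_lm")
  td <- tidy(fake, rope = 1.24)
  srt <- sort(draws[, "x"])
  expect_equal(td$conf.low[td$term == "x"],
               unname(quantile(draws[, "x"], 0.025)))
  expect_equal(td$median[td$term == "x"], median(srt))
  # verdict logic on constructed intervals
  draws2 <- cbind(a = runif(1000, -0.5, 0.5), b = runif(1000, 2.7, 18.9),
                  c = runif(1000, -1, 3))
  fake2 <- structure(list(draws = draws2, rhat = rep(1, 3), y = rnorm(5)),
                     class = "bayes_lm")
  td2 <- tidy(fake2, rope = 1.24)
  expect_equal(td2$verdict, c("inside", "outside", "undecided"))
  expect_equal(td2$rope_pct[1], 100)
})

test_that("Bayes factors behave as marginal-likelihood ratios", {
  set.seed(25)
  d <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
  d$y <- 1 + 4 * d$x1 + rnorm(80)
  # self-comparison: BF exactly 1 and inconclusive by the 1/3-3 band
  self <- compare_models(d, y ~ x1, y ~ x1)
  expect_equal(self$bf, 1)
  expect_equal(self$verdict, "inconclusive")
  # antisymmetry of the log Bayes factor
  ab <- compare_models(d, y ~ x1, y ~ x2)
  ba <- compare_models(d, y ~ x2, y ~ x1)
  expect_equal(log(ab$bf), -log(ba$bf), tolerance = 1e-9)
  # the true (richer) model wins decisively across seeds
  for (s in 1:3) {
    set.seed(100 + s)
    d2 <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
    d2$y <- 2 + 5 * d2$x1 + rnorm(60)
    cmp <- compare_models(d2, y ~ x1 + x2, y ~ x2)
    expect_gt(cmp$bf, 3)
    expect_equal(cmp$verdict, "favours A")
  }
  expect_error(compare_models(d, y ~ x1, x1 ~ y), "same outcome")
})

test_that("prior sensitivity is negligible for informative data", {
  set.seed(26)
  d <- data.frame(x = rnorm(300))
  d$y <- 10 + 8 * d$x + rnorm(300)
  ps <- do.call(prior_sensitivity,
                c(list(d, y ~ x, effect = "x"), list(seed = 4),
                  fast_mcmc))
  expect_true(ps$stable)
  meds <- ps$summary$median
  expect_lt(max(meds) / min(meds) - 1, 0.05)
  expect_error(
    do.call(prior_sensitivity,
            c(list(d[0, ], y ~ x, effect = "x"), fast_mcmc)),
    "complete records"
  )
})

test_that("a 95% CrI covers the true coefficient in most synthetic cohorts", {
  covered <- 0
  for (rep in 1:20) {
    set.seed(300 + rep)
    d <- data.frame(dur = runif(30, 3, 12), int = runif(30, 0, 3))
    d$y <- 45 + 12 * scale(d$dur)[, 1] + rnorm(30, 0, 8)
    fit <- do.call(fit_bayes_lm,
                   c(list(d, y ~ dur + int, seed = rep, quiet = TRUE),
                     list(chains = 2, warmup = 300, iter = 800)))
    truth <- 12 / sd(d$dur)
    q <- quantile(fit$draws[, "dur"], c(0.025, 0.975))
    if (q[1] <= truth && truth <= q[2]) covered <- covered + 1
  }
  expect_gte(covered, 17)
})
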