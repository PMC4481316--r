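test_that("quantitative fits match the closed-form Gaussian MLE and OLS", {
  set.seed(7)
  g <- random_panel(n = 30, v = 3, seed = 7)
  y <- rnorm(30) + 0.5 * g$dosages[, 1]

  ## null model: -(n/2) (log(2 pi sigma2_mle) + 1)
  f0 <- fit_glm(character(), g, y)
  s2 <- mean((y - mean(y))^2)
  expect_equal(f0$loglik, -(30 / 2) * (log(2 * pi * s2) + 1),
               tolerance = 1e-10)

  ## 2-SNP model vs independent normal-equations oracle
  f <- fit_glm(c("v1", "v3"), g, y)
  or <- ols_oracle(g$dosages[, c("v1", "v3")], y)
  expect_equal(unname(f$coef), unname(or$beta[-1]), tolerance = 1e-8)
  expect_equal(f$loglik, or$loglik, tolerance = 1e-8)
  expect_equal(f$k - f0$k, 2L)
})

test_that("covariates are partialled out identically to a joint fit", {
  set.seed(8)
  g <- random_panel(n = 60, v = 2, seed = 8)
  country <- factor(sample(c("UK", "DE", "SE"), 60, replace = TRUE))
  y <- rnorm(60) + 0.4 * g$dosages[, 1] + 0.8 * (country == "DE")
  f <- fit_glm("v1", g, y, covariates = data.frame(country = country))
  ref <- lm(y ~ country + g$dosages[, 1])
  expect_equal(unname(f$coef), unname(coef(ref)[4]), tolerance = 1e-8)
  expect_equal(f$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("logistic fits flag separation and match glm", {
  set.seed(9)
  g <- random_panel(n = 80, v = 2, seed = 9)
  y <- rbinom(80, 1, plogis(-0.3 + 0.7 * g$dosages[, 1]))
  f <- fit_glm("v1", g, y, family = "case-control")
  ref <- glm(y ~ g$dosages[, 1], family = binomial())
  expect_true(f$converged)
  expect_equal(unname(f$coef), unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)

  ## perfect predictor -> non-estimable
  ysep <- as.numeric(g$dosages[, 2] > 0)
  fsep <- fit_glm("v2", g, ysep, family = "case-control")
  expect_false(fsep$converged)
  f0 <- fit_glm(character(), g, ysep, family = "case-control")
  expect_identical(log_abf(fsep, f0), -Inf)
})

test_that("log_abf implements the BIC relation and its closed forms", {
  ## pure arithmetic: dll = 10, dk = 1, n = e^2 -> 10 - 1 = 9
  f0 <- list(loglik = 0, k = 3, converged = TRUE, n = exp(2))
  fm <- list(loglik = 10, k = 4, converged = TRUE, n = exp(2))
  expect_equal(log_abf(fm, f0), 9)
  expect_equal(log_abf(f0, f0), 0)     # null vs null
  expect_error(log_abf(list(loglik = 1, k = 3, converged = TRUE, n = 10),
                       list(loglik = 0, k = 3, converged = TRUE, n = 12)),
               "sample counts")

  ## longhand recompute of BIC_m from the two fits on a simulated dataset
  set.seed(10)
  g <- random_panel(n = 100, v = 3, seed = 10)
  y <- rnorm(100) + 0.3 * g$dosages[, 2]
  f0 <- fit_glm(character(), g, y)
  f1 <- fit_glm("v2", g, y)
  bic_m <- -2 * (f1$loglik - f0$loglik) + (f1$k - f0$k) * log(100)
  expect_equal(log_abf(f1, f0), -bic_m / 2, tolerance = 1e-12)

  ## RSS closed form: log BF = -(n/2) log(RSS_m/RSS_0) - (k/2) log n
  rss0 <- sum(resid(lm(y ~ 1))^2)
  rss1 <- sum(resid(lm(y ~ g$dosages[, 2]))^2)
  expect_equal(log_abf(f1, f0),
               -(100 / 2) * log(rss1 / rss0) - (1 / 2) * log(100),
               tolerance = 1e-8)
})

test_that("likelihood is monotone under nesting and k tracks model size", {
  set.seed(11)
  g <- random_panel(n = 70, v = 4, seed = 11)
  y <- rnorm(70)
  models <- list(character(), "v1", c("v1", "v2"), c("v1", "v2", "v4"))
  fits <- lapply(models, fit_glm, g = g, phenotype = y)
  ll <- sapply(fits, `[[`, "loglik")
  expect_true(all(diff(ll) >= -1e-10))
  k0 <- fits[[1]]$k
  expect_equal(sapply(fits, `[[`, "k") - k0, c(0L, 1L, 2L, 3L))
})

test_that("binomial size prior has the printed mass, sums to 1, and E = n_exp", {
  pr <- prior_spec(100, 3)
  expect_equal(model_log_prior(0, pr), 100 * log(0.97), tolerance = 1e-12)
  expect_equal(exp(model_log_prior(0, pr)), 0.97^100)

  ## sum over all 2^N models of a 10-variant panel is 1 (binomial theorem)
  pr10 <- prior_spec(10, 3)
  total <- sum(choose(10, 0:10) * exp(model_log_prior(0:10, pr10)))
  expect_equal(total, 1, tolerance = 1e-12)

  ## expected model size equals n_exp for any N
  for (N in c(10, 50, 443, 667)) {
    pr <- prior_spec(N, 3)
    esz <- sum((0:N) * choose(N, 0:N) * exp(model_log_prior(0:N, pr)))
    expect_equal(esz, 3, tolerance = 1e-9)
  }
  expect_error(model_log_prior(11, pr10), "size")
  expect_error(prior_spec(10, 10), "n_exp")
})

test_that("posterior normalisation is exact, symmetric and shift-invariant", {
  df <- data.frame(model = c("", "a", "b"), size = c(0L, 1L, 1L),
                   log_abf = c(0, 5, 5), log_prior = c(0, -2, -2),
                   stringsAsFactors = FALSE)
  post <- normalise_posterior(df)
  expect_equal(sum(post$pp), 1, tolerance = 1e-12)
  expect_equal(post$pp[post$model == "a"], post$pp[post$model == "b"])

  ## longhand logsumexp on three hand-set models
  lw <- df$log_abf + df$log_prior
  expect_equal(post$pp, exp(lw) / sum(exp(lw)), tolerance = 1e-12)

  ## adding a constant to all log weights changes nothing
  df2 <- df
  df2$log_abf <- df2$log_abf + 123.4
  expect_equal(normalise_posterior(df2)$pp, post$pp, tolerance = 1e-12)

  ## null auto-added when missing and a prior is supplied
  post2 <- normalise_posterior(df[-1, ], prior = prior_spec(10, 3))
  expect_true("" %in% post2$model)
  expect_equal(sum(post2$pp), 1, tolerance = 1e-12)
  expect_error(normalise_posterior(df[0, ]), "empty")
  expect_error(normalise_posterior(rbind(df, df[2, ])), "duplicated")
})
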