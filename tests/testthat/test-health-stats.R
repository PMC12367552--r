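test_that("Pearson correlation matches its definition and degenerates
           correctly", {
  x <- 1:20
  out <- pearson_with_ci(x, 2 * x + 1)
  expect_equal(out$r, 1, tolerance = 1e-12)

  set.seed(51)
  a <- rnorm(50); b <- 0.4 * a + rnorm(50)
  got <- pearson_with_ci(a, b)
  brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, brute, tolerance = 1e-12)
  expect_true(got$ci_low < got$r && got$r < got$ci_high)

  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_with_ci(1:3, 1:3), "length")
})

test_that("independent data give near-nominal CI coverage of zero", {
  set.seed(52)
  hits <- replicate(200, {
    x <- rnorm(60); y <- rnorm(60)
    ci <- pearson_with_ci(x, y)
    ci$ci_low <= 0 && 0 <= ci$ci_high
  })
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("mixed model degenerates to OLS when group variance vanishes", {
  cfg <- world_config(seed = 9, gamma_sd = 1e-6)
  d <- generate_health_data(200, cfg, seed = 91)
  m <- suppressMessages(fit_health_model(d, "III"))
  ols <- lm(HALE ~ ExpEco + ExpSoc + GiniEco + GiniSoc + LnPop + LnGDP,
            data = d)
  ord <- match(m$coefficients$term, names(coef(ols)))
  expect_equal(m$coefficients$estimate, unname(coef(ols)[ord]),
               tolerance = 1e-6)
  expect_true(m$singular)
})

test_that("coefficient signs are recovered on generator-faithful data", {
  d <- generate_health_data(160, world_config(seed = 4), seed = 44)
  m <- suppressMessages(fit_health_model(d, "III"))
  est <- setNames(m$coefficients$estimate, m$coefficients$term)
  expect_gt(est["ExpEco"], 0)
  expect_lt(est["GiniEco"], 0)
  expect_equal(m$model_id, "III")
  expect_false(m$log_transformed)
  # model subsets drop the other block of covariates
  m1 <- suppressMessages(fit_health_model(d, "I"))
  expect_false(any(grepl("Gini", m1$coefficients$term)))
  m2 <- suppressMessages(fit_health_model(d, "II"))
  expect_false(any(grepl("Exp", m2$coefficients$term)))
})

test_that("robust and model-based SEs agree under homoscedasticity and
           the sandwich engages under heteroscedasticity", {
  # compare on the fixed-effect-group path: with only two groups the
  # realized random intercepts contaminate the marginal residuals, so
  # the homoscedastic agreement statement is about the iid-residual fit
  d <- generate_health_data(1000, world_config(seed = 6), seed = 66)
  plain <- suppressMessages(fit_health_model(d, "III",
                                             group_as_fixed = TRUE,
                                             robust_threshold = 0))
  forced <- suppressMessages(fit_health_model(d, "III",
                                              group_as_fixed = TRUE,
                                              robust_threshold = 1))
  expect_false(plain$robust_se_used)
  expect_true(forced$robust_se_used)
  rel <- abs(forced$coefficients$se / plain$coefficients$se - 1)
  expect_lt(max(rel), 0.10)

  het_cfg <- world_config(seed = 6, heteroscedastic = TRUE)
  dh <- generate_health_data(400, het_cfg, seed = 67)
  mh <- suppressMessages(fit_health_model(dh, "III"))
  expect_lt(mh$levene["p"], 0.05)
  expect_true(mh$robust_se_used)
})

test_that("the fixed-effect-group sandwich equals the HC1 oracle", {
  skip_if_not_installed("sandwich")
  d <- generate_health_data(120, world_config(seed = 8), seed = 88)
  m <- suppressMessages(fit_health_model(d, "III", group_as_fixed = TRUE,
                                         robust_threshold = 1))
  ols <- lm(HALE ~ ExpEco + ExpSoc + GiniEco + GiniSoc + LnPop + LnGDP +
              factor(group), data = d)
  hc1 <- sqrt(diag(sandwich::vcovHC(ols, type = "HC1")))
  names(hc1) <- sub("factor\\(group\\)", "group", names(hc1))
  ord <- match(m$coefficients$term, names(hc1))
  expect_equal(m$coefficients$se, unname(hc1[ord]), tolerance = 1e-8)
})

test_that("predicted health change is the linear-predictor shift", {
  ref <- reference_model_coefficients("III")
  expect_equal(predicted_health_change(ref, "GiniEco", 0.10), -0.995)
  expect_equal(predicted_health_change(ref, "GiniEco", 0), 0)
  expect_equal(predicted_health_change(ref, "ExpEco", 0.2),
               2 * predicted_health_change(ref, "ExpEco", 0.1))
  expect_error(predicted_health_change(ref, "NoSuch", 0.1), "unknown")
})

test_that("random-forest importance is reproducible and finds a planted
           signal", {
  set.seed(53)
  n <- 150
  d <- data.frame(ExpEco = runif(n), ExpSoc = runif(n),
                  GiniEco = runif(n), GiniSoc = runif(n),
                  LnPop = rnorm(n), LnGDP = rnorm(n))
  d$HALE <- 10 * d$GiniEco + rnorm(n, sd = 0.3)
  imp1 <- rf_importance(d, "HALE", n_trees = 100, n_runs = 5, seed = 7)
  imp2 <- rf_importance(d, "HALE", n_trees = 100, n_runs = 5, seed = 7)
  expect_identical(imp1, imp2)
  top <- sapply(split(imp1, imp1$run), function(r)
    r$term[which.max(r$inc_mse)])
  expect_true(all(top == "GiniEco"))
})

test_that("group comparison statistics follow their definitions", {
  g <- rep(c("a", "b"), each = 20)
  same <- rep(1:20, 2)
  out <- group_comparisons(same, g)
  expect_equal(out$statistic, 0)
  expect_equal(out$effect, 0)

  set.seed(54)
  x1 <- as.numeric(scale(rnorm(100)))       # exact mean 0, sd 1
  x2 <- as.numeric(scale(rnorm(100))) + 1   # exact mean 1, sd 1
  d2 <- group_comparisons(c(x1, x2), rep(c("a", "b"), each = 100))
  expect_equal(d2$effect, -1, tolerance = 1e-12)
  expect_equal(d2$effect_name, "cohen_d")

  # two-group ANOVA F equals t squared
  v <- c(x1, x2); grp <- rep(c("a", "b"), each = 100)
  tt <- group_comparisons(v, grp)
  av <- group_comparisons(v, factor(grp, levels = c("a", "b")))
  fit <- aov(v ~ factor(grp))
  F_val <- summary(fit)[[1]]$`F value`[1]
  expect_equal(F_val, tt$statistic^2, tolerance = 1e-10)

  # three groups: ANOVA with Cohen's f
  g3 <- rep(c("a", "b", "c"), each = 30)
  v3 <- rnorm(90) + rep(c(0, 0.5, 1), each = 30)
  a3 <- group_comparisons(v3, g3)
  expect_equal(a3$test, "anova")
  expect_equal(a3$effect_name, "cohen_f")
  eta2 <- summary(aov(v3 ~ factor(g3)))[[1]]
  eta2 <- eta2$`Sum Sq`[1] / sum(eta2$`Sum Sq`)
  expect_equal(a3$effect, sqrt(eta2 / (1 - eta2)), tolerance = 1e-12)
})

test_that("group mean ratios reproduce the published headline ratios", {
  ref <- reference_group_summary()
  north <- ref[ref$region == "Global North", ]
  south <- ref[ref$region == "Global South", ]
  get <- function(tab, ms, ct) tab$mean[tab$measure == ms &
                                          tab$category == ct]
  acc_ratio <- sapply(c("economic", "social", "environmental"),
    function(ct) group_mean_ratio(get(north, "access", ct),
                                  get(south, "access", ct)))
  expect_equal(unname(acc_ratio), c(1.25, 2.00, 1.43))
  gini_ratio <- sapply(c("economic", "social", "environmental"),
    function(ct) group_mean_ratio(get(south, "gini", ct),
                                  get(north, "gini", ct)))
  expect_equal(unname(gini_ratio), c(1.23, 1.09, 1.44))
})
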