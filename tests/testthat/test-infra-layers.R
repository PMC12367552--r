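test_that("max normalization scales to [0,1] over valid cells only", {
  expect_equal(valid_values(normalize_type_layer(make_layer(c(2, 4)))),
               c(0.5, 1))
  expect_equal(valid_values(normalize_type_layer(make_layer(c(3, 3, 3)))),
               c(1, 1, 1))
  out <- normalize_type_layer(make_layer(c(0, 5, NA, 10)))
  expect_equal(as.vector(out$values), c(0, 0.5, NA, 1))

  expect_error(normalize_type_layer(make_layer(c(0, 0))), "all-zero")
  expect_error(normalize_type_layer(make_layer(c(NA_real_, NA_real_))),
               "masked")
})

test_that("max normalization is idempotent", {
  set.seed(11)
  for (i in 1:10) {
    v <- matrix(rgamma(48, 1.5) * 10, 6, 8)
    v[sample(48, 5)] <- NA
    once <- normalize_type_layer(grid_layer(v))
    twice <- normalize_type_layer(once)
    expect_identical(twice$values, once$values)
  }
})

test_that("equal-weight aggregation averages over valid contributors", {
  expect_equal(valid_values(aggregate_category(
    list(make_layer(0.2), make_layer(0.6)))), 0.4)
  one <- make_layer(c(0.1, 0.9))
  expect_equal(aggregate_category(list(one))$values, one$values)
  out <- aggregate_category(list(make_layer(1), make_layer(0),
                                 make_layer(NA_real_)))
  expect_equal(valid_values(out), 0.5)
  expect_error(aggregate_category(list()), "non-empty")
})

test_that("aggregation stays within the per-cell input envelope", {
  set.seed(12)
  layers <- lapply(1:4, function(i) {
    v <- matrix(runif(30), 5, 6)
    v[sample(30, 3)] <- NA
    grid_layer(v)
  })
  agg <- aggregate_category(layers)
  stack <- simplify2array(lapply(layers, function(l) l$values))
  lo <- apply(stack, c(1, 2), min, na.rm = TRUE)
  hi <- apply(stack, c(1, 2), max, na.rm = TRUE)
  ok <- agg$mask
  expect_true(all(agg$values[ok] >= lo[ok] - 1e-12))
  expect_true(all(agg$values[ok] <= hi[ok] + 1e-12))
})

test_that("environmental composite follows its defining formula", {
  ci <- make_layer(0.4); g <- make_layer(0); a <- make_layer(0.5)
  h <- make_layer(0.5)
  expect_equal(valid_values(environmental_composite(ci, g, a, h)), 0.7)

  # degenerate denominator is floored, stays finite
  out0 <- environmental_composite(make_layer(0.2), make_layer(0.3),
                                  make_layer(0), make_layer(0),
                                  epsilon = 1e-6)
  expect_true(is.finite(valid_values(out0)))
  expect_equal(valid_values(out0), 0.5 * 0.2 + 0.5 * exp(0.3) / 1e-6)
})

test_that("composite matches direct evaluation of the exp/log form", {
  set.seed(13)
  n <- 1000
  ci <- runif(n); g <- runif(n); a <- runif(n); h <- runif(n)
  out <- environmental_composite(make_layer(ci), make_layer(g),
                                 make_layer(a), make_layer(h))
  direct <- 0.5 * ci + 0.5 * exp(g) / log(exp(a) * exp(h))
  expect_equal(valid_values(out), direct, tolerance = 1e-12)
})

test_that("composite is monotone in each of its inputs", {
  base <- list(ci = 0.3, g = 0.4, a = 0.5, h = 0.6)
  val <- function(ci, g, a, h)
    valid_values(environmental_composite(make_layer(ci), make_layer(g),
                                         make_layer(a), make_layer(h)))
  v0 <- val(base$ci, base$g, base$a, base$h)
  expect_gt(val(base$ci + 0.1, base$g, base$a, base$h), v0)
  expect_gt(val(base$ci, base$g + 0.1, base$a, base$h), v0)
  expect_lt(val(base$ci, base$g, base$a + 0.1, base$h), v0)
  expect_lt(val(base$ci, base$g, base$a, base$h + 0.1), v0)
})

test_that("calibration fit recovers an exact power law and matches the
           closed-form least-squares oracle", {
  set.seed(14)
  iv <- runif(50, 0.01, 1)
  infra <- make_layer(iv, nrow = 5)
  ntl <- make_layer(exp(1.58 * log(iv) + 5.03), nrow = 5)
  fit <- fit_calibration(infra, ntl)
  expect_equal(fit$slope, 1.58, tolerance = 1e-7)
  expect_equal(fit$intercept, 5.03, tolerance = 1e-7)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(fit$n, 50L)

  # identity relation
  same <- fit_calibration(infra, infra)
  expect_equal(same$slope, 1, tolerance = 1e-10)
  expect_equal(same$intercept, 0, tolerance = 1e-10)

  # noisy data: equality with an independent closed-form OLS
  ntl2 <- make_layer(exp(1.2 * log(iv) + 3 + rnorm(50, sd = 0.4)),
                     nrow = 5)
  fit2 <- fit_calibration(infra, ntl2)
  oracle <- ols_closed_form(log(iv), log(valid_values(ntl2)))
  expect_equal(fit2$slope, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(fit2$intercept, unname(oracle["intercept"]),
               tolerance = 1e-10)
})

test_that("calibration fit rejects degenerate inputs", {
  expect_error(fit_calibration(make_layer(c(1, 1)), make_layer(c(2, 3))),
               "fewer than 3")
  expect_error(fit_calibration(make_layer(c(0.5, 0.5, 0.5)),
                               make_layer(c(1, 2, 3))), "zero variance")
})

test_that("applying a calibration back-transforms the power law", {
  fit <- list(slope = 1.58, intercept = 5.03)
  expect_equal(valid_values(apply_calibration(make_layer(1), fit)),
               exp(5.03))
  expect_equal(valid_values(apply_calibration(make_layer(0), fit)), 0)
  idv <- c(0, 0.2, 0.7, 1)
  expect_equal(
    valid_values(apply_calibration(make_layer(idv),
                                   list(slope = 1, intercept = 0))), idv)
})

test_that("calibration preserves cell ranking and round-trips noise-free
           night-time lights", {
  set.seed(15)
  iv <- runif(80, 0.001, 1)
  infra <- make_layer(iv, nrow = 8)
  ntl_v <- exp(1.58 * log(iv) + 5.03)
  ntl <- make_layer(ntl_v, nrow = 8)
  fit <- fit_calibration(infra, ntl)
  cal <- apply_calibration(infra, fit)
  expect_identical(order(valid_values(cal)), order(iv))
  expect_lt(max(abs(valid_values(cal) - ntl_v) / ntl_v), 1e-10)
})

test_that("the type catalogue and its sensitivity remap are complete", {
  cat0 <- default_type_catalog()
  expect_setequal(names(cat0), c("telecom", "energy", "transport",
                                 "health", "education", "water", "waste"))
  expect_equal(unname(cat0[c("water", "waste")]),
               c("environmental", "environmental"))
  cat1 <- default_type_catalog(sensitivity_remap = TRUE)
  expect_setequal(names(cat1), names(cat0))
  expect_false("environmental" %in% cat1)
  expect_equal(unname(cat1["water"]), "economic")
  expect_equal(unname(cat1["waste"]), "social")
})
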