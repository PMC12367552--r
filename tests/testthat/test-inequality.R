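test_that("weighted Gini matches hand-derived cases", {
  expect_equal(weighted_gini(c(2, 5, 1), c(0.4, 0.4, 0.4)), 0)
  expect_equal(weighted_gini(c(1, 1), c(0, 1)), 0.5)
  # scale invariance
  set.seed(31)
  p <- rgamma(20, 2); a <- runif(20)
  expect_equal(weighted_gini(p, a * 10), weighted_gini(p, a),
               tolerance = 1e-12)
  expect_message(g0 <- weighted_gini(c(1, 2), c(0, 0)), "zero")
  expect_equal(g0, 0)
  expect_error(weighted_gini(c(1, -1), c(0.2, 0.3)), "negative")
})

test_that("Lorenz-trapezoid Gini equals the pairwise-difference oracle", {
  set.seed(32)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    p <- rgamma(n, shape = runif(1, 0.5, 3))
    a <- rgamma(n, shape = runif(1, 0.5, 3))
    if (i %% 3 == 0) a[sample(n, ceiling(n / 4))] <- 0       # zeros
    if (i %% 4 == 0) a <- round(a, 1)                        # ties
    expect_equal(weighted_gini(p, a), gini_pairwise(p, a),
                 tolerance = 1e-12)
  }
})

test_that("Gini is invariant to merging cells with equal access", {
  set.seed(33)
  p <- c(1.5, 2.5, 3, 4); a <- c(0.2, 0.2, 0.7, 0.9)
  merged_p <- c(4, 3, 4); merged_a <- c(0.2, 0.7, 0.9)
  expect_equal(weighted_gini(p, a), weighted_gini(merged_p, merged_a),
               tolerance = 1e-14)
})

test_that("Gini respects the transfer principle and stays in [0, 1)", {
  set.seed(34)
  for (i in 1:20) {
    n <- 30
    p <- rgamma(n, 2)
    a <- rgamma(n, 1)
    g <- weighted_gini(p, a)
    expect_gte(g, 0); expect_lt(g, 1)
    # move access from a high cell to a low cell
    hi <- which.max(a); lo <- which.min(a)
    eps <- (a[hi] - a[lo]) * runif(1, 0, 0.5)
    a2 <- a; a2[hi] <- a2[hi] - eps; a2[lo] <- a2[lo] + eps
    expect_lte(weighted_gini(p, a2), g + 1e-12)
  }
  # concentration on a vanishing population share pushes Gini toward 1
  n <- 1000
  g_conc <- weighted_gini(rep(1, n), c(rep(0, n - 1), 1))
  expect_gt(g_conc, 0.99)
})

test_that("auxiliary inequality index hits its endpoints and range", {
  expect_equal(inequality_index(c(1, 2, 3), rep(0.5, 3)), 0)
  # all access mass on one of many equally populated cells -> approaches 1
  for (k in c(10, 100, 1000)) {
    val <- inequality_index(rep(1, k), c(1, rep(0, k - 1)))
    expect_equal(val, (k - 1) / k, tolerance = 1e-12)
  }
  set.seed(35)
  for (i in 1:20) {
    v <- inequality_index(rgamma(15, 2), rgamma(15, 1))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("unit-level inequality orders concentrated above equal", {
  part <- two_unit_partition(2, 8)
  pop <- grid_layer(matrix(1, 2, 8))
  infra <- matrix(0, 2, 8)
  infra[part$unit_ids == 1L] <- 0.5                # perfectly equal
  conc <- part$unit_ids == 2L
  infra[conc] <- 0; infra[which(conc)[1]] <- 1     # fully concentrated
  tab <- unit_inequality(pop, grid_layer(infra), part, "country", "econ")
  expect_equal(tab$gini[tab$unit_id == 1], 0)
  expect_gt(tab$gini[tab$unit_id == 2], tab$gini[tab$unit_id == 1])
  expect_true(all(tab$inq >= 0 & tab$inq <= 1))
})

test_that("single-cell units are flagged with Gini 0", {
  ids <- matrix(c(1L, 2L, 2L, 2L), 1, 4)
  part <- admin_partition(ids, data.frame(
    unit_id = 1:2, name = c("a", "b"), level = "country",
    region = "Asia", group = "South", parent_unit_id = NA_integer_))
  tab <- unit_inequality(make_layer(c(1, 1, 2, 1)),
                         make_layer(c(0.4, 0.1, 0.9, 0.2)), part,
                         "country")
  expect_true(tab$flagged[tab$unit_id == 1])
  expect_equal(tab$gini[tab$unit_id == 1], 0)
  expect_false(tab$flagged[tab$unit_id == 2])
})

test_that("unit inequality equals the pairwise oracle across random
           partitions", {
  set.seed(36)
  part <- two_unit_partition(5, 8)
  for (i in 1:10) {
    pop <- grid_layer(matrix(rgamma(40, 2), 5, 8))
    acc <- grid_layer(matrix(rgamma(40, 1), 5, 8))
    tab <- unit_inequality(pop, acc, part, "country")
    for (u in 1:2) {
      sel <- part$unit_ids == u
      expect_equal(tab$gini[tab$unit_id == u],
                   gini_pairwise(pop$values[sel], acc$values[sel]),
                   tolerance = 1e-12)
    }
  }
})
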