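test_that("write/read round-trip preserves values, mask and geometry", {
  set.seed(42)
  v <- matrix(rnorm(100), 10, 10)
  v[c(3, 47, 91)] <- NA
  gl <- grid_layer(v, cell_size = 0.1, origin = c(52.3, -4.7))
  path <- withr::local_tempfile(fileext = ".asc")
  write_layer(gl, path)
  back <- read_layer(path)

  expect_equal(n_valid(back), 97L)
  expect_identical(back$mask, gl$mask)
  expect_identical(back$values, gl$values)
  expect_equal(back$cell_size, gl$cell_size)
  expect_equal(back$origin, gl$origin, tolerance = 1e-9)
})

test_that("reader rejects missing, truncated and single-band violations", {
  expect_error(read_layer("no/such/file.asc"), "not found")
  path <- withr::local_tempfile(fileext = ".asc")
  write_layer(grid_layer(matrix(1, 2, 2)), path)
  expect_error(read_layer(path, band = 2), "single-band")
  txt <- readLines(path)
  writeLines(txt[-length(txt)], path)  # drop a data row
  expect_error(read_layer(path), "non-rectilinear")
})

test_that("constructor enforces shape agreement and layers must align", {
  expect_error(grid_layer(matrix(1, 2, 2), mask = matrix(TRUE, 3, 2)),
               "identical shape")
  a <- grid_layer(matrix(1, 2, 2))
  b <- grid_layer(matrix(1, 3, 3))
  expect_error(aggregate_category(list(a, b)), "shape mismatch")
})

test_that("align_stack block-averages finer layers over valid children", {
  fine <- grid_layer(matrix(1:16, 4, 4, byrow = TRUE), cell_size = 0.05)
  coarse <- grid_layer(matrix(0, 2, 2), cell_size = 0.1)
  out <- align_stack(list(fine, coarse))
  expect_equal(dim(out[[1]]), c(2L, 2L))
  expect_equal(out[[1]]$values[1, 1], mean(c(1, 2, 5, 6)))
  expect_equal(out[[1]]$values[2, 2], mean(c(11, 12, 15, 16)))
  # already aligned: returned unchanged
  expect_identical(out[[2]], coarse)

  ones <- matrix(1, 4, 4); ones[2, 3] <- NA
  out2 <- align_stack(list(grid_layer(ones, cell_size = 0.05),
                           coarse))[[1]]
  expect_true(all(out2$values == 1))  # mean over valid children only
})

test_that("align_stack rejects non-integer ratios and disjoint extents", {
  a <- grid_layer(matrix(1, 3, 3), cell_size = 0.07)
  b <- grid_layer(matrix(1, 2, 2), cell_size = 0.1)
  expect_error(align_stack(list(a, b)), "non-integer")
  c1 <- grid_layer(matrix(1, 2, 2), origin = c(10, 10))
  c2 <- grid_layer(matrix(1, 2, 2), origin = c(20, 20))
  expect_error(align_stack(list(c1, c2)), "origin")
})

test_that("block-mean downsampling preserves the valid-cell mean", {
  set.seed(7)
  for (i in 1:5) {
    v <- matrix(runif(144), 12, 12)
    v[sample(144, 10)] <- NA
    fine <- grid_layer(v, cell_size = 0.025)
    coarse <- align_stack(list(fine, grid_layer(matrix(0, 3, 3),
                                                cell_size = 0.1)))[[1]]
    # every coarse cell averages its own children, so the global
    # valid-weighted mean (weights = child counts) is preserved
    cnts <- sapply(0:8, function(k) {
      r <- (k %% 3) * 4 + 1:4; c <- (k %/% 3) * 4 + 1:4
      sum(!is.na(v[r, c]))
    })
    wm <- sum(as.vector(coarse$values)[cnts > 0] * cnts[cnts > 0]) /
      sum(cnts)
    expect_equal(wm, mean(v, na.rm = TRUE), tolerance = 1e-12)
  }
})

test_that("partition round-trips through files and validates metadata", {
  part <- two_unit_partition(4, 6)
  ids_path <- withr::local_tempfile(fileext = ".asc")
  units_path <- withr::local_tempfile(fileext = ".csv")
  write_partition(part, ids_path, units_path)
  back <- read_partition(ids_path, units_path)
  expect_identical(back$unit_ids, part$unit_ids)
  expect_identical(back$units$unit_id, part$units$unit_id)

  bad_units <- part$units[1, , drop = FALSE]  # id 2 missing from table
  expect_error(admin_partition(part$unit_ids, bad_units),
               "absent from table")
  orphan <- rbind(part$units, data.frame(
    unit_id = 9L, name = "c", level = "county", region = "Europe",
    group = "North", parent_unit_id = 77L))
  expect_error(admin_partition(part$unit_ids, orphan), "parent")
})

test_that("country-level IDs are derived from county parents", {
  ids <- matrix(c(11L, 11L, 12L, 12L), 2, 2)
  units <- rbind(
    data.frame(unit_id = 1L, name = "c1", level = "country",
               region = "Asia", group = "South",
               parent_unit_id = NA_integer_),
    data.frame(unit_id = c(11L, 12L), name = c("a", "b"),
               level = "county", region = "Asia", group = "South",
               parent_unit_id = 1L))
  part <- admin_partition(ids, units)
  expect_identical(partition_ids(part, "county"), ids)
  expect_true(all(partition_ids(part, "country") == 1L))
})
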