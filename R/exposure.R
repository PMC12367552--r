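#' Population-weighted infrastructure access per administrative unit
#'
#' For each unit, access is the population-weighted mean of the
#' infrastructure field over the unit's cells,
#' \deqn{IE = \sum_i P_i I_i / \sum_i P_i,}
#' so infrastructure located where people actually live counts more. Cells
#' missing either population or infrastructure are excluded from both sums
#' by default; with `treat_missing_as_zero = TRUE` cells with valid
#' population but masked infrastructure contribute weight with the
#' infrastructure value taken as 0.
#'
#' Units with zero total population or no usable cells are excluded with a
#' warning.
#'
#' @param pop Population [grid_layer] (non-negative).
#' @param infra Infrastructure [grid_layer], aligned with `pop`.
#' @param partition An [admin_partition] aligned with the layers.
#' @param level `"country"` or `"county"`.
#' @param treat_missing_as_zero See Details.
#' @return Data frame with columns `unit_id`, `ie_raw`, `n_cells`,
#'   `total_pop`.
#' @export
population_weighted_access <- function(pop, infra, partition,
                                       level = c("country", "county"),
                                       treat_missing_as_zero = FALSE) {
  level <- match.arg(level)
  assert_aligned(pop, infra)
  ids <- partition_ids(partition, level)
  if (!identical(dim(ids), dim(pop$values)))
    stop("partition is not aligned with the layers", call. = FALSE)
  pv <- valid_values_checked(pop)
  if (any(pv < 0)) stop("population must be non-negative", call. = FALSE)

  use <- pop$mask & ids != 0L
  if (treat_missing_as_zero) {
    iv <- infra$values
    iv[!infra$mask] <- 0
  } else {
    use <- use & infra$mask
    iv <- infra$values
  }
  id <- ids[use]
  p <- pop$values[use]
  x <- iv[use]
  if (length(id) == 0L) stop("no usable cells at this level", call. = FALSE)

  num <- tapply(p * x, id, sum)
  den <- tapply(p, id, sum)
  n_cells <- tapply(p, id, length)
  out <- data.frame(
    unit_id = as.integer(names(num)),
    ie_raw = as.numeric(num) / as.numeric(den),
    n_cells = as.integer(n_cells),
    total_pop = as.numeric(den)
  )
  bad <- out$total_pop <= 0 | !is.finite(out$ie_raw)
  out <- out[!bad, , drop = FALSE]
  all_units <- partition_units(partition, level)$unit_id
  absent <- setdiff(all_units, out$unit_id)
  if (length(absent))
    warning(length(absent), " unit(s) with zero population or no valid ",
            "cells excluded: ", paste(absent, collapse = ", "),
            call. = FALSE)
  rownames(out) <- NULL
  out
}

valid_values_checked <- function(x) {
  v <- valid_values(x)
  if (length(v) == 0L) stop("layer is fully masked", call. = FALSE)
  v
}

#' Normalize raw access values by the 95th percentile
#'
#' Raw population-weighted access is divided by the 95th percentile over
#' all units of the same level and category and capped at 1, giving a
#' standardized 0-1 access score. Percentiles use linear interpolation
#' between order statistics ([stats::quantile()] type 7).
#'
#' @param raw Data frame from [population_weighted_access()] (columns
#'   `unit_id`, `ie_raw`).
#' @param level,category Labels recorded in the output.
#' @return Data frame with columns `unit_id`, `level`, `category`,
#'   `ie_raw`, `ie_norm`.
#' @export
normalize_access <- function(raw, level, category) {
  stopifnot(is.data.frame(raw), all(c("unit_id", "ie_raw") %in% names(raw)))
  if (nrow(raw) < 2L)
    stop("at least 2 units are required for percentile normalization",
         call. = FALSE)
  q95 <- stats::quantile(raw$ie_raw, 0.95, names = FALSE, type = 7)
  if (q95 <= 0) stop("degenerate access distribution: 95th percentile is 0",
                     call. = FALSE)
  data.frame(
    unit_id = raw$unit_id,
    level = level,
    category = category,
    ie_raw = raw$ie_raw,
    ie_norm = pmin(raw$ie_raw / q95, 1)
  )
}

#' Population-weighting bias of access estimates
#'
#' Difference between the population-weighted and the unweighted mean of
#' the infrastructure field per unit. Positive values mean people are
#' concentrated near infrastructure; negative values mean infrastructure
#' sits away from where people live.
#'
#' @inheritParams population_weighted_access
#' @return Data frame with columns `unit_id`, `delta`.
#' @export
access_bias <- function(pop, infra, partition,
                        level = c("country", "county")) {
  level <- match.arg(level)
  weighted <- population_weighted_access(pop, infra, partition, level)
  ids <- partition_ids(partition, level)
  use <- pop$mask & infra$mask & ids != 0L
  unweighted <- tapply(infra$values[use], ids[use], mean)
  uw <- data.frame(unit_id = as.integer(names(unweighted)),
                   mean_unweighted = as.numeric(unweighted))
  m <- merge(weighted, uw, by = "unit_id")
  data.frame(unit_id = m$unit_id, delta = m$ie_raw - m$mean_unweighted)
}

#' Access table for all three categories
#'
#' Convenience wrapper running [population_weighted_access()] and
#' [normalize_access()] for each category layer at one level.
#'
#' @param pop Population [grid_layer].
#' @param layers Named list with elements `economic`, `social`,
#'   `environmental` ([grid_layer]s).
#' @param partition An [admin_partition].
#' @param level `"country"` or `"county"`.
#' @param treat_missing_as_zero Passed through.
#' @return Data frame stacking [normalize_access()] rows over categories.
#' @export
build_access_table <- function(pop, layers, partition,
                               level = c("country", "county"),
                               treat_missing_as_zero = FALSE) {
  level <- match.arg(level)
  stopifnot(all(infra_categories %in% names(layers)))
  out <- lapply(infra_categories, function(cat) {
    raw <- population_weighted_access(pop, layers[[cat]], partition, level,
                                      treat_missing_as_zero)
    normalize_access(raw, level, cat)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
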