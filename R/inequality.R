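#' Population-weighted Gini coefficient
#'
#' Inequality of access across the cells of a unit, with per-cell
#' population as the frequency weight and per-cell access as the "income"
#' analogue. Cells are sorted by access (ties grouped); the Lorenz curve
#' plots cumulative population share against cumulative share of total
#' population-weighted access, and the Gini coefficient is one minus twice
#' the trapezoid-integrated area under it. 0 means every population-bearing
#' cell shares one access value; values approach 1 as access concentrates
#' on a vanishing population share. The result is invariant to positive
#' rescaling of the access values.
#'
#' @param pop Numeric vector of non-negative weights, `sum(pop) > 0`.
#' @param access Numeric vector of non-negative access values.
#' @return Gini coefficient in `[0, 1)`.
#' @examples
#' weighted_gini(c(1, 1), c(0, 1))  # 0.5
#' @export
weighted_gini <- function(pop, access) {
  check_inequality_inputs(pop, access)
  keep <- pop > 0
  pop <- pop[keep]; access <- access[keep]
  tot <- sum(pop * access)
  if (tot == 0) {
    message("all access values are zero; Gini defined as 0")
    return(0)
  }
  # stable ascending sort; tied access values give collinear Lorenz
  # segments, so the order among ties cannot affect the trapezoid area
  o <- order(access)
  a <- access[o]
  p <- pop[o]
  x <- cumsum(p) / sum(p)
  y <- cumsum(p * a) / sum(p * a)
  x0 <- c(0, x[-length(x)])
  y0 <- c(0, y[-length(y)])
  g <- 1 - sum((x - x0) * (y + y0))
  max(g, 0)
}

check_inequality_inputs <- function(pop, access) {
  if (length(pop) != length(access))
    stop("`pop` and `access` must have equal length", call. = FALSE)
  if (anyNA(pop) || anyNA(access))
    stop("inputs must not contain NA; drop masked cells first",
         call. = FALSE)
  if (any(pop < 0) || any(access < 0))
    stop("negative inputs are not allowed", call. = FALSE)
  if (sum(pop) <= 0) stop("total population must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Auxiliary inequality index
#'
#' A complementary 0-1 inequality measure: half the population-weighted
#' relative mean absolute deviation of access,
#' \deqn{Inq = \min\left(1, \frac{\sum_i p_i |a_i - \bar a_w|}
#'   {2\,\bar a_w \sum_i p_i}\right),}
#' where \eqn{\bar a_w} is the population-weighted mean access. 0 means
#' absolute equality; the index approaches 1 as all access mass collapses
#' onto a vanishing share of the population. The measure is pluggable: any
#' function `(pop, access) -> [0,1]` can replace it via the `inq_fun`
#' argument of [unit_inequality()].
#'
#' @inheritParams weighted_gini
#' @return Index in `[0, 1]`.
#' @export
inequality_index <- function(pop, access) {
  check_inequality_inputs(pop, access)
  keep <- pop > 0
  pop <- pop[keep]; access <- access[keep]
  abar <- sum(pop * access) / sum(pop)
  if (abar == 0) {
    message("all access values are zero; inequality index defined as 0")
    return(0)
  }
  mad <- sum(pop * abs(access - abar)) / sum(pop)
  min(mad / (2 * abar), 1)
}

#' Within-unit access inequality over a partition
#'
#' Applies [weighted_gini()] (and optionally an auxiliary index) to the
#' cells of each administrative unit. Single-cell units receive Gini 0 and
#' are flagged.
#'
#' @param pop Population [grid_layer].
#' @param infra Infrastructure [grid_layer] (access field).
#' @param partition An [admin_partition].
#' @param level `"country"` or `"county"`.
#' @param category Category label recorded in the output.
#' @param inq_fun Auxiliary index function `(pop, access) -> number`, or
#'   `NULL` to skip. Defaults to [inequality_index()].
#' @return Data frame with columns `unit_id`, `level`, `category`, `gini`,
#'   `inq`, `n_cells`, `flagged` (TRUE for degenerate single-cell units).
#' @export
unit_inequality <- function(pop, infra, partition,
                            level = c("country", "county"),
                            category = NA_character_,
                            inq_fun = inequality_index) {
  level <- match.arg(level)
  assert_aligned(pop, infra)
  ids <- partition_ids(partition, level)
  use <- pop$mask & infra$mask & ids != 0L & pop$values > 0
  id <- ids[use]
  p <- pop$values[use]
  a <- infra$values[use]
  uids <- sort(unique(id))
  res <- lapply(uids, function(u) {
    i <- id == u
    n <- sum(i)
    if (n == 1L) {
      data.frame(unit_id = u, level = level, category = category,
                 gini = 0, inq = if (is.null(inq_fun)) NA_real_ else 0,
                 n_cells = 1L, flagged = TRUE)
    } else {
      data.frame(unit_id = u, level = level, category = category,
                 gini = suppressMessages(weighted_gini(p[i], a[i])),
                 inq = if (is.null(inq_fun)) NA_real_ else
                   suppressMessages(inq_fun(p[i], a[i])),
                 n_cells = n, flagged = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Inequality table for all three categories
#'
#' @inheritParams unit_inequality
#' @param layers Named list with `economic`, `social`, `environmental`
#'   [grid_layer]s.
#' @return Stacked [unit_inequality()] rows over categories.
#' @export
build_inequality_table <- function(pop, layers, partition,
                                   level = c("country", "county"),
                                   inq_fun = inequality_index) {
  level <- match.arg(level)
  stopifnot(all(infra_categories %in% names(layers)))
  out <- lapply(infra_categories, function(cat)
    unit_inequality(pop, layers[[cat]], partition, level, cat, inq_fun))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
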