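# Independent oracles and fixture builders used across the suite.

# Gini by the pairwise-difference definition:
# G = sum_ij p_i p_j |a_i - a_j| / (2 (sum p)^2 abar_w)
gini_pairwise <- function(pop, access) {
  abar <- sum(pop * access) / sum(pop)
  if (abar == 0) return(0)
  num <- sum(outer(pop, pop) * abs(outer(access, access, "-")))
  num / (2 * sum(pop)^2 * abar)
}

# Closed-form simple OLS of y on x
ols_closed_form <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Small grid layer from a vector (column-major, matching valid_values
# order), NA = masked
make_layer <- function(v, nrow = 1L, cell_size = 0.1) {
  grid_layer(matrix(v, nrow = nrow), cell_size = cell_size)
}

# One-country partition covering an r x c grid
one_unit_partition <- function(r, c) {
  admin_partition(
    matrix(1L, r, c),
    data.frame(unit_id = 1L, name = "only", level = "country",
               region = "Europe", group = "North",
               parent_unit_id = NA_integer_)
  )
}

# Two-country partition: left half unit 1, right half unit 2
two_unit_partition <- function(r, c) {
  ids <- matrix(2L, r, c)
  ids[, seq_len(c %/% 2)] <- 1L
  admin_partition(
    ids,
    data.frame(unit_id = 1:2, name = c("a", "b"), level = "country",
               region = c("Europe", "Africa"), group = c("North", "South"),
               parent_unit_id = NA_integer_)
  )
}
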