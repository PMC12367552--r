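#' Classify one access dimension into H/M/L levels
#'
#' Units are labelled low (`L`) below the 25th percentile, high (`H`) above
#' the 75th percentile and medium (`M`) in between, with quantiles computed
#' over the supplied units (linear interpolation, [stats::quantile()]
#' type 7). Values exactly equal to a threshold are `M`: `H` and `L` mark
#' genuine quartile exceedances. Because the rule depends only on ranks,
#' any strictly monotone transform of the values yields the same labels.
#'
#' @param values Numeric vector of per-unit access values (length >= 4).
#' @return Character vector of levels in `{"H", "M", "L"}`.
#' @export
classify_dimension <- function(values) {
  if (length(values) < 4L)
    stop("at least 4 units are required for quartile classification",
         call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1] == q[2]) {
    warning("degenerate quantiles (q25 == q75); all units classed M",
            call. = FALSE)
    return(rep("M", length(values)))
  }
  ifelse(values < q[1], "L", ifelse(values > q[2], "H", "M"))
}

#' Composite category label from per-dimension levels
#'
#' Joins the economic, social and environmental levels, in that fixed
#' order, into one of the 27 labels such as `"H-M-L"`.
#'
#' @param economic,social,environmental Levels in `{"H", "M", "L"}`;
#'   vectors are recycled element-wise.
#' @return Character vector of category labels.
#' @export
composite_category <- function(economic, social, environmental) {
  check_levels(economic); check_levels(social); check_levels(environmental)
  paste(economic, social, environmental, sep = "-")
}

check_levels <- function(x) {
  bad <- !(x %in% c("H", "M", "L"))
  if (any(bad))
    stop("invalid level symbol: ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' All 27 composite categories
#'
#' @return Character vector of the 27 labels, economic varying slowest.
#' @export
category_space <- function() {
  lv <- c("H", "M", "L")
  g <- expand.grid(env = lv, soc = lv, eco = lv,
                   stringsAsFactors = FALSE)
  paste(g$eco, g$soc, g$env, sep = "-")
}

#' General class from per-dimension levels
#'
#' Class `I`: no dimension is low (access above average with minor
#' disparities). Class `II`: at least one high and one low dimension
#' (marked disparities). Class `III`: no dimension reaches high. Every
#' level triple receives exactly one class.
#'
#' @inheritParams composite_category
#' @return Character vector in `{"I", "II", "III"}`.
#' @examples
#' assign_class("H", "H", "L")  # "II"
#' assign_class("M", "M", "M")  # "I"
#' @export
assign_class <- function(economic, social, environmental) {
  check_levels(economic); check_levels(social); check_levels(environmental)
  n <- max(length(economic), length(social), length(environmental))
  eco <- rep_len(economic, n); soc <- rep_len(social, n)
  env <- rep_len(environmental, n)
  out <- character(n)
  for (i in seq_len(n)) {
    lv <- c(eco[i], soc[i], env[i])
    out[i] <- if (!any(lv == "L")) "I"
      else if (any(lv == "H")) "II"
      else "III"
  }
  out
}

#' Composite classification of an access table
#'
#' Turns a normalized access table (one row per unit x category) into one
#' composite record per unit: per-dimension H/M/L levels, the 27-way
#' category label, and the general class.
#'
#' @param access Data frame from [build_access_table()] with columns
#'   `unit_id`, `level`, `category`, `ie_norm`.
#' @param value_col Column holding the access value to classify
#'   (default `"ie_norm"`).
#' @return Data frame with columns `unit_id`, `level`, `econ_level`,
#'   `soc_level`, `env_level`, `category`, `general_class`.
#' @export
classify_access <- function(access, value_col = "ie_norm") {
  stopifnot(is.data.frame(access),
            all(c("unit_id", "level", "category", value_col) %in%
                  names(access)))
  lev <- unique(access$level)
  if (length(lev) != 1L)
    stop("classify one administrative level at a time", call. = FALSE)
  wide <- list()
  for (cat in infra_categories) {
    sub <- access[access$category == cat, c("unit_id", value_col)]
    if (nrow(sub) == 0L) stop("missing category: ", cat, call. = FALSE)
    names(sub)[2L] <- cat
    wide[[cat]] <- sub
  }
  m <- Reduce(function(a, b) merge(a, b, by = "unit_id"), wide)
  if (anyNA(m)) stop("units must have all three categories", call. = FALSE)
  econ <- classify_dimension(m$economic)
  soc <- classify_dimension(m$social)
  env <- classify_dimension(m$environmental)
  data.frame(
    unit_id = m$unit_id,
    level = lev,
    econ_level = econ,
    soc_level = soc,
    env_level = env,
    category = composite_category(econ, soc, env),
    general_class = assign_class(econ, soc, env)
  )
}
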