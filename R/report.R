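#' Group summary of access or inequality values
#'
#' Mean, standard deviation and count per group, the building block of the
#' grouped summary tables (Global North vs South, regions, global).
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of equal length.
#' @return Data frame with columns `group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(values, g, mean)),
    sd = as.numeric(tapply(values, g, stats::sd)),
    row.names = NULL
  )
}

#' Ratio of two group means at printed precision
#'
#' Headline comparisons such as "access in one group is 1.25 times that in
#' the other" are ratios of group means reported to two decimals. This
#' routine computes that ratio from the (already rounded) printed means
#' and rounds the result the same way.
#'
#' @param numerator,denominator Group mean values (printed precision).
#' @param digits Decimals of the reported ratio (default 2).
#' @return Rounded ratio `numerator / denominator`.
#' @examples
#' group_mean_ratio(0.45, 0.36)  # 1.25
#' @export
group_mean_ratio <- function(numerator, denominator, digits = 2L) {
  if (any(denominator == 0)) stop("denominator mean is zero", call. = FALSE)
  round(numerator / denominator, digits)
}

#' Published reference group summary statistics
#'
#' Country-level reference summary statistics (mean and sd of access and
#' Gini by group and region, at printed precision) distributed with the
#' package, used as inputs for ratio recomputation and for context in
#' reports.
#'
#' @return Data frame with columns `region`, `n`, `measure`
#'   (`"access"`/`"gini"`), `category`, `mean`, `sd`.
#' @export
reference_group_summary <- function() {
  path <- system.file("extdata", "global_group_summary.csv",
                      package = "infraccess", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published reference mixed-model coefficient table
#'
#' Reference coefficient estimates (with standard errors, z, p and 95%
#' CIs, at printed precision) of the three country-level health models
#' with HALE as response, distributed with the package. The `p` column
#' holds 0.001 where the printed value is an upper bound "<0.001".
#'
#' @param model_id `"I"`, `"II"`, `"III"` or `"all"`.
#' @return List with `coefficients` (data frame: `model`, `term`,
#'   `estimate`, `se`, `z`, `p`, `ci_low`, `ci_high`) and `r2` (named
#'   vector), shaped so it can be passed to [predicted_health_change()].
#' @export
reference_model_coefficients <- function(model_id = c("III", "I", "II",
                                                      "all")) {
  model_id <- match.arg(model_id)
  path <- system.file("extdata", "reference_model_coefficients.csv",
                      package = "infraccess", mustWork = TRUE)
  cf <- utils::read.csv(path, stringsAsFactors = FALSE)
  r2 <- c(I = 0.60, II = 0.65, III = 0.66)
  if (model_id != "all") {
    cf <- cf[cf$model == model_id, , drop = FALSE]
    r2 <- r2[model_id]
  }
  rownames(cf) <- NULL
  list(coefficients = cf, r2 = r2)
}

#' Grouped report tables from pipeline outputs
#'
#' Builds the two standard report tables from per-unit results joined to
#' unit metadata: per-group/region mean +/- sd with t or ANOVA statistics
#' for every measure x category, and North/South (access) and South/North
#' (inequality) mean ratios.
#'
#' @param access Access table ([build_access_table()] output).
#' @param inequality Inequality table ([build_inequality_table()] output).
#' @param units Unit metadata (from [partition_units()]).
#' @return List with `summary` (group, region rows), `tests` (one
#'   [group_comparisons()] row per measure x category x grouping) and
#'   `ratios` (measure, category, ratio).
#' @export
report_tables <- function(access, inequality, units) {
  acc <- merge(access, units[, c("unit_id", "region", "group")],
               by = "unit_id")
  ine <- merge(inequality, units[, c("unit_id", "region", "group")],
               by = "unit_id")
  long <- rbind(
    data.frame(measure = "access", category = acc$category,
               value = acc$ie_norm, group = acc$group,
               region = acc$region),
    data.frame(measure = "gini", category = ine$category,
               value = ine$gini, group = ine$group, region = ine$region)
  )
  combos <- unique(long[, c("measure", "category")])
  summaries <- list(); tests <- list(); ratios <- list()
  for (i in seq_len(nrow(combos))) {
    ms <- combos$measure[i]; ct <- combos$category[i]
    sub <- long[long$measure == ms & long$category == ct, ]
    gs <- group_summary(sub$value, sub$group)
    gs$measure <- ms; gs$category <- ct; gs$grouping <- "group"
    rs <- group_summary(sub$value, sub$region)
    rs$measure <- ms; rs$category <- ct; rs$grouping <- "region"
    summaries[[length(summaries) + 1L]] <- rbind(gs, rs)

    # comparison tests need every group populated with >= 2 units
    if (all(table(sub$group) >= 2L) && length(unique(sub$group)) >= 2L) {
      tg <- group_comparisons(sub$value, sub$group)
      tg$measure <- ms; tg$category <- ct; tg$grouping <- "group"
      tests[[length(tests) + 1L]] <- tg
    }
    if (length(unique(sub$region)) > 2L && all(table(sub$region) >= 2L)) {
      tr <- group_comparisons(sub$value, sub$region)
      tr$measure <- ms; tr$category <- ct; tr$grouping <- "region"
      tests[[length(tests) + 1L]] <- tr
    }

    mn <- gs$mean[gs$group == "North"]; msouth <- gs$mean[gs$group == "South"]
    if (length(mn) == 1L && length(msouth) == 1L) {
      ratios[[length(ratios) + 1L]] <- data.frame(
        measure = ms, category = ct,
        # access reported North over South, inequality South over North
        ratio = if (ms == "access") group_mean_ratio(round(mn, 2),
                                                     round(msouth, 2))
                else group_mean_ratio(round(msouth, 2), round(mn, 2))
      )
    }
  }
  list(summary = do.call(rbind, summaries),
       tests = do.call(rbind, tests),
       ratios = if (length(ratios)) do.call(rbind, ratios) else NULL)
}
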