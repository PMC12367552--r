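health_covariates <- c("ExpEco", "ExpSoc", "GiniEco", "GiniSoc",
                       "LnPop", "LnGDP")

model_terms <- function(model_id) {
  switch(model_id,
    "I"   = c("ExpEco", "ExpSoc", "LnPop", "LnGDP"),
    "II"  = c("GiniEco", "GiniSoc", "LnPop", "LnGDP"),
    "III" = c("ExpEco", "ExpSoc", "GiniEco", "GiniSoc", "LnPop", "LnGDP"),
    stop("model_id must be 'I', 'II' or 'III'", call. = FALSE))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Two-sided test of association with a 95% CI obtained through the Fisher
#' z-transform, as reported for access-health scatter relationships.
#'
#' @param x,y Numeric vectors, `n >= 4`, finite, non-constant.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y) || length(x) < 4L)
    stop("x and y must have equal length >= 4", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  ct <- stats::cor.test(x, y, conf.level = conf_level)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1L],
       ci_high = ct$conf.int[2L], p = ct$p.value, n = length(x))
}

#' Fit a health-association mixed-effects model
#'
#' Linear mixed-effects regression of a country-level health outcome
#' (HALE, or DALYs) on infrastructure access and/or access-inequality
#' covariates with population and GDP controls, and a random intercept for
#' the North/South group capturing baseline health differences:
#' Model `"I"` uses access covariates (`ExpEco`, `ExpSoc`) only, `"II"`
#' inequality covariates (`GiniEco`, `GiniSoc`) only, `"III"` all four;
#' `LnPop` and `LnGDP` enter every model.
#'
#' Diagnostics follow the reporting convention of the study design:
#' a Kolmogorov-Smirnov test of the response against a normal with
#' estimated mean/sd decides whether the response is log-transformed
#' (only when KS p < 0.05); Levene's test on residuals across groups
#' decides whether heteroscedasticity-consistent (sandwich, HC1-style)
#' standard errors replace the model-based ones (when Levene p < 0.05).
#' Wald z statistics, two-sided p-values and 95% CIs are reported without
#' multiplicity adjustment; R-squared is the squared correlation between
#' fitted and observed response.
#'
#' A random intercept over only two groups is statistically fragile and
#' often estimated with zero variance (the fit then degenerates to
#' ordinary least squares); a diagnostic message is emitted and
#' `group_as_fixed = TRUE` offers a fixed-effect-group fallback.
#'
#' @param data Data frame with columns `group` (`"North"`/`"South"`), the
#'   response, and the model covariates.
#' @param model_id `"I"`, `"II"` or `"III"`.
#' @param response Response column name (default `"HALE"`).
#' @param group_as_fixed Replace the random intercept by a group fixed
#'   effect (ordinary least squares).
#' @param robust_threshold Levene p-value below which sandwich SEs are
#'   used (default 0.05).
#' @return A `health_model` object: list with `model_id`, `response`,
#'   `coefficients` (term, estimate, se, z, p, ci_low, ci_high),
#'   `random_intercepts`, `ranef_var`, `sigma2`, `r2`, `ks`, `levene`,
#'   `robust_se_used`, `log_transformed`, `singular`, `n`, `fit`.
#' @export
fit_health_model <- function(data, model_id = c("III", "I", "II"),
                             response = "HALE", group_as_fixed = FALSE,
                             robust_threshold = 0.05) {
  model_id <- match.arg(model_id)
  terms <- model_terms(model_id)
  need <- c("group", response, terms)
  if (!all(need %in% names(data)))
    stop("missing columns: ",
         paste(setdiff(need, names(data)), collapse = ", "), call. = FALSE)
  if (anyNA(data[need])) stop("missing values in model columns",
                              call. = FALSE)
  groups <- unique(data$group)
  if (length(groups) < 2L)
    stop("at least 2 groups are required for the random intercept",
         call. = FALSE)

  y <- data[[response]]
  ks <- suppressWarnings(
    stats::ks.test(y, "pnorm", mean = mean(y), sd = stats::sd(y)))
  log_transformed <- ks$p.value < 0.05
  if (log_transformed) {
    if (any(y <= 0))
      stop("log transform requested by KS test but response has ",
           "non-positive values", call. = FALSE)
    y <- log(y)
  }
  df <- data
  df$.y <- y
  df$group <- factor(df$group)

  rhs <- paste(terms, collapse = " + ")
  if (group_as_fixed) {
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs, "+ group")),
                     data = df)
    X <- stats::model.matrix(fit)
    beta_all <- stats::coef(fit)
    sigma2 <- summary(fit)$sigma^2
    Vinv_fun <- NULL
    tau2 <- 0
    singular <- FALSE
    ran <- data.frame(group = character(0), intercept = numeric(0))
    fitted_y <- stats::fitted(fit)
    resid_y <- stats::resid(fit)
    vc <- stats::vcov(fit)
  } else {
    fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 | group)"))
    fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE))
    singular <- lme4::isSingular(fit)
    if (singular)
      message("random-intercept variance estimated at the boundary ",
              "(singular fit); with few groups consider group_as_fixed")
    else if (length(levels(df$group)) == 2L)
      message("random intercept over only 2 groups is fragile; ",
              "interpret its variance with caution")
    X <- lme4::getME(fit, "X")
    beta_all <- lme4::fixef(fit)
    vcomp <- lme4::VarCorr(fit)
    tau2 <- as.numeric(vcomp$group[1L])
    sigma2 <- stats::sigma(fit)^2
    re <- lme4::ranef(fit)$group
    ran <- data.frame(group = rownames(re), intercept = re[[1L]])
    fitted_y <- stats::fitted(fit)
    resid_y <- stats::resid(fit)
    vc <- as.matrix(stats::vcov(fit))
  }

  lev <- car::leveneTest(resid_y ~ df$group)
  levene_F <- lev$`F value`[1L]
  levene_p <- lev$`Pr(>F)`[1L]
  robust <- is.finite(levene_p) && levene_p < robust_threshold
  if (robust)
    vc <- robust_vcov(X, df$.y, beta_all, df$group, sigma2, tau2)

  se <- sqrt(diag(vc))
  z <- beta_all / se
  p <- 2 * stats::pnorm(-abs(z))
  zq <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = names(beta_all),
    estimate = unname(beta_all),
    se = unname(se),
    z = unname(z),
    p = unname(p),
    ci_low = unname(beta_all - zq * se),
    ci_high = unname(beta_all + zq * se)
  )
  rownames(coefs) <- NULL

  structure(list(
    model_id = model_id,
    response = response,
    coefficients = coefs,
    random_intercepts = ran,
    ranef_var = tau2,
    sigma2 = sigma2,
    r2 = stats::cor(fitted_y, df$.y)^2,
    ks = c(D = unname(ks$statistic), p = ks$p.value),
    levene = c(F = levene_F, p = levene_p),
    robust_se_used = robust,
    log_transformed = log_transformed,
    singular = singular,
    n = nrow(df),
    fit = fit
  ), class = "health_model")
}

# HC1-style sandwich covariance for the fixed effects of a random-intercept
# model: bread (X' V^-1 X)^-1 with V = sigma2 I + tau2 * same-group,
# meat X' V^-1 diag(e^2) V^-1 X scaled by n/(n - p), e the marginal
# residuals y - X beta.
robust_vcov <- function(X, y, beta, group, sigma2, tau2) {
  n <- nrow(X); p <- ncol(X)
  V <- diag(sigma2, n)
  if (tau2 > 0) {
    same <- outer(as.integer(factor(group)), as.integer(factor(group)),
                  "==")
    V <- V + tau2 * same
  }
  W <- solve(V)
  bread <- solve(crossprod(X, W %*% X))
  e <- as.numeric(y - X %*% beta)
  meat <- crossprod(X, W %*% (e^2 * (W %*% X))) * n / (n - p)
  vc <- bread %*% meat %*% bread
  dimnames(vc) <- list(colnames(X), colnames(X))
  vc
}

#' @export
print.health_model <- function(x, ...) {
  cat(sprintf("<health_model> Model %s, response %s%s, n = %d\n",
              x$model_id, x$response,
              if (x$log_transformed) " (log)" else "", x$n))
  cat(sprintf("  R2 = %.3f; KS D = %.3f (p = %.3f); Levene F = %.2f (p = %.3g); %s SEs\n",
              x$r2, x$ks["D"], x$ks["p"], x$levene["F"], x$levene["p"],
              if (x$robust_se_used) "robust (sandwich)" else "model-based"))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Linear-predictor health change for a covariate shift
#'
#' Returns `beta * delta`, the change in the linear predictor of the
#' fitted health model when one covariate moves by `delta` with all others
#' held fixed (for example, a 0.10 increase in the economic access Gini).
#'
#' @param result A `health_model`, or any list carrying a `coefficients`
#'   data frame with columns `term` and `estimate`.
#' @param covariate Covariate name.
#' @param delta Shift in the covariate's own units.
#' @return Numeric change in the (possibly log) response scale.
#' @export
predicted_health_change <- function(result, covariate, delta) {
  cf <- result$coefficients
  if (is.null(cf) || !all(c("term", "estimate") %in% names(cf)))
    stop("`result` must carry a coefficients table", call. = FALSE)
  i <- match(covariate, cf$term)
  if (is.na(i)) stop("unknown covariate: ", covariate, call. = FALSE)
  cf$estimate[i] * delta
}

#' Random-forest variable importance distributions
#'
#' Fits a random forest of `n_trees` trees `n_runs` times with distinct
#' seeds derived from `seed`, and collects per-covariate distributions of
#' the two standard importance measures: increase in mean squared error
#' under permutation and increase in node purity.
#'
#' @param data Data frame holding `response` and the covariates.
#' @param response Response column name.
#' @param covariates Covariate column names (default: the six model
#'   covariates).
#' @param n_trees Trees per forest (default 500).
#' @param n_runs Number of repeated fits (default 100).
#' @param seed Master seed; run `i` uses `seed + i`.
#' @return Data frame with columns `run`, `term`, `inc_mse`,
#'   `inc_node_purity`.
#' @export
rf_importance <- function(data, response, covariates = health_covariates,
                          n_trees = 500L, n_runs = 100L, seed = 1L) {
  need <- c(response, covariates)
  if (!all(need %in% names(data)))
    stop("missing columns: ",
         paste(setdiff(need, names(data)), collapse = ", "), call. = FALSE)
  x <- data[covariates]
  y <- data[[response]]
  if (nrow(x) < 5L) stop("too few observations to grow a forest",
                         call. = FALSE)
  out <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(seed + i)
    rf <- randomForest::randomForest(x, y, ntree = n_trees,
                                     importance = TRUE)
    imp <- randomForest::importance(rf)
    out[[i]] <- data.frame(
      run = i,
      term = rownames(imp),
      inc_mse = imp[, "%IncMSE"],
      inc_node_purity = imp[, "IncNodePurity"]
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group-difference statistics
#'
#' Two groups: two-sided pooled-variance t-test with Cohen's d. More than
#' two groups: two-sided one-way ANOVA with Cohen's f
#' (\eqn{f = \sqrt{\eta^2 / (1 - \eta^2)}}). No multiple-comparison
#' adjustment is applied.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length, >= 2 groups with
#'   >= 2 observations each.
#' @return One-row data frame: `test`, `statistic`, `df1`, `df2`, `p`,
#'   `effect_name`, `effect`, `n_groups`.
#' @export
group_comparisons <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  g <- factor(groups)
  tab <- table(g)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  if (length(tab) == 2L) {
    sp <- split(values, g)
    tt <- stats::t.test(sp[[1L]], sp[[2L]], var.equal = TRUE)
    n1 <- length(sp[[1L]]); n2 <- length(sp[[2L]])
    pooled_sd <- sqrt(((n1 - 1) * stats::var(sp[[1L]]) +
                       (n2 - 1) * stats::var(sp[[2L]])) / (n1 + n2 - 2))
    d <- if (pooled_sd == 0) 0 else
      (mean(sp[[1L]]) - mean(sp[[2L]])) / pooled_sd
    data.frame(test = "t", statistic = unname(tt$statistic),
               df1 = 1, df2 = unname(tt$parameter), p = tt$p.value,
               effect_name = "cohen_d", effect = d, n_groups = 2L)
  } else {
    fit <- stats::aov(values ~ g)
    an <- summary(fit)[[1L]]
    ss_b <- an$`Sum Sq`[1L]; ss_w <- an$`Sum Sq`[2L]
    eta2 <- ss_b / (ss_b + ss_w)
    data.frame(test = "anova", statistic = an$`F value`[1L],
               df1 = an$Df[1L], df2 = an$Df[2L], p = an$`Pr(>F)`[1L],
               effect_name = "cohen_f", effect = sqrt(eta2 / (1 - eta2)),
               n_groups = length(tab))
  }
}
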