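#' Configuration for the synthetic study world
#'
#' Bundles every knob of the synthetic-world generator with defaults
#' emulating the structure of the real gridded inputs: log-normally
#' clustered population, per-type infrastructure counts positively coupled
#' to population with strong abundance skew (power poles and roads
#' vastly outnumber hospitals), smooth ambient fields, night-time lights
#' as a noisy power law of economic infrastructure, and country health
#' outcomes from the full linear predictor with group random intercepts.
#'
#' Randomness is hierarchically seeded: the world seed spawns a fixed
#' child seed per layer, so adding or regenerating one layer never
#' perturbs the others.
#'
#' @param seed World seed (integer).
#' @param n_row,n_col Grid shape (cells).
#' @param cell_size Cell size in degrees.
#' @param n_countries Number of countries (>= 4).
#' @param counties_per_country Counties per country (a perfect square
#'   lays out cleanly; default 4).
#' @param frac_north Fraction of countries in the Global North group.
#' @param pop_mu,pop_sigma Log-scale location and dispersion of cell
#'   population.
#' @param pop_gain Log-population lift at cluster centres.
#' @param clusters_per_country,cluster_spread Population cluster count and
#'   spatial spread (cells).
#' @param concentration Exponent coupling infrastructure to population
#'   (the inequality knob): scalar, or one value per country. 0 gives a
#'   spatially uniform expected count (the equality extreme); larger
#'   values concentrate infrastructure where people are, raising
#'   within-country Gini.
#' @param concentration_range If non-`NULL`, a length-2 range from which
#'   per-country concentrations are drawn, overriding `concentration`
#'   (heterogeneous worlds).
#' @param abundance Named expected count scale per infrastructure type.
#' @param count_size Negative-binomial size (inverse overdispersion) of
#'   the count draws.
#' @param env_corr_len Correlation length (cells) of the smooth ambient
#'   fields (green, air, heat).
#' @param ntl_a,ntl_b,ntl_noise_sd True slope/intercept of the log-log
#'   night-time-lights law and its log-scale noise.
#' @param beta Named true coefficients of the health linear predictor:
#'   `const`, `LnPop`, `LnGDP`, `ExpEco`, `ExpSoc`, `GiniEco`, `GiniSoc`.
#' @param gamma_sd Standard deviation of the group random intercepts.
#' @param resid_sd Residual standard deviation of the health outcome.
#' @param heteroscedastic If `TRUE`, the South group's residual sd is
#'   tripled, exercising the Levene/sandwich path.
#' @return A `world_config` list.
#' @export
world_config <- function(seed = 1L,
                         n_row = 60L, n_col = 96L, cell_size = 0.1,
                         n_countries = 12L, counties_per_country = 4L,
                         frac_north = 1 / 3,
                         pop_mu = 3, pop_sigma = 1, pop_gain = 3,
                         clusters_per_country = 3L, cluster_spread = 4,
                         concentration = 1.2,
                         concentration_range = NULL,
                         abundance = c(telecom = 500, energy = 2000,
                                       transport = 1000, health = 50,
                                       education = 80, water = 100,
                                       waste = 60),
                         count_size = 20,
                         env_corr_len = 5L,
                         ntl_a = 1.58, ntl_b = 5.03, ntl_noise_sd = 0.3,
                         beta = c(const = 66.86, LnPop = -2.07,
                                  LnGDP = 2.01, ExpEco = 3.84,
                                  ExpSoc = 2.23, GiniEco = -9.95,
                                  GiniSoc = 3.03),
                         gamma_sd = 2, resid_sd = 3,
                         heteroscedastic = FALSE) {
  if (n_countries < 4L) stop("n_countries must be >= 4", call. = FALSE)
  stopifnot(pop_sigma > 0, count_size > 0, ntl_noise_sd >= 0,
            gamma_sd > 0, resid_sd > 0)
  req <- c("const", "LnPop", "LnGDP", "ExpEco", "ExpSoc", "GiniEco",
           "GiniSoc")
  if (!all(req %in% names(beta)))
    stop("beta must name: ", paste(req, collapse = ", "), call. = FALSE)
  cfg <- list(seed = as.integer(seed), n_row = as.integer(n_row),
              n_col = as.integer(n_col), cell_size = cell_size,
              n_countries = as.integer(n_countries),
              counties_per_country = as.integer(counties_per_country),
              frac_north = frac_north, pop_mu = pop_mu,
              pop_sigma = pop_sigma, pop_gain = pop_gain,
              clusters_per_country = as.integer(clusters_per_country),
              cluster_spread = cluster_spread,
              concentration = concentration,
              concentration_range = concentration_range,
              abundance = abundance, count_size = count_size,
              env_corr_len = as.integer(env_corr_len),
              ntl_a = ntl_a, ntl_b = ntl_b, ntl_noise_sd = ntl_noise_sd,
              beta = beta[req], gamma_sd = gamma_sd, resid_sd = resid_sd,
              heteroscedastic = isTRUE(heteroscedastic))
  class(cfg) <- "world_config"
  cfg
}

# fixed child-seed offsets (hierarchical seeding)
child_seed <- function(config, layer) {
  offsets <- c(partition = 11L, pop = 23L, telecom = 31L, energy = 32L,
               transport = 33L, health = 34L, education = 35L,
               water = 36L, waste = 37L, green = 41L, air = 42L,
               heat = 43L, ntl = 51L, gdp = 61L, health_outcome = 71L,
               concentration = 81L)
  off <- offsets[[layer]]
  (config$seed %% 2000000000L) + off
}

#' Ground truth of a world configuration
#'
#' The configured true parameter values a recovery test should see:
#' night-time-lights law coefficients, health coefficients, random
#' intercept scale, and per-country concentration with the implied
#' expected within-country inequality ordering.
#'
#' @param config A [world_config()].
#' @return List with `ntl_a`, `ntl_b`, `beta`, `gamma_sd`, `resid_sd`,
#'   `concentration`, `expected_gini_order` (unit IDs, most equal first).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "world_config"))
  conc <- country_concentrations(config)
  list(ntl_a = config$ntl_a, ntl_b = config$ntl_b, beta = config$beta,
       gamma_sd = config$gamma_sd, resid_sd = config$resid_sd,
       concentration = conc,
       expected_gini_order = order(conc))
}

country_concentrations <- function(config) {
  n <- config$n_countries
  if (!is.null(config$concentration_range)) {
    set.seed(child_seed(config, "concentration"))
    stats::runif(n, config$concentration_range[1L],
                 config$concentration_range[2L])
  } else {
    rep_len(config$concentration, n)
  }
}

# circular moving-average smoothing along rows then columns
smooth_field <- function(m, corr_len) {
  if (corr_len <= 0L) return(m)
  k <- rep(1 / (2 * corr_len + 1), 2 * corr_len + 1)
  m <- apply(m, 2L, function(col)
    as.numeric(stats::filter(col, k, sides = 2, circular = TRUE)))
  t(apply(m, 1L, function(row)
    as.numeric(stats::filter(row, k, sides = 2, circular = TRUE))))
}

# rank-transform a matrix to (0, 1)
to_unit <- function(m) {
  r <- rank(m, ties.method = "average")
  matrix((r - 0.5) / length(m), nrow(m), ncol(m))
}

region_pool <- c("Europe", "Asia", "North America", "South America",
                 "Oceania", "Africa")

make_partition <- function(config) {
  n <- config$n_countries
  tiles_r <- max(1L, floor(sqrt(n)))
  tiles_c <- ceiling(n / tiles_r)
  row_breaks <- round(seq(0, config$n_row, length.out = tiles_r + 1L))
  col_breaks <- round(seq(0, config$n_col, length.out = tiles_c + 1L))
  ids <- matrix(0L, config$n_row, config$n_col)
  cpc <- config$counties_per_country
  sub_r <- max(1L, floor(sqrt(cpc)))
  sub_c <- ceiling(cpc / sub_r)
  county_rows <- list()
  county_id <- n
  for (k in seq_len(n)) {
    tr <- (k - 1L) %/% tiles_c + 1L
    tc <- (k - 1L) %% tiles_c + 1L
    rows <- (row_breaks[tr] + 1L):row_breaks[tr + 1L]
    cols <- (col_breaks[tc] + 1L):col_breaks[tc + 1L]
    srb <- round(seq(0, length(rows), length.out = sub_r + 1L))
    scb <- round(seq(0, length(cols), length.out = sub_c + 1L))
    placed <- 0L
    for (i in seq_len(sub_r)) for (j in seq_len(sub_c)) {
      if (placed >= cpc) break
      rr <- rows[(srb[i] + 1L):srb[i + 1L]]
      cc <- cols[(scb[j] + 1L):scb[j + 1L]]
      if (!length(rr) || !length(cc)) next
      county_id <- county_id + 1L
      placed <- placed + 1L
      ids[rr, cc] <- county_id
      county_rows[[length(county_rows) + 1L]] <- data.frame(
        unit_id = county_id,
        name = sprintf("county_%d_%d", k, placed),
        level = "county",
        region = region_pool[(k - 1L) %% length(region_pool) + 1L],
        group = if (k <= round(config$frac_north * n)) "North" else "South",
        parent_unit_id = k
      )
    }
  }
  countries <- data.frame(
    unit_id = seq_len(n),
    name = sprintf("country_%d", seq_len(n)),
    level = "country",
    region = region_pool[(seq_len(n) - 1L) %% length(region_pool) + 1L],
    group = ifelse(seq_len(n) <= round(config$frac_north * n),
                   "North", "South"),
    parent_unit_id = NA_integer_
  )
  admin_partition(ids, rbind(countries, do.call(rbind, county_rows)))
}

make_population <- function(config, partition) {
  set.seed(child_seed(config, "pop"))
  country_ids <- partition_ids(partition, "country")
  base <- matrix(0, config$n_row, config$n_col)
  rows <- row(base); cols <- col(base)
  for (k in seq_len(config$n_countries)) {
    in_k <- which(country_ids == k)
    if (!length(in_k)) next
    centres <- sample(in_k, min(config$clusters_per_country,
                                length(in_k)))
    for (ct in centres) {
      d2 <- (rows - rows[ct])^2 + (cols - cols[ct])^2
      base <- base + exp(-d2 / (2 * config$cluster_spread^2))
    }
  }
  base <- base / max(base)
  logpop <- config$pop_mu + config$pop_gain * base +
    config$pop_sigma * matrix(stats::rnorm(length(base)),
                              nrow(base), ncol(base))
  grid_layer(exp(logpop), cell_size = config$cell_size)
}

make_type_layer <- function(config, type, pop, partition) {
  set.seed(child_seed(config, type))
  conc <- country_concentrations(config)
  country_ids <- partition_ids(partition, "country")
  rel <- pop$values / mean(pop$values)
  kappa <- matrix(0, config$n_row, config$n_col)
  inside <- country_ids != 0L
  kappa[inside] <- conc[country_ids[inside]]
  mu <- config$abundance[[type]] * rel ^ kappa
  counts <- matrix(
    stats::rnbinom(length(mu), size = config$count_size, mu = mu),
    nrow(mu), ncol(mu))
  grid_layer(counts * 1.0, cell_size = config$cell_size)
}

make_env_field <- function(config, which) {
  set.seed(child_seed(config, which))
  z <- matrix(stats::rnorm(config$n_row * config$n_col),
              config$n_row, config$n_col)
  grid_layer(to_unit(smooth_field(z, config$env_corr_len)),
             cell_size = config$cell_size)
}

make_ntl <- function(config, econ_initial) {
  set.seed(child_seed(config, "ntl"))
  v <- econ_initial$values
  noise <- matrix(stats::rnorm(length(v), sd = config$ntl_noise_sd),
                  nrow(v), ncol(v))
  out <- ifelse(v > 0, exp(config$ntl_b + config$ntl_a * log(v) + noise),
                0)
  out[!econ_initial$mask] <- NA_real_
  grid_layer(out, mask = econ_initial$mask,
             cell_size = config$cell_size)
}

#' Generate a complete synthetic study world
#'
#' Produces gridded layers (population, the seven per-type infrastructure
#' counts, green/air/heat ambient fields, night-time lights), a two-level
#' administrative partition, and a country covariate table whose health
#' outcome is drawn from the configured linear predictor with group
#' random intercepts — all deterministic given the configured seed.
#'
#' The country covariates (`ExpEco`, `ExpSoc`, `GiniEco`, `GiniSoc`) are
#' computed from the generated grids with the package's own access and
#' inequality operations, using the *true* night-time-lights law for
#' calibration, so pipeline estimates can be compared against them.
#'
#' @param config A [world_config()].
#' @return List with `layers` (named list of [grid_layer]s: the seven
#'   types plus `population`, `green`, `air`, `heat`, `ntl`),
#'   `urban_mask` (logical matrix, the densely populated region used to
#'   restrict calibration fits), `partition`, `covariates` (country
#'   table), and `truth` ([ground_truth()] plus the realized group
#'   intercepts `gamma`).
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  partition <- make_partition(config)
  pop <- make_population(config, partition)
  types <- names(config$abundance)
  type_layers <- lapply(types, make_type_layer, config = config,
                        pop = pop, partition = partition)
  names(type_layers) <- types
  green <- make_env_field(config, "green")
  air <- make_env_field(config, "air")
  heat <- make_env_field(config, "heat")

  econ_init <- aggregate_category(
    lapply(type_layers[c("telecom", "energy", "transport")],
           normalize_type_layer))
  soc_init <- aggregate_category(
    lapply(type_layers[c("health", "education")], normalize_type_layer))
  ci_env <- aggregate_category(
    lapply(type_layers[c("water", "waste")], normalize_type_layer))
  ntl <- make_ntl(config, econ_init)
  urban_mask <- pop$values > stats::quantile(valid_values(pop), 0.6)

  truth <- ground_truth(config)
  true_fit <- list(slope = config$ntl_a, intercept = config$ntl_b)
  econ <- apply_calibration(econ_init, true_fit)
  soc <- apply_calibration(soc_init, true_fit)
  env <- environmental_composite(ci_env, green, air, heat)
  layers3 <- list(economic = econ, social = soc, environmental = env)

  access <- suppressWarnings(
    build_access_table(pop, layers3, partition, "country"))
  ineq <- build_inequality_table(pop, layers3, partition, "country")

  countries <- partition_units(partition, "country")
  wide <- function(tbl, col, cat) {
    s <- tbl[tbl$category == cat, c("unit_id", col)]
    names(s)[2L] <- paste0(col, "_", cat); s
  }
  cov <- countries[, c("unit_id", "name", "region", "group")]
  cov <- merge(cov, wide(access, "ie_norm", "economic"), by = "unit_id")
  cov <- merge(cov, wide(access, "ie_norm", "social"), by = "unit_id")
  cov <- merge(cov, wide(ineq, "gini", "economic"), by = "unit_id")
  cov <- merge(cov, wide(ineq, "gini", "social"), by = "unit_id")
  names(cov)[match(c("ie_norm_economic", "ie_norm_social",
                     "gini_economic", "gini_social"), names(cov))] <-
    c("ExpEco", "ExpSoc", "GiniEco", "GiniSoc")

  ids <- partition_ids(partition, "country")
  use <- pop$mask & ids != 0L
  totpop <- tapply(pop$values[use], ids[use], sum)
  cov$LnPop <- log(as.numeric(totpop[as.character(cov$unit_id)]))

  set.seed(child_seed(config, "gdp"))
  cov$LnGDP <- 22 + 2 * cov$ExpEco + 0.5 * (cov$LnPop - mean(cov$LnPop)) +
    stats::rnorm(nrow(cov), sd = 0.8)

  set.seed(child_seed(config, "health_outcome"))
  gamma <- stats::rnorm(2L, sd = config$gamma_sd)
  names(gamma) <- c("North", "South")
  b <- config$beta
  lp <- b["const"] + gamma[cov$group] + b["LnPop"] * cov$LnPop +
    b["LnGDP"] * cov$LnGDP + b["ExpEco"] * cov$ExpEco +
    b["ExpSoc"] * cov$ExpSoc + b["GiniEco"] * cov$GiniEco +
    b["GiniSoc"] * cov$GiniSoc
  sd_vec <- rep(config$resid_sd, nrow(cov))
  if (config$heteroscedastic) sd_vec[cov$group == "South"] <-
    3 * config$resid_sd
  cov$HALE <- as.numeric(lp) + stats::rnorm(nrow(cov), sd = sd_vec)
  cov$DALY <- 25000 - 250 * as.numeric(lp) +
    stats::rnorm(nrow(cov), sd = 250 * config$resid_sd)
  truth$gamma <- gamma

  list(
    layers = c(type_layers,
               list(population = pop, green = green, air = air,
                    heat = heat, ntl = ntl)),
    urban_mask = urban_mask,
    partition = partition,
    covariates = cov,
    truth = truth
  )
}

#' Fast country-table generator for health-model recovery studies
#'
#' Draws a country covariate table directly from the health linear
#' predictor — group random intercepts realized per call, covariates
#' independent of group — without building any grids. Intended for
#' repeated parameter-recovery simulation at realistic country counts.
#'
#' @param n Number of countries.
#' @param config A [world_config()] supplying `beta`, `gamma_sd`,
#'   `resid_sd`, `frac_north` and `heteroscedastic`.
#' @param seed Seed for this draw.
#' @return Data frame with `group`, `LnPop`, `LnGDP`, `ExpEco`, `ExpSoc`,
#'   `GiniEco`, `GiniSoc`, `HALE`; realized intercepts in
#'   `attr(, "gamma")`.
#' @export
generate_health_data <- function(n = 160L, config = world_config(),
                                 seed = config$seed) {
  stopifnot(inherits(config, "world_config"), n >= 10L)
  set.seed(seed)
  n_north <- max(2L, round(config$frac_north * n))
  group <- c(rep("North", n_north), rep("South", n - n_north))
  df <- data.frame(
    group = group,
    LnPop = stats::rnorm(n, 16, 1.5),
    LnGDP = stats::rnorm(n, 24, 1.5),
    ExpEco = stats::rbeta(n, 2, 3),
    ExpSoc = stats::rbeta(n, 2, 4),
    GiniEco = stats::rbeta(n, 6, 5),
    GiniSoc = stats::rbeta(n, 10, 2.5)
  )
  gamma <- stats::rnorm(2L, sd = config$gamma_sd)
  names(gamma) <- c("North", "South")
  b <- config$beta
  lp <- b["const"] + gamma[df$group] + b["LnPop"] * df$LnPop +
    b["LnGDP"] * df$LnGDP + b["ExpEco"] * df$ExpEco +
    b["ExpSoc"] * df$ExpSoc + b["GiniEco"] * df$GiniEco +
    b["GiniSoc"] * df$GiniSoc
  sd_vec <- rep(config$resid_sd, n)
  if (config$heteroscedastic) sd_vec[df$group == "South"] <-
    3 * config$resid_sd
  df$HALE <- as.numeric(lp) + stats::rnorm(n, sd = sd_vec)
  attr(df, "gamma") <- gamma
  df
}
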