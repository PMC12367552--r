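#' Infrastructure type catalogue
#'
#' Maps the seven infrastructure systems to the three analysis categories.
#' The default assignment places telecommunication, energy and transport
#' under economic infrastructure; health and education under social; water
#' and waste under environmental. The sensitivity variant folds the water
#' and waste systems into the socio-economic categories (water with
#' economic, waste with social), leaving the environmental composite to the
#' ambient components (green space, air quality, heat).
#'
#' @param sensitivity_remap If `TRUE`, return the sensitivity assignment.
#' @return Named character vector: infrastructure type -> category.
#' @examples
#' default_type_catalog()
#' @export
default_type_catalog <- function(sensitivity_remap = FALSE) {
  if (sensitivity_remap) {
    c(telecom = "economic", energy = "economic", transport = "economic",
      water = "economic",
      health = "social", education = "social", waste = "social")
  } else {
    c(telecom = "economic", energy = "economic", transport = "economic",
      health = "social", education = "social",
      water = "environmental", waste = "environmental")
  }
}

infra_categories <- c("economic", "social", "environmental")

#' Normalize an infrastructure count layer to [0, 1]
#'
#' Divides by the maximum valid cell value so that cross-type comparison is
#' possible despite very different absolute abundances (power poles vs
#' hospitals). The maximum is taken over valid cells only.
#'
#' @param layer A [grid_layer] with non-negative values.
#' @return A `grid_layer` in `[0, 1]` whose maximum valid cell equals 1.
#' @export
normalize_type_layer <- function(layer) {
  stopifnot(is_grid_layer(layer))
  v <- valid_values(layer)
  if (length(v) == 0L) stop("layer is fully masked", call. = FALSE)
  if (any(v < 0)) stop("layer values must be non-negative", call. = FALSE)
  mx <- max(v)
  if (mx == 0) stop("all-zero layer cannot be normalized", call. = FALSE)
  grid_layer(layer$values / mx, mask = layer$mask,
             cell_size = layer$cell_size, origin = layer$origin)
}

#' Equal-weight aggregation of normalized layers
#'
#' Cell-wise arithmetic mean over the layers that are valid at each cell;
#' a cell is masked only when every contributing layer is masked there.
#'
#' @param layers Non-empty list of aligned [grid_layer] objects.
#' @return A `grid_layer` of cell-wise means.
#' @export
aggregate_category <- function(layers) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("`layers` must be a non-empty list", call. = FALSE)
  ref <- assert_aligned(.list = layers)
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  cnt <- matrix(0L, nrow(ref$values), ncol(ref$values))
  for (l in layers) {
    v <- l$values
    v[!l$mask] <- 0
    acc <- acc + v
    cnt <- cnt + l$mask
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  grid_layer(out, cell_size = ref$cell_size, origin = ref$origin)
}

#' Environmental infrastructure composite
#'
#' Combines the facility-based environmental layer with ambient living
#' conditions:
#' \deqn{Env = 0.5\,CI_{env} + 0.5\, e^{Green} / (Air + Heat)}
#' where the denominator is the exact value of \eqn{\ln(e^{Air} e^{Heat})}.
#' `Green` is green-space fraction, `Air` normalized PM2.5 and `Heat`
#' normalized heat duration, all in `[0, 1]`. Higher green space raises the
#' composite; higher pollution or heat lowers it. The denominator is
#' floored at `epsilon` because normalized layers can be exactly zero.
#' The output is deliberately not rescaled here; scale is absorbed by the
#' 95th-percentile normalization applied to access values downstream.
#'
#' @param ci_env [grid_layer] of facility-based environmental
#'   infrastructure in `[0, 1]` (mean of normalized water and waste
#'   layers), or `NULL` to use only the ambient term.
#' @param green,air,heat Aligned [grid_layer]s in `[0, 1]`.
#' @param epsilon Floor on the denominator (default `1e-6`).
#' @return A `grid_layer`, masked where any input is masked.
#' @export
environmental_composite <- function(ci_env, green, air, heat,
                                    epsilon = 1e-6) {
  assert_aligned(green, air, heat, .list = if (is.null(ci_env)) NULL
                 else list(ci_env))
  for (nm in c("green", "air", "heat")) {
    l <- get(nm)
    v <- valid_values(l)
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("`", nm, "` must be valued in [0, 1]", call. = FALSE)
  }
  denom <- pmax(air$values + heat$values, epsilon)
  ambient <- exp(green$values) / denom
  if (is.null(ci_env)) {
    out <- ambient
    m <- green$mask & air$mask & heat$mask
  } else {
    out <- 0.5 * ci_env$values + 0.5 * ambient
    m <- ci_env$mask & green$mask & air$mask & heat$mask
  }
  out[!m] <- NA_real_
  grid_layer(out, mask = m, cell_size = green$cell_size,
             origin = green$origin)
}

#' Fit the night-time-lights calibration model
#'
#' Ordinary least squares of `ln(ntl)` on `ln(infra)` over cells selected
#' by `mask` (typically an urban-plus-buffer mask); cells where either
#' value is non-positive are dropped since the logarithm is undefined.
#' Night-time lights act as a socio-economic surrogate: a strong log-log
#' relationship lets the raw, possibly incomplete infrastructure counts be
#' rescaled onto a radiance-consistent scale.
#'
#' @param infra Normalized infrastructure [grid_layer] (values in `[0,1]`).
#' @param ntl Night-time-lights [grid_layer], aligned with `infra`.
#' @param mask Optional logical matrix restricting the fit region.
#' @return A `calibration_fit`: list with `slope` (a), `intercept` (b),
#'   `r` (Pearson correlation of the log pairs) and `n`.
#' @export
fit_calibration <- function(infra, ntl, mask = NULL) {
  assert_aligned(infra, ntl)
  sel <- infra$mask & ntl$mask &
    !is.na(infra$values) & !is.na(ntl$values) &
    infra$values > 0 & ntl$values > 0
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(infra$values)))
      stop("`mask` shape must match the layers", call. = FALSE)
    sel <- sel & mask
  }
  x <- log(infra$values[sel])
  y <- log(ntl$values[sel])
  n <- length(x)
  if (n < 3L) stop("fewer than 3 usable cells for calibration",
                   call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in ln(infrastructure)",
                               call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(
    list(slope = unname(fit$coefficients[2L]),
         intercept = unname(fit$coefficients[1L]),
         r = stats::cor(x, y), n = n),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> ln(I) = %.4f ln(I') + %.4f  (r = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' Apply a fitted calibration to a normalized layer
#'
#' Back-transforms the log-log fit: `I = exp(b) * I'^a` for `I' > 0`, with
#' `I = 0` kept at zero-infrastructure cells (continuity convention; the
#' power law itself is undefined at 0). For positive slope the mapping is
#' strictly increasing, so cell rankings are preserved.
#'
#' @param infra_prime Normalized [grid_layer] in `[0, 1]`.
#' @param fit A `calibration_fit` (or list with `slope` and `intercept`).
#' @return Calibrated `grid_layer`.
#' @export
apply_calibration <- function(infra_prime, fit) {
  stopifnot(is_grid_layer(infra_prime))
  if (is.null(fit$slope) || is.null(fit$intercept))
    stop("`fit` must carry slope and intercept", call. = FALSE)
  v <- infra_prime$values
  out <- ifelse(v > 0, exp(fit$intercept) * v ^ fit$slope, 0)
  out[!infra_prime$mask] <- NA_real_
  grid_layer(out, mask = infra_prime$mask,
             cell_size = infra_prime$cell_size,
             origin = infra_prime$origin)
}

#' Build the three category layers from per-type count layers
#'
#' Runs the mapping stage end to end: per-type max normalization,
#' equal-weight aggregation into initial category layers, the environmental
#' composite, and (optionally) night-time-lights calibration of the
#' economic and social layers with one shared coefficient pair.
#'
#' @param type_layers Named list of per-type count [grid_layer]s; names
#'   must be a subset of the catalogue's types.
#' @param green,air,heat Ambient [grid_layer]s in `[0, 1]`.
#' @param catalog Type -> category map, see [default_type_catalog()].
#' @param ntl Optional night-time-lights layer enabling calibration.
#' @param calibration_mask Optional logical matrix (urban-plus-buffer
#'   region) restricting the calibration fit.
#' @param per_category_fit If `TRUE`, fit separate coefficients for the
#'   economic and social layers; default is one shared fit on the economic
#'   layer applied to both.
#' @param epsilon Denominator floor of [environmental_composite()].
#' @return List with elements `economic`, `social`, `environmental`
#'   (grid_layers) and `calibration` (a `calibration_fit` or `NULL`).
#' @export
build_infrastructure_layers <- function(type_layers, green, air, heat,
                                        catalog = default_type_catalog(),
                                        ntl = NULL,
                                        calibration_mask = NULL,
                                        per_category_fit = FALSE,
                                        epsilon = 1e-6) {
  if (is.null(names(type_layers)) || any(names(type_layers) == ""))
    stop("`type_layers` must be a named list", call. = FALSE)
  unknown <- setdiff(names(type_layers), names(catalog))
  if (length(unknown))
    stop("types absent from catalogue: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  norm <- lapply(type_layers, normalize_type_layer)
  by_cat <- split(norm, catalog[names(norm)])

  initial <- list()
  for (cat in c("economic", "social")) {
    if (is.null(by_cat[[cat]]))
      stop("no layers mapped to category '", cat, "'", call. = FALSE)
    initial[[cat]] <- aggregate_category(by_cat[[cat]])
  }
  ci_env <- if (!is.null(by_cat[["environmental"]]))
    aggregate_category(by_cat[["environmental"]]) else NULL
  env <- environmental_composite(ci_env, green, air, heat,
                                 epsilon = epsilon)

  fit <- NULL
  if (!is.null(ntl)) {
    fit <- fit_calibration(initial$economic, ntl, mask = calibration_mask)
    if (per_category_fit) {
      fit_soc <- fit_calibration(initial$social, ntl,
                                 mask = calibration_mask)
      initial$social <- apply_calibration(initial$social, fit_soc)
    } else {
      initial$social <- apply_calibration(initial$social, fit)
    }
    initial$economic <- apply_calibration(initial$economic, fit)
  }
  list(economic = initial$economic, social = initial$social,
       environmental = env, calibration = fit)
}
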