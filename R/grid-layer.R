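#' Gridded layer on a regular latitude/longitude grid
#'
#' A `grid_layer` is the unit of all mapping computation in infraccess: a
#' real-valued 2-D field on a regular lat/lon grid (nominally 0.1 degree)
#' together with a validity mask. Row 1 is the northern edge; latitude
#' decreases with the row index. Masked-out cells are excluded from every
#' reduction (maxima, percentiles, sums) performed by the package.
#'
#' @param values Numeric matrix of cell values. `NA` entries are masked out.
#' @param mask Optional logical matrix, `TRUE` for valid cells. Defaults to
#'   `!is.na(values)`. Cells masked `FALSE` have their value set to `NA`.
#' @param cell_size Cell edge length in degrees (default 0.1).
#' @param origin Numeric `(lat, lon)` of the grid's upper-left corner.
#'
#' @return An object of class `grid_layer` with fields `values`, `mask`,
#'   `cell_size` and `origin`.
#' @examples
#' gl <- grid_layer(matrix(1:12, 3, 4))
#' n_valid(gl)
#' @export
grid_layer <- function(values, mask = NULL, cell_size = 0.1,
                       origin = c(90, -180)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  if (!identical(dim(values), dim(mask)))
    stop("`values` and `mask` must have identical shape", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  if (length(origin) != 2L || anyNA(origin))
    stop("`origin` must be numeric (lat, lon)", call. = FALSE)
  mask[is.na(values)] <- FALSE
  values[!mask] <- NA_real_
  structure(
    list(values = values, mask = mask, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("<grid_layer> %d x %d cells @ %g deg, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  cat(sprintf("  valid cells: %d / %d", sum(x$mask), length(x$mask)))
  if (any(x$mask)) {
    rng <- range(x$values[x$mask])
    cat(sprintf("; range [%g, %g]", rng[1], rng[2]))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.grid_layer <- function(x) dim(x$values)

#' @rdname grid_layer
#' @param x A `grid_layer`.
#' @export
is_grid_layer <- function(x) inherits(x, "grid_layer")

#' @rdname grid_layer
#' @export
n_valid <- function(x) {
  stopifnot(is_grid_layer(x))
  sum(x$mask)
}

#' Valid cell values of a layer
#'
#' @param x A `grid_layer`.
#' @return Numeric vector of values at valid cells, in column-major order.
#' @export
valid_values <- function(x) {
  stopifnot(is_grid_layer(x))
  x$values[x$mask]
}

# Stop unless all layers share shape, cell size and origin.
assert_aligned <- function(..., .list = NULL) {
  layers <- c(list(...), .list)
  layers <- Filter(Negate(is.null), layers)
  stopifnot(length(layers) >= 1L)
  ref <- layers[[1L]]
  for (l in layers) {
    if (!is_grid_layer(l)) stop("all inputs must be grid_layer objects",
                                call. = FALSE)
    if (!identical(dim(l$values), dim(ref$values)))
      stop("shape mismatch between layers: ",
           paste(dim(ref$values), collapse = "x"), " vs ",
           paste(dim(l$values), collapse = "x"), call. = FALSE)
    if (abs(l$cell_size - ref$cell_size) > 1e-9)
      stop("cell-size mismatch between layers", call. = FALSE)
    if (max(abs(l$origin - ref$origin)) > 1e-9)
      stop("origin mismatch between layers", call. = FALSE)
  }
  invisible(ref)
}

#' Read a gridded layer from an ESRI ASCII grid file
#'
#' Rasters are exchanged as ESRI ASCII grids (`.asc`): a plain-text header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of cell values, northernmost row first. Cells equal to
#' the declared nodata value are masked.
#'
#' @param path Path to an `.asc` file.
#' @param band Band index; ASCII grids are single-band so only `1` is valid.
#' @return A [grid_layer].
#' @seealso [write_layer()]
#' @export
read_layer <- function(path, band = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!identical(as.integer(band), 1L))
    stop("ASCII grids are single-band; band must be 1", call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L)
      stop("malformed header line in ", path, ": ", ln, call. = FALSE)
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  req <- c("ncols", "nrows", "cellsize", "nodata_value")
  if (!all(req %in% names(hdr)) || anyNA(unlist(hdr[req])))
    stop("unreadable or incomplete ASCII grid header in ", path,
         call. = FALSE)
  has_corner <- all(c("xllcorner", "yllcorner") %in% names(hdr))
  if (!has_corner)
    stop("ASCII grid header must declare xllcorner/yllcorner", call. = FALSE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(path, what = numeric(), skip = 6L, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("non-rectilinear grid: expected ", nr * nc, " values, found ",
         length(vals), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  origin <- c(hdr$yllcorner + nr * hdr$cellsize, hdr$xllcorner)
  grid_layer(m, cell_size = hdr$cellsize, origin = origin)
}

#' Write a gridded layer to an ESRI ASCII grid file
#'
#' @param layer A [grid_layer].
#' @param path Output path.
#' @param nodata Value written for masked cells (default -9999).
#' @param digits Significant digits used when formatting values (default 17,
#'   enough for exact double round-trip).
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path, nodata = -9999, digits = 17L) {
  stopifnot(is_grid_layer(layer))
  v <- layer$values
  if (any(v[layer$mask] == nodata, na.rm = TRUE))
    stop("a valid cell equals the nodata value; choose another nodata",
         call. = FALSE)
  v[!layer$mask] <- nodata
  nr <- nrow(v); nc <- ncol(v)
  xll <- layer$origin[2]
  yll <- layer$origin[1] - nr * layer$cell_size
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10f", xll),
    sprintf("yllcorner %.10f", yll),
    sprintf("cellsize %.10f", layer$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Align a stack of layers onto the coarsest common grid
#'
#' Layers sharing the same origin are brought to the coarsest cell size by
#' block-mean downsampling: each coarse cell is the mean of its valid fine
#' children. Cell sizes must be identical or integer multiples of the
#' coarsest. A coarse cell is masked only when all of its children are
#' masked.
#'
#' @param layers List of [grid_layer] objects with a common origin.
#' @return List of aligned `grid_layer` objects on the coarsest grid.
#' @examples
#' fine <- grid_layer(matrix(1, 4, 4), cell_size = 0.05)
#' coarse <- grid_layer(matrix(0, 2, 2), cell_size = 0.1)
#' out <- align_stack(list(fine, coarse))
#' dim(out[[1]])
#' @export
align_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  for (l in layers)
    if (!is_grid_layer(l)) stop("all inputs must be grid_layer objects",
                                call. = FALSE)
  ref <- layers[[1L]]
  for (l in layers)
    if (max(abs(l$origin - ref$origin)) > 1e-9)
      stop("disjoint extents: layers must share an origin", call. = FALSE)
  target <- max(vapply(layers, function(l) l$cell_size, numeric(1)))
  lapply(layers, function(l) {
    ratio <- target / l$cell_size
    if (abs(ratio - round(ratio)) > 1e-9)
      stop("non-integer resolution ratio: ", l$cell_size, " vs ", target,
           call. = FALSE)
    ratio <- as.integer(round(ratio))
    if (ratio == 1L) return(l)
    block_mean(l, ratio, target)
  })
}

# Block-mean downsample by an integer factor; mean over valid children only.
block_mean <- function(layer, factor, target_cell) {
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  if (nr %% factor != 0L || nc %% factor != 0L)
    stop("layer shape ", nr, "x", nc, " not divisible by factor ", factor,
         call. = FALSE)
  v <- layer$values
  v[!layer$mask] <- 0
  w <- layer$mask * 1
  ri <- (seq_len(nr) - 1L) %/% factor + 1L
  ci <- (seq_len(nc) - 1L) %/% factor + 1L
  sum_block <- function(m) {
    t(rowsum(t(rowsum(m, ri)), ci))
  }
  sums <- sum_block(v)
  cnts <- sum_block(w)
  out <- sums / cnts           # NaN where no valid children
  out[cnts == 0] <- NA_real_
  grid_layer(out, cell_size = target_cell, origin = layer$origin)
}
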