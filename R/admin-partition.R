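#' Administrative partition of the grid
#'
#' An `admin_partition` couples an integer unit-ID field, aligned cell-for-
#' cell to the study grid, with a unit metadata table. The ID field holds
#' the finest (county) unit IDs; country membership is derived through each
#' county's `parent_unit_id`. ID 0 marks cells outside every unit.
#'
#' @param unit_ids Integer matrix of county-level unit IDs (0 = no unit).
#' @param units Data frame with columns `unit_id`, `name`,
#'   `level` (`"country"` or `"county"`), `region`, `group`
#'   (`"North"` or `"South"`), `parent_unit_id` (`NA` for countries).
#'
#' @return An object of class `admin_partition`.
#' @export
admin_partition <- function(unit_ids, units) {
  if (!is.matrix(unit_ids)) stop("`unit_ids` must be a matrix", call. = FALSE)
  storage.mode(unit_ids) <- "integer"
  req <- c("unit_id", "name", "level", "region", "group", "parent_unit_id")
  if (!is.data.frame(units) || !all(req %in% names(units)))
    stop("`units` must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  units <- as.data.frame(units)[, req]
  if (anyDuplicated(units$unit_id))
    stop("duplicate unit_id in metadata table", call. = FALSE)
  if (!all(units$level %in% c("country", "county")))
    stop("level must be 'country' or 'county'", call. = FALSE)
  ids_in_field <- setdiff(unique(as.vector(unit_ids)), 0L)
  ids_in_field <- ids_in_field[!is.na(ids_in_field)]
  missing <- setdiff(ids_in_field, units$unit_id)
  if (length(missing))
    stop("unit IDs present in field but absent from table: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  counties <- units[units$level == "county", ]
  if (nrow(counties)) {
    parents <- counties$parent_unit_id
    country_ids <- units$unit_id[units$level == "country"]
    if (anyNA(parents) || !all(parents %in% country_ids))
      stop("every county must reference a valid parent country",
           call. = FALSE)
  }
  structure(list(unit_ids = unit_ids, units = units),
            class = "admin_partition")
}

#' @export
print.admin_partition <- function(x, ...) {
  cat(sprintf("<admin_partition> %d x %d cells; %d countries, %d counties\n",
              nrow(x$unit_ids), ncol(x$unit_ids),
              sum(x$units$level == "country"),
              sum(x$units$level == "county")))
  invisible(x)
}

#' @rdname admin_partition
#' @param x Object to test.
#' @export
is_admin_partition <- function(x) inherits(x, "admin_partition")

#' Unit-ID field at a given administrative level
#'
#' At `"county"` level this is the stored ID field; at `"country"` level
#' county IDs are replaced by their parent-country IDs.
#'
#' @param partition An [admin_partition].
#' @param level `"country"` or `"county"`.
#' @return Integer matrix of unit IDs at the requested level.
#' @export
partition_ids <- function(partition, level = c("country", "county")) {
  stopifnot(is_admin_partition(partition))
  level <- match.arg(level)
  ids <- partition$unit_ids
  if (level == "county") return(ids)
  units <- partition$units
  map <- units$parent_unit_id
  names(map) <- as.character(units$unit_id)
  # countries map to themselves
  map[units$level == "country"] <- units$unit_id[units$level == "country"]
  out <- ids
  nz <- ids != 0L & !is.na(ids)
  out[nz] <- as.integer(map[as.character(ids[nz])])
  out
}

#' Metadata rows for one administrative level
#'
#' @inheritParams partition_ids
#' @return Data frame of units at that level.
#' @export
partition_units <- function(partition, level = c("country", "county")) {
  stopifnot(is_admin_partition(partition))
  level <- match.arg(level)
  partition$units[partition$units$level == level, , drop = FALSE]
}

#' Read / write an administrative partition
#'
#' The ID field travels as an ESRI ASCII grid (see [read_layer()]) with
#' nodata for out-of-unit cells; unit metadata travels as a CSV with header
#' `unit_id,name,level,region,group,parent_unit_id`.
#'
#' @param ids_path Path to the unit-ID `.asc` raster.
#' @param units_path Path to the unit metadata CSV.
#' @return An [admin_partition].
#' @export
read_partition <- function(ids_path, units_path) {
  lay <- read_layer(ids_path)
  ids <- lay$values
  ids[!lay$mask] <- 0
  storage.mode(ids) <- "integer"
  units <- utils::read.csv(units_path, stringsAsFactors = FALSE)
  admin_partition(ids, units)
}

#' @rdname read_partition
#' @param partition An [admin_partition].
#' @export
write_partition <- function(partition, ids_path, units_path) {
  stopifnot(is_admin_partition(partition))
  ids <- partition$unit_ids
  v <- ids * 1.0
  v[ids == 0L] <- NA_real_
  write_layer(grid_layer(v), ids_path, nodata = -1)
  utils::write.csv(partition$units, units_path, row.names = FALSE)
  invisible(list(ids = ids_path, units = units_path))
}
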