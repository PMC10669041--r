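#' Trait schema for a single wetland variable
#'
#' A schema entry describes one column of a wetland-trait table: its
#' measurement kind, unit, closed allowed range and (for semi-quantitative
#' variables) the meaning of each ordinal level.
#'
#' @param name Variable name (column header).
#' @param kind One of `"continuous"`, `"ordinal"` or `"count"`. Ordinal and
#'   count variables must take integer values inside `allowed_range`.
#' @param unit Unit of measure (free text; `"dimensionless"` for scores).
#' @param allowed_range Numeric length-2 vector `c(lower, upper)`,
#'   `lower <= upper`.
#' @param level_labels Optional named character vector mapping ordinal levels
#'   to their meaning, e.g. `c("0" = "absent", "3" = "widespread")`.
#'
#' @return An object of class `trait_schema`.
#' @export
#' @examples
#' trait_schema("water salinity", "ordinal", "dimensionless", c(0, 3),
#'              c("0" = "absent", "1" = "localized",
#'                "2" = "scattered", "3" = "widespread"))
trait_schema <- function(name, kind = c("continuous", "ordinal", "count"),
                         unit = "dimensionless", allowed_range,
                         level_labels = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  allowed_range <- as.numeric(allowed_range)
  if (length(allowed_range) != 2L || anyNA(allowed_range)) {
    stop("`allowed_range` must be two finite numbers", call. = FALSE)
  }
  if (allowed_range[1] > allowed_range[2]) {
    stop("`allowed_range` lower bound exceeds upper bound for '", name, "'",
         call. = FALSE)
  }
  if (kind %in% c("ordinal", "count") &&
      any(allowed_range != round(allowed_range))) {
    stop("ordinal/count variable '", name,
         "' needs integer range endpoints", call. = FALSE)
  }
  structure(
    list(name = name, kind = kind, unit = unit,
         allowed_range = allowed_range, level_labels = level_labels),
    class = "trait_schema"
  )
}

#' @export
print.trait_schema <- function(x, ...) {
  cat(sprintf("<trait_schema> %s [%s, %s] (%s, %s)\n", x$name,
              format(x$allowed_range[1]), format(x$allowed_range[2]),
              x$kind, x$unit))
  invisible(x)
}

#' Default wetland-trait schema
#'
#' The ten-variable schema used throughout: three spatial traits (wetland
#' size, isolation, distance to the coastline), six anthropic/hydrological
#' traits scored on ordinal scales, and the target variable (number of bird
#' species per wetland).
#'
#' @return A named list of [trait_schema()] objects, in canonical column
#'   order; the last entry is the target variable.
#' @export
#' @examples
#' sch <- default_schema()
#' sch[["Water discharges"]]$allowed_range  # 0 2
default_schema <- function() {
  wsl <- c("0" = "absent", "1" = "localized", "2" = "scattered",
           "3" = "widespread")
  sc2 <- wsl[1:3]
  entries <- list(
    trait_schema("Wetland size", "continuous", "hectares", c(13.3, 2048)),
    trait_schema("Isolation", "continuous", "meters", c(296, 54472)),
    trait_schema("Distance to the coastline", "continuous", "meters",
                 c(0, 2050)),
    trait_schema("Mean water level", "ordinal", "dimensionless", c(1, 11),
                 c("1" = "0-10 cm", "2" = "10-20 cm", "3" = "20-30 cm")),
    trait_schema("Water salinity", "ordinal", "dimensionless", c(0, 3), wsl),
    trait_schema("Water diversions", "ordinal", "dimensionless", c(0, 3), wsl),
    trait_schema("Water discharges", "ordinal", "dimensionless", c(0, 2), sc2),
    trait_schema("Tourism pressure", "ordinal", "dimensionless", c(0, 3), wsl),
    trait_schema("Anthropization", "ordinal", "dimensionless", c(0, 2), sc2),
    trait_schema("Number of species", "count", "dimensionless", c(2, 32))
  )
  stats::setNames(entries, vapply(entries, `[[`, "", "name"))
}

#' Name of the target (species richness) column in the default schema
#' @return A character scalar.
#' @export
target_node <- function() "Number of species"

#' Construct a validated wetland-trait table
#'
#' @param values A data frame of trait columns (one column per schema entry).
#' @param schema A list of [trait_schema()] objects; defaults to
#'   [default_schema()].
#' @param wetland_id Character vector of unique row identifiers; defaults to
#'   `w01, w02, ...`.
#'
#' @return An object of class `wetland_table`: the validated data frame with
#'   attributes `schema` and `wetland_id`.
#' @export
wetland_table <- function(values, schema = default_schema(),
                          wetland_id = NULL) {
  values <- as.data.frame(values, check.names = FALSE)
  nms <- vapply(schema, `[[`, "", "name")

  # header match is case-insensitive; canonical names are restored
  idx <- match(tolower(nms), tolower(names(values)))
  if (anyNA(idx)) {
    stop("schema error: missing column(s): ",
         paste(nms[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  values <- values[idx]
  names(values) <- nms

  n <- nrow(values)
  if (n == 0L) stop("schema error: table has no rows", call. = FALSE)
  if (is.null(wetland_id)) wetland_id <- sprintf("w%02d", seq_len(n))
  wetland_id <- as.character(wetland_id)
  if (anyDuplicated(wetland_id)) {
    stop("duplicate wetland_id: ",
         paste(unique(wetland_id[duplicated(wetland_id)]), collapse = ", "),
         call. = FALSE)
  }

  for (s in schema) {
    col <- values[[s$name]]
    if (!is.numeric(col)) {
      col <- suppressWarnings(as.numeric(col))
      values[[s$name]] <- col
    }
    if (anyNA(col)) {
      bad <- wetland_id[is.na(col)]
      stop("validation error: missing value for trait '", s$name,
           "' in wetland ", paste(bad, collapse = ", "), call. = FALSE)
    }
    out <- col < s$allowed_range[1] | col > s$allowed_range[2]
    if (s$kind %in% c("ordinal", "count")) out <- out | col != round(col)
    if (any(out)) {
      i <- which(out)[1]
      stop(sprintf(
        "validation error: wetland '%s', trait '%s', value %s outside [%s, %s]%s",
        wetland_id[i], s$name, format(col[i]),
        format(s$allowed_range[1]), format(s$allowed_range[2]),
        if (s$kind != "continuous") " (integer levels only)" else ""),
        call. = FALSE)
    }
  }

  structure(values, schema = schema, wetland_id = wetland_id,
            class = c("wetland_table", "data.frame"))
}

#' @export
print.wetland_table <- function(x, ...) {
  cat(sprintf("<wetland_table> %d wetlands x %d variables\n", nrow(x),
              ncol(x)))
  print.data.frame(utils::head(cbind(wetland_id = attr(x, "wetland_id"),
                                     as.data.frame(x)), 6L), ...)
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

#' Load a wetland-trait table from delimited text
#'
#' Reads a comma-separated file (dot decimal, UTF-8, one header row) whose
#' columns match the schema names (case-insensitively). An optional
#' `wetland_id` column provides row identifiers. Every cell is validated
#' against the schema range; the first offending cell aborts the load with a
#' message naming the wetland, the trait and the value.
#'
#' @param path Path to a CSV file.
#' @param schema A list of [trait_schema()]; defaults to [default_schema()].
#'   Pass a modified schema to accept alternative encodings (e.g. water level
#'   measured in centimetres instead of the 1-11 ordinal class).
#' @return A [wetland_table()].
#' @export
load_trait_table <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("schema error: cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(raw) == 0L || ncol(raw) == 0L) {
    stop("schema error: empty table in '", path, "'", call. = FALSE)
  }
  id_col <- which(tolower(names(raw)) == "wetland_id")
  wid <- if (length(id_col)) as.character(raw[[id_col[1]]]) else NULL
  if (length(id_col)) raw <- raw[-id_col]
  wetland_table(raw, schema = schema, wetland_id = wid)
}

#' Write a wetland-trait table as normalized CSV
#'
#' @param table A [wetland_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  stopifnot(inherits(table, "wetland_table"))
  out <- cbind(wetland_id = attr(table, "wetland_id"), as.data.frame(table))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
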