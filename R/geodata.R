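#' @importFrom stats pnorm runif rnorm setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

FACILITY_COLS <- c("id", "name", "level", "nhis_accredited", "lga", "x", "y")
ENROLLEE_COLS <- c("id", "x", "y", "used_facility_id")
FACILITY_LEVELS <- c("primary", "secondary", "tertiary")

#' Define a study area
#'
#' A study area is the region over which point densities are computed. It is
#' either an explicit polygon (one outer ring, optional hole rings) in planar
#' metres, or a bare area in square metres; the Clark-Evans statistic only
#' needs the scalar area, while grid aggregation additionally uses the
#' polygon (or, absent one, the bounding rectangle of the data).
#'
#' All coordinates throughout the package are planar metres in a projected
#' system (e.g. UTM); nothing here computes on longitude/latitude.
#'
#' @param polygon a two-column matrix of ring vertices (x, y), or a list of
#'   such matrices where the first ring is the outer boundary and subsequent
#'   rings are holes. Optional if \code{area} is given.
#' @param area area in square metres. Optional if \code{polygon} is given
#'   (then computed by the shoelace formula). If both are supplied they must
#'   agree within 0.1\%.
#' @return an object of class \code{study_area} with elements \code{polygon}
#'   (list of rings or \code{NULL}), \code{area} (m^2) and \code{bbox}
#'   (xmin, ymin, xmax, ymax; for a bare area, a square of that area anchored
#'   at the origin).
#' @examples
#' sq <- study_area(polygon = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' sq$area
#' @export
study_area <- function(polygon = NULL, area = NULL) {
  if (is.null(polygon) && is.null(area)) {
    stop("supply a polygon, an area, or both", call. = FALSE)
  }
  rings <- NULL
  if (!is.null(polygon)) {
    rings <- if (is.list(polygon)) lapply(polygon, as.matrix) else list(as.matrix(polygon))
    computed <- polygon_area(rings)
    if (is.null(area)) {
      area <- computed
    } else if (abs(computed - area) > 0.001 * area) {
      stop(sprintf(
        "polygon area %.6g m^2 disagrees with the stated area %.6g m^2 by more than 0.1%%",
        computed, area), call. = FALSE)
    }
  }
  if (!is.finite(area) || area <= 0) stop("area must be a positive number of m^2", call. = FALSE)
  bbox <- if (!is.null(rings)) {
    all_xy <- do.call(rbind, rings)
    c(xmin = min(all_xy[, 1]), ymin = min(all_xy[, 2]),
      xmax = max(all_xy[, 1]), ymax = max(all_xy[, 2]))
  } else {
    side <- sqrt(area)
    c(xmin = 0, ymin = 0, xmax = side, ymax = side)
  }
  structure(list(polygon = rings, area = area, bbox = bbox),
            class = "study_area")
}

#' @export
print.study_area <- function(x, ...) {
  cat("Study area:", format(x$area, big.mark = ","), "m^2;",
      if (is.null(x$polygon)) "no polygon (implicit square extent)"
      else sprintf("%d ring(s)", length(x$polygon)), "\n")
  invisible(x)
}

#' Planar polygon area (shoelace formula)
#'
#' Absolute area of a polygon given as one or more rings of planar vertices.
#' The first ring is the outer boundary; any further rings are holes and
#' their areas are subtracted. Rings may be open (the closing vertex is
#' implied). Orientation does not matter.
#'
#' @param polygon a two-column matrix (single ring) or list of such matrices.
#' @return area in the square of the coordinate unit (m^2 for metres).
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # 1
#' @export
polygon_area <- function(polygon) {
  rings <- if (is.list(polygon)) polygon else list(polygon)
  shoelace <- function(r) {
    r <- as.matrix(r)
    if (nrow(r) > 1 && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(unique(r)) < 3) {
      stop("degenerate polygon ring: fewer than 3 distinct vertices", call. = FALSE)
    }
    x <- r[, 1]; y <- r[, 2]
    j <- c(2:nrow(r), 1L)
    abs(sum(x * y[j] - x[j] * y)) / 2
  }
  areas <- vapply(rings, shoelace, numeric(1))
  if (length(areas) == 1) areas else areas[1] - sum(areas[-1])
}

# Even-odd point-in-polygon test for a list of rings (holes handled by the
# crossing count). Delegates to mgcv's C implementation.
points_in_polygon <- function(x, y, rings) {
  bnd <- do.call(rbind, lapply(rings, function(r) {
    r <- as.matrix(r)
    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
    rbind(r, c(NA, NA))
  }))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  mgcv::in.out(bnd, cbind(x, y))
}

validate_facilities <- function(df) {
  check_columns(df, FACILITY_COLS, "facility")
  df <- df[, FACILITY_COLS]
  df$id <- as.character(df$id)
  df$name <- as.character(df$name)
  df$level <- as.character(df$level)
  df$lga <- as.character(df$lga)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  df$nhis_accredited <- parse_bool(df$nhis_accredited, "nhis_accredited")
  check_unique_ids(df, "facility")
  check_finite_coords(df, "facility")
  bad <- which(!df$level %in% FACILITY_LEVELS)
  if (length(bad) > 0) {
    stop_schema("facility level must be one of %s; invalid at row(s): %s",
                paste(FACILITY_LEVELS, collapse = "/"),
                paste(bad, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

validate_enrollees <- function(df) {
  check_columns(df, ENROLLEE_COLS, "enrollee")
  df <- df[, ENROLLEE_COLS]
  df$id <- as.character(df$id)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  df$used_facility_id <- as.character(df$used_facility_id)
  check_unique_ids(df, "enrollee")
  check_finite_coords(df, "enrollee")
  bad <- which(is.na(df$used_facility_id) | df$used_facility_id == "")
  if (length(bad) > 0) {
    stop_schema("enrollee table has empty used_facility_id at row(s): %s",
                paste(bad, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Read a facility table
#'
#' Reads health-facility records from CSV (columns
#' \code{id,name,level,nhis_accredited,lga,x,y}) or from a GeoJSON
#' FeatureCollection of Point features carrying the same fields as
#' properties. Coordinates are planar metres. Row/feature order is
#' preserved. Records are validated: ids must be unique, coordinates
#' finite, and \code{level} one of primary/secondary/tertiary.
#'
#' @param path file path.
#' @param format \code{"csv"} or \code{"geojson"}.
#' @return a data.frame of validated facility records.
#' @seealso [write_facilities()], [read_enrollees()]
#' @export
read_facilities <- function(path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- if (format == "csv") {
    read.csv(path, colClasses = "character", check.names = TRUE)
  } else {
    read_geojson_points(path)
  }
  validate_facilities(df)
}

#' Read an enrollee table
#'
#' Reads insured-person records (CSV columns
#' \code{id,x,y,used_facility_id}, or GeoJSON Point features with the same
#' properties). \code{x, y} are the recorded (landmark-proxy) residence in
#' planar metres; \code{used_facility_id} names the facility the enrollee
#' actually attends and must be non-empty — it is resolved against a
#' facility table at analysis time by [assign_nearest()].
#'
#' @inheritParams read_facilities
#' @return a data.frame of validated enrollee records.
#' @export
read_enrollees <- function(path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- if (format == "csv") {
    read.csv(path, colClasses = "character", check.names = TRUE)
  } else {
    read_geojson_points(path)
  }
  validate_enrollees(df)
}

#' Write facility or enrollee tables
#'
#' @param records a validated facility or enrollee data.frame.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"geojson"}.
#' @return the path, invisibly.
#' @rdname write_records
#' @export
write_facilities <- function(records, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  records <- validate_facilities(records)
  if (format == "csv") write.csv(records, path, row.names = FALSE)
  else write_geojson(records, path)
  invisible(path)
}

#' @rdname write_records
#' @export
write_enrollees <- function(records, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  records <- validate_enrollees(records)
  if (format == "csv") write.csv(records, path, row.names = FALSE)
  else write_geojson(records, path)
  invisible(path)
}

#' Write records as GeoJSON
#'
#' Emits an RFC 7946 FeatureCollection. A data.frame with \code{x}/\code{y}
#' columns becomes Point features (coordinates ordered x, y; all other
#' columns carried as Feature properties). A [hub_lines()] table becomes
#' LineString features with \code{enrollee_id, facility_id, distance_m,
#' bypassed} properties.
#'
#' @param records a facility/enrollee data.frame or a \code{hub_lines} table.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_geojson <- function(records, path) {
  features <- if (inherits(records, "hub_lines")) {
    lapply(seq_len(nrow(records)), function(i) {
      list(
        type = "Feature",
        geometry = list(
          type = "LineString",
          coordinates = list(c(records$x0[i], records$y0[i]),
                             c(records$x1[i], records$y1[i]))
        ),
        properties = list(
          enrollee_id = records$enrollee_id[i],
          facility_id = records$facility_id[i],
          distance_m = records$distance_m[i],
          bypassed = records$bypassed[i]
        )
      )
    })
  } else {
    props <- setdiff(names(records), c("x", "y"))
    lapply(seq_len(nrow(records)), function(i) {
      list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(records$x[i], records$y[i])),
        properties = as.list(records[i, props, drop = FALSE])
      )
    })
  }
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# Parse a GeoJSON FeatureCollection of Points back into a flat data.frame
# with x, y plus one column per property.
read_geojson_points <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    stop_schema("not a GeoJSON FeatureCollection: %s", path)
  }
  if (length(fc$features) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  rows <- lapply(fc$features, function(f) {
    if (!identical(f$geometry$type, "Point")) {
      stop_schema("expected Point features, found %s", f$geometry$type)
    }
    c(list(x = as.numeric(f$geometry$coordinates[[1]]),
           y = as.numeric(f$geometry$coordinates[[2]])),
      f$properties)
  })
  props <- names(rows[[1]])
  df <- as.data.frame(lapply(setNames(props, props), function(p) {
    vapply(rows, function(r) {
      v <- r[[p]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  }), stringsAsFactors = FALSE)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  df
}

LGA_COLS <- c("name", "stratum", "population", "facilities_primary",
              "facilities_secondary", "facilities_tertiary",
              "nhis_facilities", "enrollees")

#' Read an administrative-area (LGA) summary table
#'
#' One row per local government area: \code{name}, \code{stratum}
#' (\code{urban} or \code{semiurban}), \code{population}, facility counts by
#' care level (\code{facilities_primary}, \code{facilities_secondary},
#' \code{facilities_tertiary}), \code{nhis_facilities} (accredited count)
#' and \code{enrollees}. Accredited facilities cannot exceed the secondary
#' plus tertiary count, since the insurance scheme does not accredit
#' primary-care facilities.
#'
#' @param path CSV file path.
#' @return a validated data.frame of LGA records.
#' @export
read_lga_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  validate_lga_table(read.csv(path, check.names = TRUE))
}

validate_lga_table <- function(df) {
  check_columns(df, LGA_COLS, "LGA")
  df <- df[, LGA_COLS]
  df$name <- as.character(df$name)
  df$stratum <- tolower(as.character(df$stratum))
  bad <- which(!df$stratum %in% c("urban", "semiurban"))
  if (length(bad) > 0) {
    stop_schema("stratum must be urban or semiurban; invalid at row(s): %s",
                paste(bad, collapse = ", "))
  }
  counts <- c("population", "facilities_primary", "facilities_secondary",
              "facilities_tertiary", "nhis_facilities", "enrollees")
  for (col in counts) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]]) | df[[col]] < 0)) {
      stop_schema("LGA column %s must be a non-negative count", col)
    }
  }
  over <- which(df$nhis_facilities >
                  df$facilities_secondary + df$facilities_tertiary)
  if (length(over) > 0) {
    stop_schema(paste0("nhis_facilities exceeds secondary+tertiary count at ",
                       "row(s): %s (primary facilities are not accredited)"),
                paste(over, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}
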