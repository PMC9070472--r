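#' Run the full accessibility pipeline
#'
#' Orchestrates simulate (or load) -> nearest-neighbour analysis -> hotspot
#' mapping -> nearest-facility assignment -> report tables, writing every
#' product plus a machine-readable run manifest to \code{out_dir}. Each
#' stage is logged; a failure aborts with the stage name and cause.
#'
#' The configuration is a list, or a path to a YAML/JSON document, with:
#' \describe{
#'   \item{seed}{integer; seeds every stochastic stage.}
#'   \item{simulate}{optional list of [synthetic_config()] arguments
#'     (\code{n_facilities}, \code{pattern}, \code{n_enrollees},
#'     \code{decay_lambda}, \code{area}, ...). Mutually required with
#'     \code{inputs}: exactly one source of data must be named.}
#'   \item{inputs}{optional list with \code{facilities} and \code{enrollees}
#'     file paths, their \code{format}, and \code{area} (m^2) or
#'     \code{boundary} (GeoJSON polygon is not read; supply \code{area}).}
#'   \item{nna}{optional list: \code{alpha} (default 0.05).}
#'   \item{hotspot}{optional list: \code{cell_size}, \code{band} (m).}
#'   \item{assign}{optional list: \code{accredited_only} (default TRUE).}
#' }
#'
#' Outputs written: \code{facilities.csv}, \code{enrollees.csv},
#' \code{nna_result.json}, \code{hotspot_cells.csv},
#' \code{hotspot_cells.geojson}, \code{assignments.csv},
#' \code{hub_lines_nearest.geojson}, \code{hub_lines_used.geojson},
#' \code{bypass_table.csv}, \code{distance_summary.csv},
#' \code{manifest.json}.
#'
#' @param config list or path to a YAML/JSON config document.
#' @param out_dir output directory (created if absent); overrides any
#'   \code{out_dir} in the config.
#' @param seed optional integer overriding the config seed (flags win over
#'   config, config wins over defaults).
#' @return (invisibly) a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config$seed <- as.integer(config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir given", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    message(sprintf("[%s] running", name))
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (!has_sim && !has_inputs) {
    stop("config error: neither a 'simulate' block nor an 'inputs' block is present",
         call. = FALSE)
  }

  dat <- if (has_sim) {
    stage("simulate", {
      args <- config$simulate
      if (!is.null(args$area) && !inherits(args$area, "study_area")) {
        args$area <- study_area(area = as.numeric(args$area))
      }
      args$seed <- config$seed
      simulate_dataset(do.call(synthetic_config, args))
    })
  } else {
    stage("load", {
      inp <- config$inputs
      fmt <- inp$format %||% "csv"
      list(
        facilities = read_facilities(inp$facilities, fmt),
        enrollees = read_enrollees(inp$enrollees, fmt),
        config = list(area = study_area(area = as.numeric(inp$area)))
      )
    })
  }
  area <- dat$config$area
  facilities <- dat$facilities
  enrollees <- dat$enrollees
  write.csv(facilities, file.path(out_dir, "facilities.csv"), row.names = FALSE)
  write.csv(enrollees, file.path(out_dir, "enrollees.csv"), row.names = FALSE)

  nna <- stage("nna", {
    clark_evans(facilities, area, alpha = config$nna$alpha %||% 0.05)
  })
  jsonlite::write_json(unclass(nna), file.path(out_dir, "nna_result.json"),
                       auto_unbox = TRUE, digits = NA)

  cells <- stage("hotspot", {
    hotspot_analysis(facilities, area,
                     cell_size = config$hotspot$cell_size,
                     band = config$hotspot$band)
  })
  write.csv(as.data.frame(cells), file.path(out_dir, "hotspot_cells.csv"),
            row.names = FALSE)
  cell_pts <- data.frame(x = cells$center_x, y = cells$center_y,
                         cell_id = cells$cell_id, count = cells$count,
                         gi_z = cells$gi_z, p_raw = cells$p_raw,
                         p_adj = cells$p_adj, bin = cells$bin)
  write_geojson(cell_pts, file.path(out_dir, "hotspot_cells.geojson"))

  assignments <- stage("assign", {
    assign_nearest(enrollees, facilities,
                   accredited_only = config$assign$accredited_only %||% TRUE)
  })
  write.csv(assignments, file.path(out_dir, "assignments.csv"), row.names = FALSE)
  write_geojson(hub_lines(assignments, enrollees, facilities, "nearest"),
                file.path(out_dir, "hub_lines_nearest.geojson"))
  write_geojson(hub_lines(assignments, enrollees, facilities, "used"),
                file.path(out_dir, "hub_lines_used.geojson"))

  reports <- stage("report", {
    list(bypass = bypass_table(assignments),
         distance = distance_summary(assignments))
  })
  write.csv(reports$bypass, file.path(out_dir, "bypass_table.csv"),
            row.names = FALSE)
  write.csv(reports$distance, file.path(out_dir, "distance_summary.csv"),
            row.names = FALSE)

  manifest <- list(
    package = "geoaccess",
    version = as.character(packageVersion("geoaccess")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("out_dir"))],
    n_facilities = nrow(facilities),
    n_enrollees = nrow(enrollees),
    area_m2 = area$area,
    nna = list(rn = nna$rn, z = nna$z_score, p = nna$p_value,
               pattern = nna$pattern),
    overall_bypass_pct = reports$bypass$pct_bypassed[nrow(reports$bypass)],
    outputs = c("facilities.csv", "enrollees.csv", "nna_result.json",
                "hotspot_cells.csv", "hotspot_cells.geojson",
                "assignments.csv", "hub_lines_nearest.geojson",
                "hub_lines_used.geojson", "bypass_table.csv",
                "distance_summary.csv"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("[done] all outputs written to ", out_dir)
  invisible(list(facilities = facilities, enrollees = enrollees, nna = nna,
                 cells = cells, assignments = assignments, reports = reports,
                 manifest = manifest))
}

# Read a YAML or JSON config file (by extension; YAML parses JSON too).
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
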