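#' Assign each enrollee to the nearest facility and flag bypassing
#'
#' For every enrollee, finds the Euclidean-nearest facility (by default
#' restricted to accredited facilities, the set an insured person may use),
#' records the distances to the nearest and to the actually used facility,
#' and flags bypassing: using a facility that is not among the co-nearest
#' facilities (equal to the minimum distance within a 1e-6 m tolerance).
#' Ties for nearest are reported as the lexicographically smallest facility
#' id; the full co-nearest set is used for the bypass decision, so using
#' ANY co-nearest facility is not bypassing.
#'
#' Distances are straight-line (Euclidean) on the planar coordinates, the
#' study's proxy for travel cost; no road network or travel time is
#' considered.
#'
#' @param enrollees validated enrollee table ([read_enrollees()]).
#' @param facilities validated facility table ([read_facilities()]).
#' @param accredited_only restrict the candidate set (and the resolution of
#'   \code{used_facility_id}) to accredited facilities (default TRUE).
#' @param tol distance tie tolerance in metres (default 1e-6).
#' @return a data.frame of class \code{assignments} with columns
#'   \code{enrollee_id}, \code{nearest_facility_id}, \code{nearest_distance},
#'   \code{used_facility_id}, \code{used_distance}, \code{bypassed}
#'   (distances in metres).
#' @export
assign_nearest <- function(enrollees, facilities, accredited_only = TRUE,
                           tol = 1e-6) {
  fac <- facilities
  if (accredited_only) fac <- fac[fac$nhis_accredited, , drop = FALSE]
  if (nrow(fac) == 0) {
    stop("no facilities left after the accreditation filter", call. = FALSE)
  }
  used_idx <- match(enrollees$used_facility_id, fac$id)
  if (anyNA(used_idx)) {
    bad <- enrollees$id[is.na(used_idx)]
    stop(sprintf("used_facility_id does not resolve for enrollee(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  d <- sqrt(outer(enrollees$x, fac$x, "-")^2 +
              outer(enrollees$y, fac$y, "-")^2)
  nearest_distance <- apply(d, 1L, min)
  n <- nrow(enrollees)
  nearest_id <- character(n)
  bypassed <- logical(n)
  for (i in seq_len(n)) {
    co <- fac$id[d[i, ] <= nearest_distance[i] + tol]
    nearest_id[i] <- min(co)
    bypassed[i] <- !(enrollees$used_facility_id[i] %in% co)
  }
  out <- data.frame(
    enrollee_id = enrollees$id,
    nearest_facility_id = nearest_id,
    nearest_distance = nearest_distance,
    used_facility_id = enrollees$used_facility_id,
    used_distance = d[cbind(seq_len(n), used_idx)],
    bypassed = bypassed,
    stringsAsFactors = FALSE
  )
  class(out) <- c("assignments", "data.frame")
  out
}

#' Hub lines from enrollees to facilities
#'
#' Builds the straight segments ("spider-web diagram") joining each
#' enrollee's recorded residence to either the nearest or the used facility,
#' ready for [write_geojson()] as LineString features with
#' \code{enrollee_id, facility_id, distance_m, bypassed} properties.
#'
#' @param assignments an \code{assignments} table from [assign_nearest()].
#' @param enrollees the enrollee table used for the assignment.
#' @param facilities the facility table used for the assignment.
#' @param which \code{"nearest"} or \code{"used"} facility endpoint.
#' @return a data.frame of class \code{hub_lines} with the segment
#'   endpoints (\code{x0, y0, x1, y1}) and properties.
#' @export
hub_lines <- function(assignments, enrollees, facilities,
                      which = c("nearest", "used")) {
  which <- match.arg(which)
  fid <- if (which == "nearest") assignments$nearest_facility_id
         else assignments$used_facility_id
  dist_m <- if (which == "nearest") assignments$nearest_distance
            else assignments$used_distance
  ei <- match(assignments$enrollee_id, enrollees$id)
  fi <- match(fid, facilities$id)
  out <- data.frame(
    enrollee_id = assignments$enrollee_id,
    facility_id = fid,
    distance_m = dist_m,
    bypassed = assignments$bypassed,
    x0 = enrollees$x[ei], y0 = enrollees$y[ei],
    x1 = facilities$x[fi], y1 = facilities$y[fi],
    stringsAsFactors = FALSE
  )
  class(out) <- c("hub_lines", "data.frame")
  out
}

#' Bypassing status by patronised facility
#'
#' Groups assignments by the facility the enrollee USES (the study
#' interviewed patrons at each facility) and tabulates how many of each
#' facility's patrons bypassed a nearer facility to get there. Percentages
#' are computed from the counts at 1 decimal place (half-up); the total
#' row recomputes its percentages from the summed counts, never by summing
#' the per-facility percentages.
#'
#' @param assignments an \code{assignments} table from [assign_nearest()].
#' @return a data.frame of class \code{bypass_summary} with one row per
#'   patronised facility plus a \code{"Total"} row: \code{facility_id},
#'   \code{n_patrons}, \code{n_bypassed}, \code{pct_bypassed},
#'   \code{n_non_bypassed}, \code{pct_non_bypassed}.
#' @export
bypass_table <- function(assignments) {
  if (nrow(assignments) == 0) stop("no assignments", call. = FALSE)
  ids <- sort(unique(assignments$used_facility_id))
  rows <- lapply(ids, function(f) {
    sel <- assignments$used_facility_id == f
    np <- sum(sel); nb <- sum(assignments$bypassed[sel])
    data.frame(facility_id = f, n_patrons = np, n_bypassed = nb,
               pct_bypassed = round_half_up(100 * nb / np, 1),
               n_non_bypassed = np - nb,
               pct_non_bypassed = round_half_up(100 * (np - nb) / np, 1),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  np <- sum(tab$n_patrons); nb <- sum(tab$n_bypassed)
  total <- data.frame(facility_id = "Total", n_patrons = np, n_bypassed = nb,
                      pct_bypassed = round_half_up(100 * nb / np, 1),
                      n_non_bypassed = np - nb,
                      pct_non_bypassed = round_half_up(100 * (np - nb) / np, 1),
                      stringsAsFactors = FALSE)
  out <- rbind(tab, total)
  rownames(out) <- NULL
  class(out) <- c("bypass_summary", "data.frame")
  out
}

#' Shortest and longest distance travelled, by patronised facility
#'
#' For each facility, the minimum and maximum straight-line distance
#' travelled by its patrons (distance to the USED facility), reported in
#' kilometres at 3 decimal places (half-up). A final \code{"Average"} row
#' holds the unweighted arithmetic mean of each column over the facility
#' rows. Facilities with no patrons do not appear.
#'
#' @param assignments an \code{assignments} table from [assign_nearest()].
#' @return a data.frame of class \code{distance_summary} with columns
#'   \code{facility_id}, \code{shortest_km}, \code{longest_km}.
#' @export
distance_summary <- function(assignments) {
  if (nrow(assignments) == 0) stop("no assignments", call. = FALSE)
  ids <- sort(unique(assignments$used_facility_id))
  rows <- lapply(ids, function(f) {
    dd <- assignments$used_distance[assignments$used_facility_id == f]
    data.frame(facility_id = f,
               shortest_km = round_half_up(min(dd) / 1000, 3),
               longest_km = round_half_up(max(dd) / 1000, 3),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  avg <- data.frame(facility_id = "Average",
                    shortest_km = round_half_up(mean(tab$shortest_km), 3),
                    longest_km = round_half_up(mean(tab$longest_km), 3),
                    stringsAsFactors = FALSE)
  out <- rbind(tab, avg)
  rownames(out) <- NULL
  class(out) <- c("distance_summary", "data.frame")
  out
}
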