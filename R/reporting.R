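#' Coverage statistics by administrative stratum
#'
#' Sums an LGA summary table (see [read_lga_table()]) by stratum and derives
#' the headline coverage percentages, all recomputed from the raw sums and
#' printed at 1 decimal place (half-up):
#' \itemize{
#'   \item \code{urban_pop_share}: urban population / gross population;
#'   \item \code{urban_nhis_coverage}, \code{semiurban_nhis_coverage}:
#'     stratum enrollees / stratum population;
#'   \item \code{urban_enrollee_share}, \code{semiurban_enrollee_share}:
#'     stratum enrollees / total enrollees;
#'   \item per-LGA \code{nhis_accreditation_share}: accredited facilities /
#'     ALL facilities in the LGA (the convention of the source tables).
#' }
#'
#' @param lga_table a validated LGA data.frame; at least one urban and one
#'   semiurban row.
#' @return an object of class \code{coverage_report}: a list with
#'   \code{stratum_totals} (data.frame), the derived percentages, and
#'   \code{per_lga} (data.frame with \code{name}, \code{stratum},
#'   \code{total_facilities}, \code{nhis_accreditation_share}).
#' @export
coverage_stats <- function(lga_table) {
  lga_table <- validate_lga_table(lga_table)
  if (!all(c("urban", "semiurban") %in% lga_table$stratum)) {
    stop("need at least one urban and one semiurban record", call. = FALSE)
  }
  tot_fac <- lga_table$facilities_primary + lga_table$facilities_secondary +
    lga_table$facilities_tertiary
  agg <- function(stratum) {
    sel <- lga_table$stratum == stratum
    c(population = sum(lga_table$population[sel]),
      facilities = sum(tot_fac[sel]),
      nhis_facilities = sum(lga_table$nhis_facilities[sel]),
      enrollees = sum(lga_table$enrollees[sel]))
  }
  urban <- agg("urban"); semi <- agg("semiurban")
  gross_pop <- urban["population"] + semi["population"]
  total_enr <- urban["enrollees"] + semi["enrollees"]
  if (gross_pop <= 0) stop("gross population is zero", call. = FALSE)
  pct <- function(num, den) round_half_up(100 * num / den, 1)
  per_lga <- data.frame(
    name = lga_table$name, stratum = lga_table$stratum,
    total_facilities = tot_fac,
    nhis_accreditation_share = ifelse(
      tot_fac > 0, round_half_up(100 * lga_table$nhis_facilities / tot_fac, 1), NA),
    stringsAsFactors = FALSE
  )
  structure(list(
    stratum_totals = data.frame(
      stratum = c("urban", "semiurban"),
      population = c(urban["population"], semi["population"]),
      facilities = c(urban["facilities"], semi["facilities"]),
      nhis_facilities = c(urban["nhis_facilities"], semi["nhis_facilities"]),
      enrollees = c(urban["enrollees"], semi["enrollees"]),
      row.names = NULL
    ),
    urban_pop_share = unname(pct(urban["population"], gross_pop)),
    urban_nhis_coverage = unname(pct(urban["enrollees"], urban["population"])),
    semiurban_nhis_coverage = unname(pct(semi["enrollees"], semi["population"])),
    urban_enrollee_share = unname(pct(urban["enrollees"], total_enr)),
    semiurban_enrollee_share = unname(pct(semi["enrollees"], total_enr)),
    per_lga = per_lga
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Coverage report\n")
  print(x$stratum_totals, row.names = FALSE)
  cat(sprintf("  urban population share:      %5.1f%%\n", x$urban_pop_share))
  cat(sprintf("  urban scheme coverage:       %5.1f%%\n", x$urban_nhis_coverage))
  cat(sprintf("  semiurban scheme coverage:   %5.1f%%\n", x$semiurban_nhis_coverage))
  cat(sprintf("  urban enrollee share:        %5.1f%%\n", x$urban_enrollee_share))
  cat(sprintf("  semiurban enrollee share:    %5.1f%%\n", x$semiurban_enrollee_share))
  invisible(x)
}

#' Leslie Kish minimum sample size for a proportion
#'
#' \code{n = ceiling(z^2 p (1 - p) / d^2)} for anticipated proportion
#' \code{p}, absolute precision \code{d} and standard-normal quantile
#' \code{z} (1.96 for 95\% confidence). The ceiling is the conservative
#' convention: never report fewer subjects than the formula requires.
#'
#' @param p anticipated proportion, strictly between 0 and 1.
#' @param d absolute precision (margin of error), > 0.
#' @param z standard-normal quantile (default 1.96).
#' @return integer minimum sample size.
#' @examples
#' kish_sample_size(0.5, 0.05)    # 385
#' kish_sample_size(0.407, 0.05)  # 371
#' @export
kish_sample_size <- function(p, d, z = 1.96) {
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  if (!is.finite(d) || d <= 0) stop("d must be > 0", call. = FALSE)
  as.integer(ceiling(z^2 * p * (1 - p) / d^2))
}
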