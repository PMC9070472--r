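#' Round half away from zero
#'
#' Rounding with the half-up convention used by the report tables (base R's
#' \code{round} rounds halves to even). \code{round_half_up(0.15, 1)} is 0.2.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse CSV-style booleans: true/false, 1/0, yes/no (case-insensitive).
parse_bool <- function(x, field = "value") {
  if (is.logical(x)) return(x)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "1", "yes", "t")] <- TRUE
  out[s %in% c("false", "0", "no", "f")] <- FALSE
  if (anyNA(out)) {
    bad <- which(is.na(out))
    stop(sprintf("cannot parse %s as boolean at row(s) %s: %s",
                 field, paste(bad, collapse = ", "),
                 paste(unique(s[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

stop_schema <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_schema("%s table is missing required column(s): %s",
                what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

check_finite_coords <- function(df, what) {
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad) > 0) {
    stop_schema("%s table has non-finite coordinates at row(s): %s",
                what, paste(bad, collapse = ", "))
  }
  invisible(df)
}

check_unique_ids <- function(df, what) {
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0) {
    stop_schema("%s table has duplicated id(s): %s",
                what, paste(dup, collapse = ", "))
  }
  invisible(df)
}

# Per-point distance to the nearest other point, plain O(n^2) scan.
# Vectorised in blocks so the full n x n matrix is never materialised for
# large n; exact for coincident points (distance 0 to a duplicate).
nn_distances <- function(x, y, block = 512L) {
  n <- length(x)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}
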