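#' Parse year-month or full dates
#'
#' Accepts `"YYYY"`, `"YYYY-MM"` or `"YYYY-MM-DD"` strings (and `Date`
#' objects), returning `Date`s anchored at the first of the month/year.
#'
#' @param x Character or `Date` vector.
#' @return `Date` vector (`NA` where unparsable or empty).
#' @export
parse_date_ym <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- trimws(as.character(x))
  x[x == "" | is.na(x)] <- NA
  full <- ifelse(grepl("^\\d{4}$", x), paste0(x, "-01-01"),
          ifelse(grepl("^\\d{4}-\\d{2}$", x), paste0(x, "-01"), x))
  as.Date(full, format = "%Y-%m-%d")
}

#' Oldest date associated with a family
#'
#' The discovery date of a family is the minimum over its literature
#' reference dates and the dates of its sequence records, whichever source is
#' older. Families with no date in either source are excluded upstream with
#' a warning.
#'
#' @param family_dates Literature dates (character or `Date`).
#' @param record_dates Sequence-record dates (character or `Date`).
#' @return The minimum `Date`, or `NA` if no date is available.
#' @export
oldest_date <- function(family_dates, record_dates = NULL) {
  d <- c(parse_date_ym(family_dates), parse_date_ym(record_dates))
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(as.Date(NA))
  min(d)
}

#' Count domains of life in a Venn presence pattern
#'
#' Maps each unit of a domain-level presence matrix to its
#' number-of-domains class (`"1-domain"`, `"2-domain"`, `"3-domain"`),
#' counting Archaea, Bacteria and Eukaryota only — viral presence does not
#' change the class.
#'
#' @param matrix A domain-level `presence_matrix`.
#' @return Named character vector unit -> class (`NA` for units present in
#'   no domain of life).
#' @export
domain_count_class <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  cellular <- intersect(c("Archaea", "Bacteria", "Eukaryota"),
                        matrix$column_ids)
  n <- rowSums(matrix$present[, cellular, drop = FALSE])
  cls <- ifelse(n >= 1L, paste0(n, "-domain"), NA_character_)
  stats::setNames(cls, matrix$unit_ids)
}

#' Cumulative discovery curves per domain-distribution class
#'
#' For each class, the cumulative number of families whose oldest associated
#' date falls at or before each year. Dates are binned by year. Each series
#' is monotone non-decreasing and ends at its class size.
#'
#' @param dates Named `Date` (or parsable character) vector: family
#'   accession -> oldest date (see [oldest_date()]). Families with `NA`
#'   dates are dropped with a warning.
#' @param classes Named character vector: family accession -> class label
#'   (e.g. from [domain_count_class()]).
#' @return data.frame with columns `class`, `year`, `cumulative`; one row
#'   per (class, year with at least one discovery).
#' @export
discovery_curve <- function(dates, classes) {
  dates <- stats::setNames(parse_date_ym(dates), names(dates))
  drop <- is.na(dates)
  if (any(drop)) {
    warning(sum(drop), " families excluded from discovery curve: no date")
    dates <- dates[!drop]
  }
  cls <- classes[names(dates)]
  keep <- !is.na(cls)
  dates <- dates[keep]
  cls <- cls[keep]
  if (length(dates) == 0L) {
    return(data.frame(class = character(0), year = integer(0),
                      cumulative = integer(0)))
  }
  year <- as.integer(format(dates, "%Y"))
  out <- lapply(sort(unique(cls)), function(cl) {
    y <- sort(year[cls == cl])
    yy <- unique(y)
    data.frame(class = cl, year = yy,
               cumulative = cumsum(as.integer(table(factor(y, levels = yy)))))
  })
  do.call(rbind, out)
}

#' Write discovery curves to TSV
#'
#' @param curve data.frame from [discovery_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_discovery_curve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
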