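DOMAINS <- c("Archaea", "Bacteria", "Eukaryota", "Viruses")
DOMAIN_LETTERS <- c(Archaea = "A", Bacteria = "B", Eukaryota = "E",
                    Viruses = "V")

#' Build a presence/absence matrix of RNA units across taxonomic columns
#'
#' Bins vetted annotations into a boolean occupancy matrix of family (or
#' clan) by taxonomic unit, with a parallel support matrix counting the
#' annotations behind each cell. Columns are either the four top-level sets
#' (`columns = "domain"`) or the major divisions of one domain
#' (`columns = "division"`). Taxa whose domain (or division) resolved to
#' `UNASSIGNED` contribute to no column. At clan level the member families'
#' rows are OR-ed: a clan is present wherever any member family is, and its
#' support is the summed member support.
#'
#' @param records Annotation data.frame (`family_accession`, `taxon_id`, ...).
#' @param assignments data.frame from [assign_division()].
#' @param level `"family"` or `"clan"`.
#' @param columns `"domain"` (all four sets) or `"division"`.
#' @param domain For `columns = "division"`: which domain's divisions.
#' @param division_levels For `columns = "division"`: the full set of
#'   division columns the matrix must carry (e.g. [domain_divisions()]).
#'   Defaults to the divisions observed in the assignments of that domain.
#' @param clan_map For `level = "clan"`: data.frame with columns
#'   `family_accession`, `clan_accession`. Families without a clan keep their
#'   own accession as the unit (a clan replaces its member families, so
#'   headline counts mix families and clans without double counting).
#' @return Object of class `presence_matrix`: list with `present` (logical
#'   matrix), `support` (integer matrix), `unit_ids`, `column_ids`, `level`.
#' @export
build_presence <- function(records, assignments,
                           level = c("family", "clan"),
                           columns = c("domain", "division"),
                           domain = NULL, division_levels = NULL,
                           clan_map = NULL) {
  level <- match.arg(level)
  columns <- match.arg(columns)
  asn <- assignments[match(records$taxon_id, assignments$taxon_id), ,
                     drop = FALSE]
  if (columns == "domain") {
    col_ids <- DOMAINS
    col_of <- asn$domain
  } else {
    if (is.null(domain)) {
      stop("usage error: columns = 'division' requires a domain")
    }
    keep <- !is.na(asn$domain) & asn$domain == domain
    records <- records[keep, , drop = FALSE]
    asn <- asn[keep, , drop = FALSE]
    col_of <- asn$division
    col_ids <- division_levels
    if (is.null(col_ids)) {
      col_ids <- sort(setdiff(unique(col_of), UNASSIGNED))
    }
  }
  unit_of <- records$family_accession
  if (level == "clan") {
    if (is.null(clan_map)) {
      stop("configuration error: clan level requested but no clan map given")
    }
    m <- match(unit_of, clan_map$family_accession)
    clan <- clan_map$clan_accession[m]
    repl <- !is.na(m) & !is.na(clan) & clan != ""
    unit_of[repl] <- clan[repl]
  }
  ok <- !is.na(col_of) & col_of %in% col_ids
  unit_ids <- sort(unique(unit_of))
  support <- matrix(0L, nrow = length(unit_ids), ncol = length(col_ids),
                    dimnames = list(unit_ids, col_ids))
  if (any(ok)) {
    tab <- table(factor(unit_of[ok], levels = unit_ids),
                 factor(col_of[ok], levels = col_ids))
    support[] <- as.integer(tab)
  }
  structure(list(present = support > 0L, support = support,
                 unit_ids = unit_ids, column_ids = col_ids, level = level),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix (", x$level, "): ", length(x$unit_ids), " units x ",
      length(x$column_ids), " columns [",
      paste(x$column_ids, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Partition units into four-set Venn regions by domain presence
#'
#' Assigns every unit of a domain-level presence matrix to exactly one of
#' the 15 non-empty regions of the four-set (Archaea, Bacteria, Eukaryota,
#' Viruses) Venn diagram, keyed by sorted letter codes (`"A"`, `"AB"`, ...,
#' `"ABEV"`). Units present in no column are excluded from every region and
#' reported separately.
#'
#' @param matrix A domain-level `presence_matrix` (columns exactly the four
#'   sets).
#' @return Object of class `venn_partition`: list with `region_counts`
#'   (named integer vector over the 15 regions), `region_units` (named list
#'   of accessions), `n_units` (units with non-empty presence), `n_empty`,
#'   and `single_set_fraction` (share of units confined to one set).
#' @export
venn_partition <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (!identical(sort(matrix$column_ids), sort(DOMAINS))) {
    stop("usage error: venn_partition needs columns exactly {",
         paste(DOMAINS, collapse = ", "), "}")
  }
  pres <- matrix$present[, DOMAINS, drop = FALSE]
  regions <- .venn_region_names()
  key <- apply(pres, 1L, function(r) {
    paste(DOMAIN_LETTERS[DOMAINS[r]], collapse = "")
  })
  nonempty <- key != ""
  counts <- stats::setNames(integer(length(regions)), regions)
  tab <- table(key[nonempty])
  counts[names(tab)] <- as.integer(tab)
  units <- lapply(regions, function(rg) {
    sort(matrix$unit_ids[nonempty & key == rg])
  })
  names(units) <- regions
  structure(list(
    region_counts = counts,
    region_units = units,
    n_units = sum(nonempty),
    n_empty = sum(!nonempty),
    single_set_fraction =
      if (sum(nonempty)) sum(counts[c("A", "B", "E", "V")]) / sum(nonempty)
      else NA_real_
  ), class = "venn_partition")
}

.venn_region_names <- function() {
  lets <- unname(DOMAIN_LETTERS)
  out <- character(0)
  for (k in 1:4) {
    cmb <- utils::combn(lets, k)
    out <- c(out, apply(cmb, 2L, paste, collapse = ""))
  }
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition:", x$n_units, "units in regions;", x$n_empty,
      "with empty presence\n")
  print(x$region_counts[x$region_counts > 0L])
  invisible(x)
}

#' Classify units as broadly distributed within a domain
#'
#' A unit is broadly distributed when it is present in at least the given
#' fraction of the domain's major taxonomic divisions. The boundary is
#' inclusive (exactly 50% counts as broad) and the denominator is the full
#' set of division columns the matrix carries, not only occupied ones
#' (`occupied_only = TRUE` restricts it for sensitivity checks).
#'
#' @param matrix A division-level `presence_matrix` for one domain.
#' @param threshold Fraction in (0, 1]; default 0.5.
#' @param domain Optional domain label recorded in the output.
#' @param occupied_only If `TRUE`, the denominator counts only divisions with
#'   at least one annotated unit.
#' @return data.frame with one row per unit: `unit_id`, `domain`,
#'   `divisions_present`, `divisions_total`, `broad`.
#' @export
broad_distribution <- function(matrix, threshold = 0.5, domain = NA_character_,
                               occupied_only = FALSE) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("configuration error: threshold must lie in (0, 1]")
  }
  total <- if (occupied_only) sum(colSums(matrix$present) > 0L)
           else length(matrix$column_ids)
  if (total < 1L) stop("configuration error: no division columns")
  npres <- rowSums(matrix$present)
  data.frame(
    unit_id = matrix$unit_ids,
    domain = domain,
    divisions_present = as.integer(npres),
    divisions_total = as.integer(total),
    broad = npres / total >= threshold,
    stringsAsFactors = FALSE
  )
}

#' Round half-up to a number of decimal places
#'
#' Percentage rounding used in reporting (printed rates round half away from
#' zero, not to even).
#'
#' @param x Numeric vector (non-negative use expected).
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Broad-distribution rate of a domain
#'
#' The share of a domain's units (with at least one division presence) that
#' are broadly distributed, as a fraction and as a percentage rounded
#' half-up to one decimal.
#'
#' @param calls data.frame from [broad_distribution()] (one domain), or any
#'   data.frame with logical `broad` and integer `divisions_present`.
#' @param count_only_present Drop units with zero division presence from the
#'   denominator (default `TRUE`; such units exist when the division matrix
#'   was given a fixed unit roster).
#' @return List with `broad` (count), `total`, `fraction`, `percent`.
#' @export
broad_distribution_rate <- function(calls, count_only_present = TRUE) {
  if (count_only_present && "divisions_present" %in% names(calls)) {
    calls <- calls[calls$divisions_present > 0L, , drop = FALSE]
  }
  if (nrow(calls) == 0L) {
    stop("undefined rate: no units with presence in this domain")
  }
  b <- sum(calls$broad)
  n <- nrow(calls)
  list(broad = b, total = n, fraction = b / n,
       percent = round_half_up(100 * b / n, 1L))
}

#' Units present in two or more domains of life
#'
#' Interdomain units are those present in at least two of Archaea, Bacteria
#' and Eukaryota; viruses are a fourth set in the Venn analysis, not a
#' domain of life, so a unit shared between one domain and viruses only is
#' not interdomain and is reported separately.
#'
#' @param matrix A domain-level `presence_matrix`.
#' @return List with `interdomain` (sorted accessions in >= 2 domains of
#'   life) and `virus_sharing` (sorted accessions in exactly one domain of
#'   life plus Viruses).
#' @export
interdomain_units <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  cellular <- intersect(c("Archaea", "Bacteria", "Eukaryota"),
                        matrix$column_ids)
  ndom <- rowSums(matrix$present[, cellular, drop = FALSE])
  viral <- if ("Viruses" %in% matrix$column_ids) {
    matrix$present[, "Viruses"]
  } else rep(FALSE, length(matrix$unit_ids))
  list(
    interdomain = sort(unique(matrix$unit_ids[ndom >= 2L])),
    virus_sharing = sort(unique(matrix$unit_ids[ndom == 1L & viral]))
  )
}

#' Normalised taxonomic abundance of units per group
#'
#' For each unit and taxonomic group, the fraction of the group's sampled
#' taxa carrying at least one annotation of the unit. The denominator is an
#' explicit roster of sampled taxa per group, keeping the normalisation
#' auditable and independent of annotation density; annotated taxa outside
#' the roster are ignored with a warning.
#'
#' @param records Annotation data.frame.
#' @param assignments data.frame from [assign_division()] (used only to
#'   restrict records to assigned taxa; may be `NULL`).
#' @param roster Named list: group label -> vector of taxon ids sampled in
#'   that group. Empty groups are skipped with a warning.
#' @return Numeric matrix unit x group with values in \[0, 1\].
#' @export
normalized_abundance <- function(records, assignments = NULL, roster) {
  stopifnot(is.list(roster), length(names(roster)) == length(roster))
  empty <- lengths(roster) == 0L
  if (any(empty)) {
    warning("skipping empty roster group(s): ",
            paste(names(roster)[empty], collapse = ", "))
    roster <- roster[!empty]
  }
  units <- sort(unique(records$family_accession))
  out <- matrix(0, nrow = length(units), ncol = length(roster),
                dimnames = list(units, names(roster)))
  all_roster <- unlist(roster, use.names = FALSE)
  outside <- setdiff(unique(records$taxon_id), all_roster)
  if (length(outside)) {
    warning(length(outside), " annotated taxa outside the roster ignored")
  }
  for (g in names(roster)) {
    taxa <- roster[[g]]
    sel <- records$taxon_id %in% taxa
    if (!any(sel)) next
    hits <- tapply(records$taxon_id[sel], records$family_accession[sel],
                   function(t) length(unique(t)))
    out[names(hits), g] <- unname(hits) / length(taxa)
  }
  out
}

#' Write a presence matrix to TSV
#'
#' Long format: `unit_id`, `column`, `present`, `support`.
#'
#' @param matrix A `presence_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence <- function(matrix, path) {
  long <- data.frame(
    unit_id = rep(matrix$unit_ids, times = length(matrix$column_ids)),
    column = rep(matrix$column_ids, each = length(matrix$unit_ids)),
    present = as.vector(matrix$present),
    support = as.vector(matrix$support)
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a presence matrix written by [write_presence()]
#'
#' @param path TSV path.
#' @param level `"family"` or `"clan"` tag to restore.
#' @return A `presence_matrix`.
#' @export
read_presence <- function(path, level = "family") {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  units <- unique(long$unit_id)
  cols <- unique(long$column)
  support <- matrix(0L, length(units), length(cols),
                    dimnames = list(units, cols))
  support[cbind(match(long$unit_id, units), match(long$column, cols))] <-
    as.integer(long$support)
  structure(list(present = support > 0L, support = support,
                 unit_ids = units, column_ids = cols, level = level),
            class = "presence_matrix")
}
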