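#' Vetting configuration
#'
#' Parameters of the false-positive removal applied to families whose
#' annotations span more than one domain. The `margin` is the width in bits
#' of the marginal zone above the family's curated seed bitscore cutoff:
#' annotations scoring inside `[cutoff, cutoff + margin)` are treated as too
#' close to the threshold to establish homology on score alone and are
#' dropped unless curator evidence confirms them.
#'
#' @param margin Width of the marginal zone in bits (default 10).
#' @param drop_misannotated Drop records whose evidence flag is
#'   `MISANNOTATED` (default `TRUE`).
#' @param drop_flagged_untested Drop marginal records whose evidence is not
#'   `CONFIRMED` (default `TRUE`); if `FALSE`, such records are only counted.
#' @param vet_all Apply vetting to every family, not only multi-domain ones.
#' @return A list of class `vet_config`.
#' @export
vet_config <- function(margin = 10, drop_misannotated = TRUE,
                       drop_flagged_untested = TRUE, vet_all = FALSE) {
  stopifnot(is.numeric(margin), length(margin) == 1L, margin >= 0)
  structure(list(margin = margin,
                 drop_misannotated = isTRUE(drop_misannotated),
                 drop_flagged_untested = isTRUE(drop_flagged_untested),
                 vet_all = isTRUE(vet_all)),
            class = "vet_config")
}

#' Flag annotations in the marginal bitscore zone
#'
#' An annotation is marginal iff its bitscore is strictly below
#' `seed_cutoff + margin`. The boundary is half-open: a score exactly at
#' `cutoff + margin` is confident. Scores below the cutoff itself (which
#' should not occur in curated exports) fall in the same marginal zone and
#' are not special-cased.
#'
#' @param records data.frame of annotations with columns `family_accession`
#'   and `bitscore` (one family only).
#' @param meta One-row data.frame (or list) of family metadata with
#'   `family_accession` and `seed_cutoff`.
#' @param config A [vet_config()].
#' @return Logical vector, `TRUE` = marginal.
#' @export
margin_flag <- function(records, meta, config = vet_config()) {
  if (nrow(records) == 0L) return(logical(0))
  if (!all(records$family_accession == meta$family_accession)) {
    stop("usage error: records and family metadata accessions differ")
  }
  records$bitscore < meta$seed_cutoff + config$margin
}

#' Vet one family's annotations
#'
#' Reproduces the two-step false-positive removal for a single family. The
#' filter only engages when the family's (pre-vetting) distribution spans
#' more than one domain; single-domain families pass through untouched.
#' For multi-domain families, records flagged `MISANNOTATED` (the outcome of
#' an external taxonomic re-confirmation, e.g. reciprocal BLAST) are dropped
#' first; then marginal records ([margin_flag()]) are dropped unless their
#' evidence is `CONFIRMED`.
#'
#' @param records data.frame of annotations of one family (columns
#'   `seq_accession`, `family_accession`, `taxon_id`, `bitscore`, `evidence`).
#' @param meta Family metadata row (needs `family_accession`, `seed_cutoff`).
#' @param domains_spanned Character vector of domains the family's
#'   annotations occupy before vetting.
#' @param config A [vet_config()].
#' @return List with `kept` (the surviving records) and `report`, a one-row
#'   data.frame with counts `kept`, `dropped_misannotation`, `dropped_margin`
#'   and `flagged_only`.
#' @export
vet_family <- function(records, meta, domains_spanned,
                       config = vet_config()) {
  n <- nrow(records)
  report <- data.frame(kept = n, dropped_misannotation = 0L,
                       dropped_margin = 0L, flagged_only = 0L)
  if (length(domains_spanned) <= 1L && !config$vet_all) {
    return(list(kept = records, report = report))
  }
  drop_mis <- config$drop_misannotated & records$evidence == "MISANNOTATED"
  marginal <- margin_flag(records, meta, config)
  flagged <- marginal & records$evidence != "CONFIRMED" & !drop_mis
  drop_marg <- if (config$drop_flagged_untested) flagged else rep(FALSE, n)
  keep <- !drop_mis & !drop_marg
  list(
    kept = records[keep, , drop = FALSE],
    report = data.frame(
      kept = sum(keep),
      dropped_misannotation = sum(drop_mis),
      dropped_margin = sum(drop_marg),
      flagged_only = if (config$drop_flagged_untested) 0L else sum(flagged)
    )
  )
}

#' Vet a full annotation table
#'
#' Applies [vet_family()] across every family in an annotation table. The
#' domains each family spans are computed from the taxon assignments
#' (`UNASSIGNED` domains do not count towards spanning).
#'
#' @param records Annotation data.frame (multiple families).
#' @param families Family metadata data.frame (`family_accession`,
#'   `seed_cutoff`, ...).
#' @param assignments data.frame from [assign_division()] covering the taxa
#'   in `records`.
#' @param config A [vet_config()].
#' @return List with `kept` (vetted annotation data.frame) and `report`
#'   (per-family report data.frame plus a `family_accession` column).
#' @export
vet_annotations <- function(records, families, assignments,
                            config = vet_config()) {
  dom <- assignments$domain[match(records$taxon_id, assignments$taxon_id)]
  fams <- unique(records$family_accession)
  kept_list <- vector("list", length(fams))
  reports <- vector("list", length(fams))
  for (i in seq_along(fams)) {
    f <- fams[i]
    sel <- records$family_accession == f
    meta <- families[families$family_accession == f, , drop = FALSE]
    if (nrow(meta) == 0L) {
      stop("usage error: no family metadata for accession ", f)
    }
    spanned <- setdiff(unique(dom[sel]), UNASSIGNED)
    res <- vet_family(records[sel, , drop = FALSE], meta[1L, ], spanned,
                      config)
    kept_list[[i]] <- res$kept
    reports[[i]] <- cbind(family_accession = f, res$report)
  }
  list(kept = do.call(rbind, kept_list),
       report = do.call(rbind, reports))
}
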