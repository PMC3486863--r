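#' Read an annotation table
#'
#' Expects a header with columns `seq_accession`, `family_accession`,
#' `taxon_id`, `bitscore`, `evidence`, `date` (the last two optional;
#' missing evidence defaults to `UNTESTED`).
#'
#' @param path TSV path.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(date = "character"))
  need <- c("seq_accession", "family_accession", "taxon_id", "bitscore")
  if (!all(need %in% names(a))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"evidence" %in% names(a)) a$evidence <- "UNTESTED"
  if (!"date" %in% names(a)) a$date <- NA_character_
  if (any(a$bitscore < 0)) stop("bitscore must be non-negative")
  a
}

#' Read a family metadata table
#'
#' Columns: `family_accession`, `name`, `clan_accession`, `seed_cutoff`,
#' `functional_path` (semicolon-separated), `date_refs` (semicolon-separated
#' dates).
#'
#' @param path TSV path.
#' @return data.frame of family metadata.
#' @export
read_families <- function(path) {
  f <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(date_refs = "character"))
  need <- c("family_accession", "seed_cutoff")
  if (!all(need %in% names(f))) {
    stop("family table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(f$seed_cutoff < 0)) stop("seed_cutoff must be non-negative")
  f
}

#' Annotation counts per division: taxonomic sampling-bias profile
#'
#' Counts annotations per (domain, division) and summarises the skew of each
#' domain as the fraction of its annotations falling in its most-annotated
#' division. A uniform spread over `k` divisions gives a top fraction near
#' `1/k`; strongly biased data approach 1.
#'
#' @param records Annotation data.frame.
#' @param assignments data.frame from [assign_division()].
#' @return List with `counts` (data.frame `domain`, `division`, `n`) and
#'   `skew` (data.frame `domain`, `n_divisions`, `top_fraction`).
#' @export
bias_profile <- function(records, assignments) {
  asn <- assignments[match(records$taxon_id, assignments$taxon_id), ,
                     drop = FALSE]
  ok <- !is.na(asn$domain) & asn$domain != UNASSIGNED &
    asn$division != UNASSIGNED
  cnt <- as.data.frame(table(domain = asn$domain[ok],
                             division = asn$division[ok]),
                       stringsAsFactors = FALSE)
  names(cnt)[3L] <- "n"
  cnt <- cnt[cnt$n > 0L, , drop = FALSE]
  cnt <- cnt[order(cnt$domain, -cnt$n), , drop = FALSE]
  rownames(cnt) <- NULL
  skew <- do.call(rbind, lapply(split(cnt, cnt$domain), function(d) {
    data.frame(domain = d$domain[1L], n_divisions = nrow(d),
               top_fraction = max(d$n) / sum(d$n))
  }))
  rownames(skew) <- NULL
  list(counts = cnt, skew = skew)
}

.require_fields <- function(config, fields, where = "config") {
  for (f in fields) {
    if (is.null(config[[f]])) {
      stop("schema error: required field '", f, "' missing from ", where)
    }
  }
}

#' Run the full census pipeline from a configuration
#'
#' Executes taxonomy loading, taxon assignment, vetting, the domain census
#' (presence matrix, Venn partition, interdomain lists), per-domain
#' division censuses with broad-distribution calls and rates, optional
#' Dollo character mapping on a species tree, optional discovery curves,
#' and the sampling-bias profile. All outputs are written under `out_dir`
#' together with a `manifest.json` recording input hashes, parameters,
#' package version and per-stage record counts.
#'
#' @param config Path to a YAML file or a list with fields:
#'   `annotations`, `families`, `taxonomy_nodes` (paths; required),
#'   `taxonomy_names` (for the NCBI dump dialect), `taxonomy_config`
#'   (YAML path or list), `clans` (optional path), `tree` / `tip_taxa`
#'   (optional paths enabling the phylogenetic stage), `margin` (default
#'   10), `broad_threshold` (default 0.5), `clade_coverage` (default 0.5),
#'   `vet_all` (default `FALSE`), `discovery` (default `TRUE`).
#' @param out_dir Output directory.
#' @return List with all in-memory stage results (invisible copies of what
#'   was written): `assignments`, `vet_report`, `presence_domain`, `venn`,
#'   `interdomain`, `broad` (per domain), `broad_rates`, `bias`,
#'   `nominations` (or `NULL`), `discovery` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  .require_fields(config, c("annotations", "families", "taxonomy_nodes"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  counts <- list()

  # stage: taxonomy
  tax_cfg <- config$taxonomy_config
  if (is.character(tax_cfg)) tax_cfg <- yaml::read_yaml(tax_cfg)
  if (is.null(tax_cfg)) tax_cfg <- list()
  index <- load_taxonomy(config$taxonomy_nodes, config$taxonomy_names,
                         tax_cfg)
  stages <- c(stages, "taxonomy")

  # stage: assignment
  ann <- read_annotations(config$annotations)
  fam <- read_families(config$families)
  assignments <- assign_division(unique(ann$taxon_id), index)
  write_assignments(assignments, file.path(out_dir, "assignments.tsv"))
  counts$annotations_in <- nrow(ann)
  counts$taxa <- nrow(assignments)
  counts$taxa_unassigned <- sum(assignments$domain == UNASSIGNED)
  stages <- c(stages, "assign")

  # stage: vetting
  vcfg <- vet_config(margin = config$margin %||% 10,
                     vet_all = isTRUE(config$vet_all))
  vet <- vet_annotations(ann, fam, assignments, vcfg)
  counts$annotations_kept <- nrow(vet$kept)
  counts$dropped_misannotation <- sum(vet$report$dropped_misannotation)
  counts$dropped_margin <- sum(vet$report$dropped_margin)
  jsonlite::write_json(vet$report, file.path(out_dir, "vet_report.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  stages <- c(stages, "vet")

  # stage: census
  clan_map <- NULL
  if (!is.null(config$clans)) {
    clan_map <- utils::read.delim(config$clans, stringsAsFactors = FALSE)
  } else if ("clan_accession" %in% names(fam) &&
             any(fam$clan_accession != "")) {
    clan_map <- fam[fam$clan_accession != "",
                    c("family_accession", "clan_accession")]
  }
  level <- if (!is.null(clan_map) && nrow(clan_map)) "clan" else "family"
  pm_fam <- build_presence(vet$kept, assignments, level = "family",
                           columns = "domain")
  pm_unit <- if (level == "clan") {
    build_presence(vet$kept, assignments, level = "clan",
                   columns = "domain", clan_map = clan_map)
  } else pm_fam
  venn <- venn_partition(pm_unit)
  inter <- interdomain_units(pm_unit)
  write_presence(pm_fam, file.path(out_dir, "presence_domain_family.tsv"))
  jsonlite::write_json(
    list(region_counts = as.list(venn$region_counts),
         n_units = venn$n_units,
         single_set_fraction = venn$single_set_fraction,
         interdomain = inter$interdomain,
         virus_sharing = inter$virus_sharing),
    file.path(out_dir, "venn.json"), auto_unbox = TRUE, digits = NA)
  thr <- config$broad_threshold %||% 0.5
  broad <- list()
  rates <- list()
  for (d in intersect(c("Archaea", "Bacteria", "Eukaryota"),
                      names(index$domain_ids))) {
    divs <- domain_divisions(index, d)
    if (length(divs) == 0L) next
    pm_d <- build_presence(vet$kept, assignments, level = level,
                           columns = "division", domain = d,
                           division_levels = divs, clan_map = clan_map)
    calls <- broad_distribution(pm_d, threshold = thr, domain = d)
    broad[[d]] <- calls
    if (any(calls$divisions_present > 0L)) {
      rates[[d]] <- broad_distribution_rate(calls)
    }
  }
  if (length(broad)) {
    utils::write.table(do.call(rbind, broad),
                       file.path(out_dir, "broad_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  counts$units <- length(pm_unit$unit_ids)
  counts$interdomain <- length(inter$interdomain)
  stages <- c(stages, "census")

  # stage: phylogenetic mapping (optional)
  nominations <- NULL
  if (!is.null(config$tree)) {
    st <- read_species_tree(config$tree, config$tip_taxa,
                            outgroup = config$outgroup)
    if (!is.null(st$tip_taxa)) {
      taxon_tip <- stats::setNames(names(st$tip_taxa),
                                   as.character(st$tip_taxa))
      pres_tips <- lapply(split(vet$kept$taxon_id,
                                vet$kept$family_accession), function(t) {
        unname(stats::na.omit(taxon_tip[as.character(unique(t))]))
      })
      pres_tips <- pres_tips[lengths(pres_tips) > 0L]
      nominations <- nominate_candidates(
        st$tree, pres_tips,
        domain_root = config$domain_root,
        max_losses = config$max_losses,
        clade_coverage = config$clade_coverage %||% 0.5)
      write_reconstructions(nominations,
                            file.path(out_dir, "reconstructions.tsv"))
      stages <- c(stages, "phylo_mapping")
    }
  }

  # stage: discovery (optional)
  disc <- NULL
  if (!identical(config$discovery, FALSE)) {
    fam_dates <- vapply(seq_len(nrow(fam)), function(i) {
      lit <- if ("date_refs" %in% names(fam)) {
        strsplit(fam$date_refs[i], ";")[[1L]]
      } else character(0)
      rec <- ann$date[ann$family_accession == fam$family_accession[i]]
      as.character(oldest_date(lit, rec))
    }, character(1))
    names(fam_dates) <- fam$family_accession
    cls <- domain_count_class(pm_fam)
    disc <- discovery_curve(fam_dates[!is.na(fam_dates)], cls)
    write_discovery_curve(disc, file.path(out_dir, "discovery_curve.tsv"))
    stages <- c(stages, "discovery")
  }

  # stage: report
  bias <- bias_profile(vet$kept, assignments)
  utils::write.table(bias$counts, file.path(out_dir, "bias_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  input_files <- unlist(config[c("annotations", "families", "taxonomy_nodes",
                                 "taxonomy_names", "clans", "tree",
                                 "tip_taxa")])
  manifest <- list(
    package = "rnacensus",
    version = as.character(utils::packageVersion("rnacensus")),
    stages = c(stages, "report"),
    inputs = as.list(tools::md5sum(input_files[file.exists(input_files)])),
    parameters = list(margin = vcfg$margin, broad_threshold = thr,
                      clade_coverage = config$clade_coverage %||% 0.5),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(assignments = assignments, vet_report = vet$report,
                 presence_domain = pm_unit, venn = venn,
                 interdomain = inter, broad = broad, broad_rates = rates,
                 bias = bias, nominations = nominations, discovery = disc,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
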