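#' Load a taxonomy from NCBI-dump-dialect or simple TSV tables
#'
#' Builds a validated [taxonomy_index] from either the two-file NCBI taxonomy
#' dump layout (pipe-delimited `nodes.dmp` / `names.dmp` field order) or a
#' simplified single-file 4-column TSV (`taxon_id`, `parent_id`, `rank`,
#' `name`). The dialect is auto-detected from the delimiter of the first line.
#'
#' The configuration attaches the biological interpretation to the bare
#' hierarchy: which named nodes are the top-level sets (Archaea, Bacteria,
#' Eukaryota, Viruses), which taxa are merged into others for division
#' accounting (e.g. annotations classified under Thaumarchaeota counted with
#' Crenarchaeota, as the NCBI database did before the phylum was recognised),
#' and which eukaryote taxa anchor the Adl-style supergroups used as
#' eukaryotic "major divisions".
#'
#' @param nodes_file Path to `nodes.dmp` or the 4-column TSV.
#' @param names_file Path to `names.dmp`; ignored (may be `NULL`) for the TSV
#'   dialect, which carries names inline.
#' @param config A list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{domains}{named character vector/list mapping domain label
#'       (`Archaea`, `Bacteria`, `Eukaryota`, `Viruses`) to the scientific
#'       name of its node. Defaults to the labels themselves.}
#'     \item{merges}{named vector/list mapping a scientific name (or taxon id)
#'       to the name/id it is merged into for division accounting.}
#'     \item{supergroups}{named vector/list mapping a eukaryote scientific
#'       name (or taxon id) to its supergroup label.}
#'   }
#' @return An object of class `taxonomy_index`.
#' @seealso [assign_division()], [domain_divisions()]
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "taxon_id\tparent_id\trank\tname",
#'   "1\t1\tno rank\troot",
#'   "2\t1\tsuperkingdom\tBacteria",
#'   "3\t2\tphylum\tProteobacteria",
#'   "4\t3\tspecies\tEscherichia coli"), tf)
#' idx <- load_taxonomy(tf, config = list(domains = c(Bacteria = "Bacteria")))
#' assign_division(4L, idx)
#' @export
load_taxonomy <- function(nodes_file, names_file = NULL, config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  first <- readLines(nodes_file, n = 1L)
  if (grepl("\t\\|", first)) {
    nodes <- .read_dmp(nodes_file)
    if (is.null(names_file)) {
      stop("NCBI dump dialect requires a names table (names.dmp)")
    }
    nm <- .read_dmp(names_file)
    # names.dmp: tax_id | name_txt | unique name | name class
    sci <- nm[nm[[4L]] == "scientific name", , drop = FALSE]
    tab <- data.frame(
      taxon_id  = as.integer(nodes[[1L]]),
      parent_id = as.integer(nodes[[2L]]),
      rank      = as.character(nodes[[3L]]),
      name      = sci[[2L]][match(as.integer(nodes[[1L]]), as.integer(sci[[1L]]))],
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.delim(nodes_file, header = TRUE, sep = "\t",
                             quote = "", stringsAsFactors = FALSE)
    need <- c("taxon_id", "parent_id", "rank", "name")
    if (!all(need %in% names(tab))) {
      stop("TSV taxonomy must have columns: ", paste(need, collapse = ", "))
    }
    tab <- tab[need]
    tab$taxon_id <- as.integer(tab$taxon_id)
    tab$parent_id <- as.integer(tab$parent_id)
  }
  build_taxonomy_index(tab, config)
}

# NCBI dump lines look like "1\t|\t1\t|\tno rank\t|\t..."; strip the
# trailing "\t|" then split on the "\t|\t" field separator.
.read_dmp <- function(path) {
  lines <- readLines(path)
  lines <- sub("\t\\|$", "", lines)
  parts <- strsplit(lines, "\t\\|\t")
  n <- max(lengths(parts))
  cols <- lapply(seq_len(n), function(i) {
    vapply(parts, function(p) if (length(p) >= i) p[[i]] else NA_character_,
           character(1))
  })
  as.data.frame(cols, col.names = paste0("V", seq_len(n)),
                stringsAsFactors = FALSE, optional = TRUE)
}

#' Construct a taxonomy index from an in-memory node table
#'
#' Lower-level constructor behind [load_taxonomy()]; useful for programmatic
#' fixtures. Validates structure: unique taxon ids, exactly one root (a node
#' that is its own parent), every parent chain terminating at the root, the
#' configured domain nodes resolving, being distinct and lying below the root,
#' and merge targets being valid non-merged nodes.
#'
#' @param tab data.frame with columns `taxon_id`, `parent_id`, `rank`, `name`.
#' @param config See [load_taxonomy()].
#' @return A `taxonomy_index`.
#' @export
build_taxonomy_index <- function(tab, config = list()) {
  if (anyDuplicated(tab$taxon_id)) {
    stop("structural error: duplicate taxon_id in nodes table")
  }
  ids <- tab$taxon_id
  parent <- tab$parent_id
  names(parent) <- as.character(ids)
  is_root <- ids == parent
  if (sum(is_root) != 1L) {
    stop("structural error: taxonomy must contain exactly one root ",
         "(a node that is its own parent); found ", sum(is_root))
  }
  root_id <- ids[is_root]
  if (!all(parent %in% ids)) {
    bad <- setdiff(unique(parent), ids)
    stop("structural error: parent id(s) absent from nodes table: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  # acyclicity: walk each node at most |nodes| steps
  depth_cap <- length(ids) + 1L
  for (id in ids) {
    cur <- id
    steps <- 0L
    while (cur != root_id) {
      cur <- parent[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > depth_cap) {
        stop("structural error: cycle detected in parent chain at taxon ", id)
      }
    }
  }

  name_of <- tab$name
  names(name_of) <- as.character(ids)
  rank_of <- tab$rank
  names(rank_of) <- as.character(ids)

  dom_cfg <- config$domains
  if (is.null(dom_cfg)) {
    dom_cfg <- c(Archaea = "Archaea", Bacteria = "Bacteria",
                 Eukaryota = "Eukaryota", Viruses = "Viruses")
  }
  dom_cfg <- unlist(dom_cfg)
  domain_ids <- integer(0)
  for (lab in names(dom_cfg)) {
    hit <- ids[!is.na(name_of) & name_of == dom_cfg[[lab]]]
    if (length(hit) == 0L) {
      if (!is.null(config$domains)) {
        stop("configuration error: domain name '", dom_cfg[[lab]],
             "' not found in taxonomy names")
      }
      next  # default config: silently skip domains absent from a toy dump
    }
    domain_ids[lab] <- hit[1L]
  }
  if (anyDuplicated(domain_ids)) {
    stop("configuration error: domain nodes are not distinct")
  }

  resolve <- function(x) {
    # accept either a taxon id or a scientific name
    if (grepl("^[0-9]+$", x)) {
      v <- as.integer(x)
      if (v %in% ids) v else NA_integer_
    } else {
      hit <- ids[!is.na(name_of) & name_of == x]
      if (length(hit)) hit[1L] else NA_integer_
    }
  }

  merge_map <- integer(0)
  if (!is.null(config$merges)) {
    mm <- unlist(config$merges)
    for (from in names(mm)) {
      fi <- resolve(from)
      ti <- resolve(mm[[from]])
      if (is.na(fi) || is.na(ti)) {
        warning("merge entry not resolved, skipped: ", from, " -> ", mm[[from]])
        next
      }
      merge_map[as.character(fi)] <- ti
    }
    chained <- as.character(merge_map) %in% names(merge_map)
    if (any(chained)) {
      stop("configuration error: chained merge targets: ",
           paste(names(merge_map)[chained], collapse = ", "))
    }
  }

  supergroup_map <- character(0)
  if (!is.null(config$supergroups)) {
    sg <- unlist(config$supergroups)
    for (from in names(sg)) {
      fi <- resolve(from)
      if (is.na(fi)) {
        warning("supergroup entry not resolved, skipped: ", from)
        next
      }
      supergroup_map[as.character(fi)] <- sg[[from]]
    }
  }

  idx <- structure(list(
    nodes = tab,
    parent = parent,
    name = name_of,
    rank = rank_of,
    root_id = root_id,
    domain_ids = domain_ids,
    merge_map = merge_map,
    supergroup_map = supergroup_map
  ), class = "taxonomy_index")

  for (lab in names(domain_ids)) {
    if (domain_ids[[lab]] == root_id ||
        !.is_descendant(idx, domain_ids[[lab]], root_id)) {
      stop("configuration error: domain node '", lab,
           "' is not a proper descendant of the root")
    }
  }
  idx
}

#' @export
print.taxonomy_index <- function(x, ...) {
  cat("taxonomy_index:", nrow(x$nodes), "nodes; root =", x$root_id, "\n")
  cat("  domains:",
      paste(sprintf("%s=%d", names(x$domain_ids), x$domain_ids),
            collapse = ", "), "\n")
  if (length(x$merge_map)) cat("  merges:", length(x$merge_map), "\n")
  if (length(x$supergroup_map)) {
    cat("  supergroup anchors:", length(x$supergroup_map), "\n")
  }
  invisible(x)
}

.is_descendant <- function(idx, id, anc) {
  cur <- id
  while (cur != idx$root_id) {
    cur <- idx$parent[[as.character(cur)]]
    if (cur == anc) return(TRUE)
  }
  anc == idx$root_id
}

# parent chain from id up to (and including) the root; id itself first
.chain <- function(idx, id) {
  out <- id
  cur <- id
  while (cur != idx$root_id) {
    cur <- idx$parent[[as.character(cur)]]
    out <- c(out, cur)
  }
  out
}

#' Resolve taxa to domain and major within-domain division
#'
#' Walks each taxon's parent chain. The domain is the unique configured
#' top-level node on the chain. The division is domain-dependent: for Archaea
#' and Bacteria it is the immediate child of the domain node on the chain (the
#' NCBI "top-level classification", typically a phylum); for Eukaryota it is
#' the first supergroup anchor encountered walking up the chain; for Viruses
#' the division is simply `"Viruses"`. Merge rules are applied both to the
#' queried id and to the resolved division node, so a taxon filed under a
#' merged phylum is counted with the merge target.
#'
#' Unknown or retired taxon ids never raise: they resolve to
#' `UNASSIGNED`/`UNASSIGNED`, so a multi-million-row run degrades gracefully
#' and the caller can audit the unassigned count.
#'
#' @param taxon_ids Integer vector of taxon ids (unknown ids allowed).
#' @param index A [taxonomy_index][load_taxonomy].
#' @return data.frame with columns `taxon_id`, `domain`, `division`;
#'   `UNASSIGNED` marks unresolved levels, and `division` is `UNASSIGNED`
#'   whenever `domain` is.
#' @export
assign_division <- function(taxon_ids, index) {
  stopifnot(inherits(index, "taxonomy_index"))
  taxon_ids <- as.integer(taxon_ids)
  uniq <- unique(taxon_ids)
  dom <- character(length(uniq))
  div <- character(length(uniq))
  for (i in seq_along(uniq)) {
    a <- .assign_one(uniq[i], index)
    dom[i] <- a[[1L]]
    div[i] <- a[[2L]]
  }
  m <- match(taxon_ids, uniq)
  data.frame(taxon_id = taxon_ids, domain = dom[m], division = div[m],
             stringsAsFactors = FALSE)
}

UNASSIGNED <- "UNASSIGNED"

.assign_one <- function(id, idx) {
  key <- as.character(id)
  if (key %in% names(idx$merge_map)) {
    id <- idx$merge_map[[key]]
    key <- as.character(id)
  }
  if (!(key %in% names(idx$parent))) {
    return(c(UNASSIGNED, UNASSIGNED))
  }
  chain <- .chain(idx, id)
  hit <- match(idx$domain_ids, chain)
  if (all(is.na(hit))) {
    return(c(UNASSIGNED, UNASSIGNED))
  }
  w <- which(!is.na(hit))[1L]
  dom_lab <- names(idx$domain_ids)[w]
  pos <- hit[w]
  if (dom_lab == "Viruses") {
    return(c(dom_lab, "Viruses"))
  }
  if (dom_lab == "Eukaryota") {
    # first supergroup anchor walking up from the taxon itself
    for (node in chain) {
      k <- as.character(node)
      if (k %in% names(idx$supergroup_map)) {
        return(c(dom_lab, idx$supergroup_map[[k]]))
      }
    }
    return(c(dom_lab, UNASSIGNED))
  }
  # Archaea / Bacteria: child of the domain node on this chain
  if (pos == 1L) {
    return(c(dom_lab, UNASSIGNED))  # queried the domain node itself
  }
  div_id <- chain[pos - 1L]
  dk <- as.character(div_id)
  if (dk %in% names(idx$merge_map)) {
    div_id <- idx$merge_map[[dk]]
  }
  c(dom_lab, idx$name[[as.character(div_id)]])
}

#' Major divisions of one domain
#'
#' The division columns a presence matrix should carry for a domain: for
#' Archaea/Bacteria the scientific names of the domain node's children
#' (merge-map keys collapsed into their targets), for Eukaryota the distinct
#' configured supergroup labels, for Viruses the single label `"Viruses"`.
#'
#' @param index A `taxonomy_index`.
#' @param domain One of `"Archaea"`, `"Bacteria"`, `"Eukaryota"`, `"Viruses"`.
#' @return Character vector of division labels, sorted.
#' @export
domain_divisions <- function(index, domain) {
  stopifnot(inherits(index, "taxonomy_index"))
  if (!domain %in% names(index$domain_ids)) {
    stop("configuration error: domain '", domain, "' not in taxonomy index")
  }
  if (domain == "Viruses") return("Viruses")
  if (domain == "Eukaryota") {
    return(sort(unique(unname(index$supergroup_map))))
  }
  dom_id <- index$domain_ids[[domain]]
  kids <- index$nodes$taxon_id[index$nodes$parent_id == dom_id &
                               index$nodes$taxon_id != dom_id]
  kids <- vapply(kids, function(k) {
    ck <- as.character(k)
    if (ck %in% names(index$merge_map)) index$merge_map[[ck]] else k
  }, integer(1))
  sort(unique(index$name[as.character(kids)]))
}

#' Write a taxon assignment table to TSV
#'
#' @param assignments data.frame from [assign_division()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
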