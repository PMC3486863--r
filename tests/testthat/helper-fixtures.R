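# Programmatic fixtures shared across the test files.

# 6-node toy taxonomy: root; Bacteria > Proteobacteria > E. coli;
# Archaea > Euryarchaeota.
toy_tax_tab <- function() {
  data.frame(
    taxon_id  = 1:6,
    parent_id = c(1L, 1L, 2L, 3L, 1L, 5L),
    rank      = c("no rank", "superkingdom", "phylum", "species",
                  "superkingdom", "phylum"),
    name      = c("root", "Bacteria", "Proteobacteria", "Escherichia coli",
                  "Archaea", "Euryarchaeota"),
    stringsAsFactors = FALSE
  )
}

toy_index <- function(extra_config = list()) {
  cfg <- utils::modifyList(
    list(domains = list(Bacteria = "Bacteria", Archaea = "Archaea")),
    extra_config)
  build_taxonomy_index(toy_tax_tab(), cfg)
}

# 8-node eukaryote chain with one supergroup anchor at the phylum level:
# root > Eukaryota > Opisthokonta(anchor is deeper) ...
euk_tax_index <- function() {
  tab <- data.frame(
    taxon_id  = 1:8,
    parent_id = c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L),
    rank      = c("no rank", "superkingdom", "kingdom", "subkingdom",
                  "phylum", "class", "genus", "species"),
    name      = c("root", "Eukaryota", "Fungi", "Dikarya", "Ascomycota",
                  "Saccharomycetes", "Saccharomyces",
                  "Saccharomyces cerevisiae"),
    stringsAsFactors = FALSE
  )
  build_taxonomy_index(tab, list(
    domains = list(Eukaryota = "Eukaryota"),
    supergroups = list(Ascomycota = "Opisthokonta")
  ))
}

# Annotation row builder.
ann_row <- function(fam, taxon, bits, evidence = "UNTESTED",
                    seq = paste0("S", taxon, fam, round(bits))) {
  data.frame(seq_accession = seq, family_accession = fam,
             taxon_id = as.integer(taxon), bitscore = bits,
             evidence = evidence, date = NA_character_,
             stringsAsFactors = FALSE)
}

fam_row <- function(acc, cutoff, clan = "", dates = "2000-01") {
  data.frame(family_accession = acc, name = acc, clan_accession = clan,
             seed_cutoff = cutoff, functional_path = "Gene;sRNA",
             date_refs = dates, stringsAsFactors = FALSE)
}

# Construct a presence_matrix directly from a logical matrix (support = 1s).
pm_from_logical <- function(present, level = "family") {
  support <- matrix(0L, nrow(present), ncol(present),
                    dimnames = dimnames(present))
  support[present] <- 1L
  structure(list(present = present, support = support,
                 unit_ids = rownames(present),
                 column_ids = colnames(present), level = level),
            class = "presence_matrix")
}

random_domain_pm <- function(n_units, p = 0.4) {
  doms <- c("Archaea", "Bacteria", "Eukaryota", "Viruses")
  m <- matrix(stats::runif(n_units * 4) < p, n_units, 4,
              dimnames = list(sprintf("U%03d", seq_len(n_units)), doms))
  pm_from_logical(m)
}

# Independent Dollo oracle: brute-force minimisation of the loss count over
# every admissible gain placement (any node whose clade contains the whole
# presence set), counting losses by top-down recursion.
oracle_dollo_losses <- function(tree, presence) {
  ti <- rnacensus:::.tree_index(tree)
  pres <- ti$tree$tip.label %in% presence
  cnt <- as.integer(ti$D %*% pres)
  k <- sum(pres)
  cands <- which(cnt == k)
  count_losses <- function(v) {
    kids <- ti$children[[v]]
    if (length(kids) == 0L) return(0L)
    s <- 0L
    for (ch in kids) {
      s <- s + if (cnt[ch] == 0L) 1L else count_losses(ch)
    }
    s
  }
  min(vapply(cands, count_losses, integer(1)))
}

# Small default simulation used by several tests (fast).
small_sim <- function(seed = 1, ...) {
  simulate_census_data(sim_params(
    seed = seed, divisions_per_domain = 4L, taxa_per_division = 4L,
    n_families = 60L, ...))
}
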