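#' Parameters for the Rfam-like simulator
#'
#' Bundles and validates the knobs of [simulate_census_data()]. Defaults
#' describe a modest but structured census: three cellular domains plus a
#' viral set, six major divisions per domain (the eukaryote supergroup scheme
#' recognises six top groups), eight sampled taxa per division, and a family
#' class mix dominated by domain-specific families with small
#' vertically-inherited and horizontally-transferred minorities, echoing the
#' strongly domain-restricted repertoires seen in curated RNA family data.
#'
#' @param seed Integer RNG seed; the whole simulation is reproducible from it.
#' @param divisions_per_domain Major divisions per cellular domain.
#' @param taxa_per_division Sampled taxa (tree tips) per division.
#' @param n_families Number of RNA families to simulate.
#' @param class_mix Named fractions over `DOMAIN_SPECIFIC`, `LUCA_VERTICAL`,
#'   `HGT_INTERDOMAIN`; must sum to 1. When `hgt_rate` is 0 the HGT share is
#'   folded into `DOMAIN_SPECIFIC` (a transfer rate of zero cannot produce an
#'   interdomain pattern).
#' @param loss_prob Per-lineage Dollo loss probability on each branch below a
#'   family's gain node.
#' @param hgt_rate Expected cross-domain transfer events per HGT family
#'   (each such family gets at least one event when the rate is positive).
#' @param fp_rate Expected false-positive annotations per family, in \[0, 1\].
#' @param cutoff_range Range of the per-family curated seed bitscore cutoff.
#' @param margin Width in bits of the marginal window; false hits score
#'   uniformly inside `[cutoff, cutoff + margin)`, true hits exponentially
#'   above `cutoff + margin`, so the margin filter separates them exactly at
#'   default noise.
#' @param true_offset_mean Mean of the exponential bitscore offset of true
#'   hits above `cutoff + margin`.
#' @param sampling_bias Concentration of annotation sampling across a
#'   domain's divisions: 0 = uniform, fully sampled; larger values skew
#'   detection towards few divisions (Dirichlet with concentration
#'   `1/sampling_bias`).
#' @param root_gain_prob Probability that a domain-specific family's gain sits
#'   at the domain root (otherwise a uniformly chosen node in the domain
#'   clade, so most families are narrow).
#' @param viruses Include a viral taxon set (no tree placement).
#' @param viral_taxa Number of viral taxa.
#' @param clan_frac Fraction of families grouped pairwise into clans.
#' @param domain_weights Sampling weights of the home domain of
#'   domain-specific and HGT families; default proportional to the published
#'   per-domain family totals (Archaea 69, Bacteria 223, Eukaryota 826) plus
#'   a small viral share.
#' @param fp_misannotated_frac Fraction of false positives flagged
#'   `MISANNOTATED` (caught by taxonomic re-confirmation) rather than
#'   `UNTESTED`.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       divisions_per_domain = 6L,
                       taxa_per_division = 8L,
                       n_families = 200L,
                       class_mix = c(DOMAIN_SPECIFIC = 0.90,
                                     LUCA_VERTICAL = 0.05,
                                     HGT_INTERDOMAIN = 0.05),
                       loss_prob = 0.05,
                       hgt_rate = 1,
                       fp_rate = 0.1,
                       cutoff_range = c(20, 50),
                       margin = 10,
                       true_offset_mean = 15,
                       sampling_bias = 0,
                       root_gain_prob = 0.15,
                       viruses = TRUE,
                       viral_taxa = 8L,
                       clan_frac = 0.1,
                       domain_weights = c(Archaea = 69, Bacteria = 223,
                                          Eukaryota = 826, Viruses = 30),
                       fp_misannotated_frac = 0.25) {
  p <- list(seed = as.integer(seed),
            divisions_per_domain = as.integer(divisions_per_domain),
            taxa_per_division = as.integer(taxa_per_division),
            n_families = as.integer(n_families),
            class_mix = class_mix, loss_prob = loss_prob,
            hgt_rate = hgt_rate, fp_rate = fp_rate,
            cutoff_range = cutoff_range, margin = margin,
            true_offset_mean = true_offset_mean,
            sampling_bias = sampling_bias,
            root_gain_prob = root_gain_prob,
            viruses = isTRUE(viruses), viral_taxa = as.integer(viral_taxa),
            clan_frac = clan_frac, domain_weights = domain_weights,
            fp_misannotated_frac = fp_misannotated_frac)
  if (p$divisions_per_domain < 1L || p$taxa_per_division < 1L ||
      p$n_families < 1L) {
    stop("configuration error: counts must be >= 1")
  }
  if (p$divisions_per_domain * p$taxa_per_division < 2L) {
    stop("configuration error: each domain needs at least two taxa")
  }
  need <- c("DOMAIN_SPECIFIC", "LUCA_VERTICAL", "HGT_INTERDOMAIN")
  if (!all(need %in% names(p$class_mix)) ||
      abs(sum(p$class_mix) - 1) > 1e-8) {
    stop("configuration error: class_mix must be named over ",
         paste(need, collapse = ", "), " and sum to 1")
  }
  for (f in c("loss_prob", "fp_rate", "fp_misannotated_frac",
              "root_gain_prob")) {
    if (p[[f]] < 0 || p[[f]] > 1) {
      stop("configuration error: ", f, " must lie in [0, 1]")
    }
  }
  if (p$hgt_rate < 0 || p$sampling_bias < 0) {
    stop("configuration error: rates must be non-negative")
  }
  structure(p, class = "sim_params")
}

ADL_SUPERGROUPS <- c("Opisthokonta", "Amoebozoa", "Archaeplastida",
                     "Chromalveolata", "Excavata", "Rhizaria")

# -- taxonomy construction ---------------------------------------------------

.sim_taxonomy <- function(p) {
  doms <- c("Archaea", "Bacteria", "Eukaryota")
  if (p$viruses) doms <- c(doms, "Viruses")
  rows <- list(data.frame(taxon_id = 1L, parent_id = 1L, rank = "no rank",
                          name = "root"))
  next_id <- 2L
  dom_ids <- integer(0)
  for (d in doms) {
    dom_ids[d] <- next_id
    rows <- c(rows, list(data.frame(taxon_id = next_id, parent_id = 1L,
                                    rank = "superkingdom", name = d)))
    next_id <- next_id + 1L
  }
  nd <- p$divisions_per_domain
  div_names <- list(
    Archaea = sprintf("Arch_phylum_%02d", seq_len(nd)),
    Bacteria = sprintf("Bact_phylum_%02d", seq_len(nd)),
    Eukaryota = if (nd <= length(ADL_SUPERGROUPS)) {
      ADL_SUPERGROUPS[seq_len(nd)]
    } else {
      c(ADL_SUPERGROUPS, sprintf("Euk_supergroup_%02d",
                                 seq_len(nd - length(ADL_SUPERGROUPS))))
    }
  )
  taxa <- list()   # per cellular division: taxon ids and names
  supergroups <- character(0)
  for (d in c("Archaea", "Bacteria", "Eukaryota")) {
    for (j in seq_len(nd)) {
      div_id <- next_id
      next_id <- next_id + 1L
      rank <- if (d == "Eukaryota") "supergroup" else "phylum"
      rows <- c(rows, list(data.frame(taxon_id = div_id,
                                      parent_id = dom_ids[[d]],
                                      rank = rank,
                                      name = div_names[[d]][j])))
      if (d == "Eukaryota") supergroups[div_names[[d]][j]] <- div_names[[d]][j]
      sp_ids <- next_id:(next_id + p$taxa_per_division - 1L)
      next_id <- next_id + p$taxa_per_division
      sp_names <- sprintf("%s_sp%02d", div_names[[d]][j],
                          seq_len(p$taxa_per_division))
      rows <- c(rows, list(data.frame(taxon_id = sp_ids, parent_id = div_id,
                                      rank = "species", name = sp_names)))
      taxa[[paste0(d, "/", div_names[[d]][j])]] <-
        data.frame(taxon_id = sp_ids, name = sp_names, domain = d,
                   division = div_names[[d]][j], stringsAsFactors = FALSE)
    }
  }
  viral <- NULL
  if (p$viruses) {
    v_ids <- next_id:(next_id + p$viral_taxa - 1L)
    next_id <- next_id + p$viral_taxa
    v_names <- sprintf("Virus_sp%02d", seq_len(p$viral_taxa))
    rows <- c(rows, list(data.frame(taxon_id = v_ids,
                                    parent_id = dom_ids[["Viruses"]],
                                    rank = "species", name = v_names)))
    viral <- data.frame(taxon_id = v_ids, name = v_names,
                        domain = "Viruses", division = "Viruses",
                        stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  config <- list(
    domains = as.list(stats::setNames(doms, doms)),
    supergroups = as.list(supergroups)
  )
  list(tab = tab, config = config,
       index = build_taxonomy_index(tab, config),
       taxa = taxa, viral = viral)
}

# -- species tree ------------------------------------------------------------

# pectinate (caterpillar) newick over tip labels, division root labelled
.caterpillar <- function(tips, label) {
  s <- tips[1L]
  if (length(tips) > 1L) {
    for (t in tips[-1L]) s <- paste0("(", s, ",", t, ")")
  }
  paste0(s, label)
}

# sample from a vector of any length (sample() treats scalars as 1:n)
.resample <- function(x, size = 1L, ...) x[sample.int(length(x), size, ...)]

.sim_tree <- function(tax) {
  dom_parts <- character(0)
  for (d in c("Archaea", "Bacteria", "Eukaryota")) {
    keys <- grep(paste0("^", d, "/"), names(tax$taxa), value = TRUE)
    divs <- vapply(keys, function(k) {
      tips <- tax$taxa[[k]]$name
      if (length(tips) == 1L) tips
      else .caterpillar(tips, paste0("DIV_", tax$taxa[[k]]$division[1L]))
    }, character(1))
    if (length(divs) > 1L) {
      part <- divs[1L]
      for (x in divs[-1L]) part <- paste0("(", part, ",", x, ")")
      dom_parts[d] <- paste0(part, "DOM_", d)
    } else {
      # single division: the domain root coincides with the division root
      dom_parts[d] <- paste0(sub("DIV_[A-Za-z0-9_]*$", "", divs[1L]),
                             "DOM_", d)
    }
  }
  nwk <- paste0("((", dom_parts[["Archaea"]], ",", dom_parts[["Bacteria"]],
                ")PROK,", dom_parts[["Eukaryota"]], ")ROOT;")
  tree <- ape::read.tree(text = nwk)
  tip_taxa <- integer(0)
  for (k in names(tax$taxa)) {
    tip_taxa[tax$taxa[[k]]$name] <- tax$taxa[[k]]$taxon_id
  }
  list(tree = tree, tip_taxa = tip_taxa[tree$tip.label])
}

# -- gain/loss machinery -----------------------------------------------------

# Simulate Dollo losses below a gain node; returns surviving tip indices and
# the number of loss events (maximal pruned subtrees).
.sim_losses <- function(ti, gain, loss_prob) {
  tips_under <- which(ti$D[gain, ])
  if (loss_prob <= 0) return(list(tips = tips_under, n_events = 0L))
  po <- ti$postorder
  for (attempt in 1:50) {
    lost <- logical(ti$M)
    n_events <- 0L
    u <- stats::runif(nrow(po))
    under <- ti$A[gain, ]
    for (i in rev(seq_len(nrow(po)))) {   # preorder: parent before child
      v <- po[i, 2L]
      if (!under[v] || v == gain) next
      if (lost[po[i, 1L]]) {
        lost[v] <- TRUE
      } else if (u[i] < loss_prob) {
        lost[v] <- TRUE
        n_events <- n_events + 1L
      }
    }
    surv <- tips_under[!lost[tips_under]]
    if (length(surv) > 0L) {
      return(list(tips = surv, n_events = n_events))
    }
  }
  list(tips = tips_under, n_events = 0L)   # loss pattern kept feasible
}

# -- the simulator -----------------------------------------------------------

#' Simulate an Rfam-like census dataset with known ground truth
#'
#' Generates a taxonomy (NCBI-dialect hierarchy of domains, divisions and
#' species), a rooted species tree over the cellular taxa (caterpillar
#' divisions joined balanced within and across domains), and annotation and
#' family metadata tables produced by an explicit evolutionary model: each
#' family gains once on the tree (at the global root for `LUCA_VERTICAL`
#' families, inside one domain otherwise), loses descendant lineages
#' independently with `loss_prob`, and — for `HGT_INTERDOMAIN` families —
#' transfers into nodes of other domains. Observed annotations carry
#' bitscores from the configured model, false positives fall in the marginal
#' window below `cutoff + margin`, and per-division detection can be skewed
#' by `sampling_bias`. Everything is reproducible from `params$seed`.
#'
#' @param params A [sim_params()].
#' @return Object of class `rna_census_sim`: list with `taxonomy_tab`,
#'   `taxonomy_config`, `index` (a `taxonomy_index`), `tree`, `tip_taxa`,
#'   `annotations`, `families`, `clan_map`, `truth` (per-family class,
#'   domains, gain node, loss/transfer counts), and `params`.
#' @export
simulate_census_data <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)

  tax <- .sim_taxonomy(p)
  tr <- .sim_tree(tax)
  ti <- .tree_index(tr$tree)
  labs <- .node_labels(ti)
  dom_node <- c(Archaea = match("DOM_Archaea", labs),
                Bacteria = match("DOM_Bacteria", labs),
                Eukaryota = match("DOM_Eukaryota", labs))
  root_node <- match("ROOT", labs)

  # taxon lookup for tree tips
  tip_taxon <- tr$tip_taxa
  all_taxa <- do.call(rbind, c(tax$taxa, list(tax$viral)))

  # class assignment
  mix <- p$class_mix
  if (p$hgt_rate == 0) {
    mix["DOMAIN_SPECIFIC"] <- mix["DOMAIN_SPECIFIC"] + mix["HGT_INTERDOMAIN"]
    mix["HGT_INTERDOMAIN"] <- 0
  }
  classes <- sample(names(mix), p$n_families, replace = TRUE, prob = mix)

  cell_w <- p$domain_weights[c("Archaea", "Bacteria", "Eukaryota")]
  fam_acc <- sprintf("SF%05d", seq_len(p$n_families))
  cutoffs <- round(stats::runif(p$n_families, p$cutoff_range[1L],
                                p$cutoff_range[2L]), 1L)
  fun_paths <- sample(c("Gene;rRNA", "Gene;tRNA", "Gene;sRNA",
                        "Gene;sRNA;snoRNA;CD-box", "Gene;sRNA;snoRNA;HACA-box",
                        "Cis-reg;riboswitch", "Cis-reg;leader",
                        "Gene;ribozyme", "Gene;sRNA;miRNA", "Gene;CRISPR"),
                      p$n_families, replace = TRUE)
  fam_year <- sample(1985:2009, p$n_families, replace = TRUE)
  fam_month <- sample(1:12, p$n_families, replace = TRUE)

  # per-domain division detection weights (sampling bias)
  nd <- p$divisions_per_domain
  det_p <- list()
  for (d in c("Archaea", "Bacteria", "Eukaryota")) {
    divs <- unique(all_taxa$division[all_taxa$domain == d])
    if (p$sampling_bias > 0) {
      g <- stats::rgamma(length(divs), shape = 1 / p$sampling_bias)
      w <- g / sum(g)
      det_p[[d]] <- stats::setNames(pmin(1, length(divs) * w), divs)
    } else {
      det_p[[d]] <- stats::setNames(rep(1, length(divs)), divs)
    }
  }
  if (p$viruses) det_p[["Viruses"]] <- c(Viruses = 1)

  truth_rows <- vector("list", p$n_families)
  ann_rows <- vector("list", p$n_families)

  for (i in seq_len(p$n_families)) {
    cl <- classes[i]
    hgt_events <- 0L
    hgt_targets <- character(0)
    if (cl == "LUCA_VERTICAL") {
      gain <- root_node
      home <- "LUCA"
    } else {
      pool <- if (cl == "DOMAIN_SPECIFIC" && p$viruses) {
        p$domain_weights
      } else {
        cell_w
      }
      home <- sample(names(pool), 1L, prob = pool)
      if (home == "Viruses") {
        gain <- NA_integer_
      } else if (stats::runif(1) < p$root_gain_prob) {
        gain <- dom_node[[home]]
      } else {
        gain <- .resample(which(ti$A[dom_node[[home]], ]))
      }
    }
    if (home == "Viruses") {
      nv <- nrow(tax$viral)
      k <- .resample(seq_len(nv))
      taxa_present <- sort(.resample(tax$viral$taxon_id, k))
      n_loss <- 0L
      gain_label <- "Viruses"
    } else {
      lr <- .sim_losses(ti, gain, p$loss_prob)
      pres_tips <- lr$tips
      n_loss <- lr$n_events
      gain_label <- labs[gain]
      if (cl == "HGT_INTERDOMAIN") {
        hgt_events <- if (p$hgt_rate > 0) {
          1L + stats::rpois(1L, max(0, p$hgt_rate - 1))
        } else 0L
        for (e in seq_len(hgt_events)) {
          target_dom <- .resample(setdiff(c("Archaea", "Bacteria",
                                            "Eukaryota"), home))
          tnode <- .resample(which(ti$A[dom_node[[target_dom]], ]))
          pres_tips <- union(pres_tips, which(ti$D[tnode, ]))
          hgt_targets <- c(hgt_targets, paste0(target_dom, ":", labs[tnode]))
        }
      }
      taxa_present <- sort(unname(tip_taxon[ti$tree$tip.label[pres_tips]]))
    }

    # observed annotations: detection thinned by division sampling weight
    meta <- all_taxa[match(taxa_present, all_taxa$taxon_id), , drop = FALSE]
    pdet <- mapply(function(dm, dv) det_p[[dm]][[dv]], meta$domain,
                   meta$division)
    detected <- stats::runif(length(taxa_present)) < pdet
    obs_taxa <- taxa_present[detected]
    n_ann_per <- 1L + stats::rpois(length(obs_taxa), 0.5)
    tax_rep <- rep(obs_taxa, n_ann_per)
    n_true <- length(tax_rep)
    scores <- cutoffs[i] + p$margin +
      stats::rexp(n_true, rate = 1 / p$true_offset_mean)
    yrs <- sample(fam_year[i]:2010, n_true, replace = TRUE)
    mos <- sample(1:12, n_true, replace = TRUE)
    fam_ann <- data.frame(
      family_accession = rep(fam_acc[i], n_true),
      taxon_id = tax_rep,
      bitscore = round(scores, 1L),
      evidence = rep("UNTESTED", n_true),
      date = sprintf("%04d-%02d", yrs, mos),
      stringsAsFactors = FALSE
    )

    # false positives: marginal-window hits in a foreign domain
    true_domains <- unique(meta$domain)
    if (cl == "HGT_INTERDOMAIN") {
      true_domains <- unique(c(true_domains,
                               sub(":.*$", "", hgt_targets), home))
    }
    n_fp <- stats::rbinom(1L, 1L, p$fp_rate)
    if (n_fp > 0L) {
      foreign <- all_taxa[!(all_taxa$domain %in% true_domains), , drop = FALSE]
      if (nrow(foreign) > 0L) {
        ft <- foreign[sample(nrow(foreign), n_fp, replace = TRUE), ,
                      drop = FALSE]
        ev <- ifelse(stats::runif(n_fp) < p$fp_misannotated_frac,
                     "MISANNOTATED", "UNTESTED")
        # floored to one decimal so rounding never lifts a false hit out of
        # the marginal window [cutoff, cutoff + margin)
        fp_ann <- data.frame(
          family_accession = rep(fam_acc[i], n_fp),
          taxon_id = ft$taxon_id,
          bitscore = floor((cutoffs[i] +
                              stats::runif(n_fp, 0, p$margin)) * 10) / 10,
          evidence = ev,
          date = sprintf("%04d-%02d", sample(fam_year[i]:2010, n_fp, TRUE),
                         sample(1:12, n_fp, TRUE)),
          stringsAsFactors = FALSE
        )
        fam_ann <- rbind(fam_ann, fp_ann)
      }
    }
    ann_rows[[i]] <- fam_ann
    truth_rows[[i]] <- data.frame(
      family_accession = fam_acc[i], class = cl,
      true_domains = paste(sort(true_domains), collapse = ";"),
      gain_node = gain_label, n_losses = n_loss,
      n_hgt_events = hgt_events,
      hgt_targets = paste(hgt_targets, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }

  annotations <- do.call(rbind, ann_rows)
  rownames(annotations) <- NULL
  annotations <- cbind(
    seq_accession = sprintf("SYN%07d", seq_len(nrow(annotations))),
    annotations, stringsAsFactors = FALSE
  )
  truth <- do.call(rbind, truth_rows)

  # clans: pair up same-domain domain-specific families
  clan_map <- data.frame(family_accession = character(0),
                         clan_accession = character(0))
  n_clan_fams <- 2L * floor(p$n_families * p$clan_frac / 2)
  if (n_clan_fams >= 2L) {
    ds <- which(classes == "DOMAIN_SPECIFIC")
    by_dom <- split(ds, truth$true_domains[ds])
    pairs <- list()
    for (g in by_dom) {
      g <- .resample(g, length(g))
      np <- floor(length(g) / 2)
      if (np > 0L) {
        for (j in seq_len(np)) {
          pairs[[length(pairs) + 1L]] <- g[c(2L * j - 1L, 2L * j)]
        }
      }
    }
    if (length(pairs)) {
      take <- utils::head(pairs, n_clan_fams %/% 2L)
      clan_map <- do.call(rbind, lapply(seq_along(take), function(j) {
        data.frame(family_accession = fam_acc[take[[j]]],
                   clan_accession = sprintf("CL%04d", j),
                   stringsAsFactors = FALSE)
      }))
    }
  }

  families <- data.frame(
    family_accession = fam_acc,
    name = paste0("synthetic RNA family ", seq_len(p$n_families)),
    clan_accession = clan_map$clan_accession[
      match(fam_acc, clan_map$family_accession)],
    seed_cutoff = cutoffs,
    functional_path = fun_paths,
    date_refs = sprintf("%04d-%02d", fam_year, fam_month),
    stringsAsFactors = FALSE
  )
  families$clan_accession[is.na(families$clan_accession)] <- ""

  structure(list(
    taxonomy_tab = tax$tab, taxonomy_config = tax$config, index = tax$index,
    tree = tr$tree, tip_taxa = tr$tip_taxa,
    annotations = annotations, families = families, clan_map = clan_map,
    truth = truth, params = p, detection = det_p
  ), class = "rna_census_sim")
}

#' @export
print.rna_census_sim <- function(x, ...) {
  cat("rna_census_sim: seed", x$params$seed, "-",
      nrow(x$truth), "families,", nrow(x$annotations), "annotations,",
      nrow(x$taxonomy_tab), "taxa\n")
  print(table(x$truth$class))
  invisible(x)
}

#' Write a simulated dataset to the on-disk dialects the pipeline reads
#'
#' Writes `nodes.tsv` (4-column taxonomy), `taxonomy_config.yaml`,
#' `tree.nwk`, `tip_taxa.tsv`, `annotations.tsv`, `families.tsv`,
#' `clans.tsv`, `truth.tsv` and `params.yaml` into `dir`. Byte-identical
#' across runs with the same seed.
#'
#' @param sim An `rna_census_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "rna_census_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(sim$taxonomy_tab, "nodes.tsv")
  yaml::write_yaml(sim$taxonomy_config, file.path(dir, "taxonomy_config.yaml"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  w(data.frame(tip = names(sim$tip_taxa), taxon_id = unname(sim$tip_taxa)),
    "tip_taxa.tsv")
  w(sim$annotations, "annotations.tsv")
  w(sim$families, "families.tsv")
  w(sim$clan_map, "clans.tsv")
  w(sim$truth, "truth.tsv")
  yaml::write_yaml(unclass(sim$params), file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Score census classification against simulation ground truth
#'
#' Infers each family's distribution class from a domain-level presence
#' matrix (3 domains of life occupied = `LUCA_VERTICAL`; 2 =
#' `HGT_INTERDOMAIN`; 1, or viruses only = `DOMAIN_SPECIFIC`; none =
#' `ABSENT`) and compares it to the simulator's truth labels.
#'
#' @param matrix Domain-level `presence_matrix` computed from the (possibly
#'   vetted) annotations, at family level.
#' @param truth The `truth` data.frame of an `rna_census_sim`.
#' @return List with `confusion` (truth x inferred table), `accuracy`
#'   (named vector per truth class present; `NA` never occurs since only
#'   present classes are reported), and `misclassified` (data.frame).
#' @export
score_recovery <- function(matrix, truth) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (nrow(truth) == 0L) stop("usage error: empty ground truth")
  unknown <- setdiff(matrix$unit_ids, truth$family_accession)
  if (length(unknown)) {
    stop("usage error: census accessions absent from truth: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  cellular <- intersect(c("Archaea", "Bacteria", "Eukaryota"),
                        matrix$column_ids)
  ndom <- rowSums(matrix$present[, cellular, drop = FALSE])
  any_pres <- rowSums(matrix$present) > 0L
  inferred_of_unit <- ifelse(ndom >= 3L, "LUCA_VERTICAL",
                      ifelse(ndom == 2L, "HGT_INTERDOMAIN",
                      ifelse(any_pres, "DOMAIN_SPECIFIC", "ABSENT")))
  names(inferred_of_unit) <- matrix$unit_ids
  inferred <- inferred_of_unit[truth$family_accession]
  inferred[is.na(inferred)] <- "ABSENT"   # family vanished from the census
  confusion <- table(truth = truth$class, inferred = inferred)
  acc <- vapply(sort(unique(truth$class)), function(cl) {
    sel <- truth$class == cl
    mean(inferred[sel] == cl)
  }, numeric(1))
  mis <- data.frame(family_accession = truth$family_accession,
                    truth = truth$class, inferred = unname(inferred),
                    stringsAsFactors = FALSE)
  mis <- mis[mis$truth != mis$inferred, , drop = FALSE]
  list(confusion = confusion, accuracy = acc, misclassified = mis)
}
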