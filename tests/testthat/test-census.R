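test_that("presence matrices bin annotations by unit and column", {
  idx <- toy_index()
  # two bacterial "divisions": add a second phylum with a species
  tab <- rbind(toy_tax_tab(), data.frame(
    taxon_id = 7:8, parent_id = c(2L, 7L), rank = c("phylum", "species"),
    name = c("Firmicutes", "Bacillus subtilis"), stringsAsFactors = FALSE))
  idx <- build_taxonomy_index(tab, list(
    domains = list(Bacteria = "Bacteria", Archaea = "Archaea")))
  recs <- rbind(ann_row("F1", 4L, 50), ann_row("F1", 4L, 52),
                ann_row("F1", 8L, 48))
  asn <- assign_division(unique(recs$taxon_id), idx)
  pm <- build_presence(recs, asn, "family", "domain")
  expect_equal(pm$column_ids, c("Archaea", "Bacteria", "Eukaryota", "Viruses"))
  expect_true(pm$present["F1", "Bacteria"])
  expect_equal(pm$support["F1", "Bacteria"], 3L)
  expect_equal(sum(pm$present["F1", ]), 1L)
  # division level
  pmd <- build_presence(recs, asn, "family", "division", domain = "Bacteria",
                        division_levels = domain_divisions(idx, "Bacteria"))
  expect_equal(sum(pmd$present["F1", ]), 2L)
  # empty input
  pm0 <- build_presence(recs[0, ], asn, "family", "domain")
  expect_equal(length(pm0$unit_ids), 0L)
  # invariant: present == support > 0
  expect_identical(pm$present, pm$support > 0L)
})

test_that("clan-level presence is the OR of member families", {
  idx <- toy_index()
  recs <- rbind(ann_row("F1", 4L, 50), ann_row("F2", 6L, 50),
                ann_row("F3", 4L, 50))
  asn <- assign_division(unique(recs$taxon_id), idx)
  clan_map <- data.frame(family_accession = c("F1", "F2"),
                         clan_accession = c("C1", "C1"))
  pm <- build_presence(recs, asn, "clan", "domain", clan_map = clan_map)
  expect_true(all(pm$present["C1", c("Archaea", "Bacteria")]))
  expect_true("F3" %in% pm$unit_ids)       # unclanned family keeps its row
  expect_false("F1" %in% pm$unit_ids)      # clan replaces members
  expect_error(build_presence(recs, asn, "clan", "domain"),
               "configuration error")
  # OR property against the family-level matrix
  pmf <- build_presence(recs, asn, "family", "domain")
  for (col in pm$column_ids) {
    expect_equal(pm$present["C1", col],
                 any(pmf$present[c("F1", "F2"), col]))
  }
})

test_that("venn partition assigns each unit to exactly one region", {
  m <- matrix(FALSE, 10, 4, dimnames = list(
    sprintf("U%02d", 1:10), c("Archaea", "Bacteria", "Eukaryota", "Viruses")))
  m[1:3, "Archaea"] <- TRUE
  m[4:6, "Bacteria"] <- TRUE
  m[7:9, "Eukaryota"] <- TRUE
  m[10, ] <- TRUE
  v <- venn_partition(pm_from_logical(m))
  expect_equal(sum(v$region_counts[c("A", "B", "E", "V")]), 9L)
  expect_equal(unname(v$region_counts["ABEV"]), 1L)
  expect_equal(v$single_set_fraction, 0.9)
  expect_equal(sum(v$region_counts), v$n_units)

  # all units in one domain
  m2 <- m; m2[] <- FALSE; m2[, "Bacteria"] <- TRUE
  v2 <- venn_partition(pm_from_logical(m2))
  expect_equal(unname(v2$region_counts["B"]), 10L)
  expect_equal(sum(v2$region_counts), 10L)

  # empty presence is not a region
  m3 <- m; m3[5, ] <- FALSE
  v3 <- venn_partition(pm_from_logical(m3))
  expect_equal(v3$n_empty, 1L)
  expect_equal(sum(v3$region_counts), 9L)

  bad <- pm_from_logical(m[, 1:3])
  expect_error(venn_partition(bad), "usage error")
})

test_that("venn conservation holds on random matrices", {
  set.seed(11)
  for (i in 1:50) {
    pm <- random_domain_pm(sample(1:40, 1), p = runif(1, 0.1, 0.9))
    v <- venn_partition(pm)
    expect_equal(sum(v$region_counts), sum(rowSums(pm$present) > 0))
    expect_equal(v$n_units + v$n_empty, length(pm$unit_ids))
  }
})

test_that("broad distribution uses an inclusive threshold over all columns", {
  m <- matrix(FALSE, 3, 5, dimnames = list(
    c("U1", "U2", "U3"), paste0("div", 1:5)))
  m["U1", 1:3] <- TRUE                     # 3/5 = 0.6 -> broad
  calls <- broad_distribution(pm_from_logical(m), domain = "Bacteria")
  expect_true(calls$broad[calls$unit_id == "U1"])
  expect_false(calls$broad[calls$unit_id == "U2"])  # 0/5 -> not broad
  expect_equal(unique(calls$divisions_total), 5L)

  m4 <- matrix(FALSE, 1, 4, dimnames = list("U1", paste0("div", 1:4)))
  m4["U1", 1:2] <- TRUE                    # exactly 50%: inclusive
  expect_true(broad_distribution(pm_from_logical(m4))$broad)

  expect_error(broad_distribution(pm_from_logical(m4), threshold = 0),
               "configuration error")
  expect_error(broad_distribution(pm_from_logical(m4), threshold = 1.2),
               "configuration error")

  # monotone: adding a presence never flips broad -> not broad
  set.seed(3)
  for (i in 1:20) {
    mm <- matrix(runif(24) < 0.4, 4, 6,
                 dimnames = list(paste0("U", 1:4), paste0("d", 1:6)))
    b0 <- broad_distribution(pm_from_logical(mm))$broad
    mm2 <- mm
    off <- which(!mm2)
    if (length(off)) mm2[off[sample.int(length(off), 1)]] <- TRUE
    b1 <- broad_distribution(pm_from_logical(mm2))$broad
    expect_true(all(b1 >= b0))
  }
})

test_that("broad rates reproduce half-up one-decimal percentages", {
  mk <- function(broad, total) {
    data.frame(unit_id = sprintf("U%03d", seq_len(total)),
               divisions_present = c(rep(2L, broad), rep(1L, total - broad)),
               divisions_total = 4L,
               broad = c(rep(TRUE, broad), rep(FALSE, total - broad)))
  }
  expect_equal(broad_distribution_rate(mk(13, 69))$percent, 18.8)
  expect_equal(broad_distribution_rate(mk(15, 223))$percent, 6.7)
  expect_equal(broad_distribution_rate(mk(20, 826))$percent, 2.4)
  expect_equal(broad_distribution_rate(mk(0, 10))$percent, 0.0)
  expect_error(broad_distribution_rate(mk(0, 10)[0, ]), "undefined")
  # half-up, not banker's: 0.15 of 1000 -> 1/8 = 12.5% stays 12.5; 1/16*100
  expect_equal(round_half_up(18.85, 1), 18.9)
  expect_equal(round_half_up(6.65, 1), 6.7)
})

test_that("interdomain listing counts domains of life, not viruses", {
  m <- matrix(FALSE, 4, 4, dimnames = list(
    c("U1", "U2", "U3", "U4"),
    c("Archaea", "Bacteria", "Eukaryota", "Viruses")))
  m["U1", c("Archaea", "Bacteria")] <- TRUE
  m["U2", "Bacteria"] <- TRUE
  m["U3", c("Bacteria", "Viruses")] <- TRUE
  r <- interdomain_units(pm_from_logical(m))
  expect_equal(r$interdomain, "U1")
  expect_equal(r$virus_sharing, "U3")
  r0 <- interdomain_units(pm_from_logical(m[0, , drop = FALSE]))
  expect_equal(length(r0$interdomain), 0L)
})

test_that("normalised abundance divides distinct annotated taxa by the roster", {
  recs <- rbind(ann_row("F1", 1L, 50), ann_row("F1", 1L, 51),
                ann_row("F1", 2L, 50), ann_row("F2", 9L, 50))
  roster <- list(G1 = 1:4, G2 = 5:8)
  expect_warning(ab <- normalized_abundance(recs, NULL, roster),
                 "outside the roster")
  expect_equal(ab["F1", "G1"], 0.5)        # taxa {1,2} of 4, duplicates ignored
  expect_equal(ab["F1", "G2"], 0.0)
  expect_true(all(ab >= 0 & ab <= 1))
  # full coverage gives exactly 1
  full <- do.call(rbind, lapply(1:4, function(t) ann_row("F3", t, 50)))
  ab2 <- normalized_abundance(full, NULL, list(G1 = 1:4))
  expect_equal(ab2["F3", "G1"], 1.0)
  expect_warning(normalized_abundance(full, NULL, list(G1 = 1:4,
                                                       G2 = integer(0))),
                 "empty roster")
})

test_that("subsampling records never creates a presence cell", {
  s <- small_sim(seed = 5)
  asn <- assign_division(unique(s$annotations$taxon_id), s$index)
  pm_full <- build_presence(s$annotations, asn, "family", "domain")
  set.seed(99)
  for (i in 1:5) {
    sub <- s$annotations[sample(nrow(s$annotations),
                                floor(nrow(s$annotations) * 0.5)), ]
    pm_sub <- build_presence(sub, asn, "family", "domain")
    common <- intersect(pm_sub$unit_ids, pm_full$unit_ids)
    expect_true(all(pm_sub$present[common, ] <= pm_full$present[common, ]))
    expect_equal(length(setdiff(pm_sub$unit_ids, pm_full$unit_ids)), 0L)
  }
})

test_that("presence matrices round-trip through TSV", {
  s <- small_sim(seed = 2)
  asn <- assign_division(unique(s$annotations$taxon_id), s$index)
  pm <- build_presence(s$annotations, asn, "family", "domain")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_presence(pm, f)
  pm2 <- read_presence(f)
  expect_equal(pm2$support[pm$unit_ids, pm$column_ids], pm$support)
})
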