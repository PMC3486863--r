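test_that("infeasible parameters are rejected", {
  expect_error(sim_params(taxa_per_division = 0), "configuration error")
  expect_error(sim_params(class_mix = c(DOMAIN_SPECIFIC = 0.5,
                                        LUCA_VERTICAL = 0.2,
                                        HGT_INTERDOMAIN = 0.2)),
               "sum to 1")
  expect_error(sim_params(loss_prob = 1.5), "configuration error")
  expect_error(sim_params(hgt_rate = -1), "configuration error")
})

test_that("the same seed reproduces the simulation byte for byte", {
  s1 <- small_sim(seed = 13)
  s2 <- small_sim(seed = 13)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed gives different data
  s3 <- small_sim(seed = 14)
  expect_false(identical(s1$annotations, s3$annotations))
})

test_that("without noise the census recovers every truth class exactly", {
  for (sd in c(3, 4)) {
    s <- small_sim(seed = sd, loss_prob = 0, hgt_rate = 0, fp_rate = 0)
    asn <- assign_division(unique(s$annotations$taxon_id), s$index)
    pm <- build_presence(s$annotations, asn, "family", "domain")
    sc <- score_recovery(pm, s$truth)
    expect_true(all(sc$accuracy == 1.0))
    expect_equal(nrow(sc$misclassified), 0L)
    # domain-specific families land in single-set regions; LUCA in A+B+E
    v <- venn_partition(pm)
    ds <- s$truth$family_accession[s$truth$class == "DOMAIN_SPECIFIC"]
    singles <- unlist(v$region_units[c("A", "B", "E", "V")])
    expect_true(all(ds %in% singles))
    luca <- s$truth$family_accession[s$truth$class == "LUCA_VERTICAL"]
    expect_true(all(luca %in% unlist(v$region_units[c("ABE", "ABEV")])))
  }
})

test_that("ground truth respects the class contracts", {
  s <- small_sim(seed = 17)
  t <- s$truth
  ds <- t[t$class == "DOMAIN_SPECIFIC", ]
  expect_true(all(!grepl(";", ds$true_domains)))   # exactly one true domain
  luca <- t[t$class == "LUCA_VERTICAL", ]
  expect_true(all(luca$gain_node == "ROOT"))
  hgt <- t[t$class == "HGT_INTERDOMAIN", ]
  expect_true(all(hgt$n_hgt_events >= 1L))
  expect_true(all(grepl(";", hgt$true_domains)))
})

test_that("vetting restores the true interdomain count when all false
           positives are marginal", {
  s <- small_sim(seed = 6, loss_prob = 0, fp_rate = 1)
  asn <- assign_division(unique(s$annotations$taxon_id), s$index)
  truth_inter <- sum(s$truth$class %in% c("HGT_INTERDOMAIN",
                                          "LUCA_VERTICAL"))
  pm_raw <- build_presence(s$annotations, asn, "family", "domain")
  raw_inter <- length(interdomain_units(pm_raw)$interdomain)
  vet <- vet_annotations(s$annotations, s$families, asn)
  pm_vet <- build_presence(vet$kept, asn, "family", "domain")
  vet_inter <- length(interdomain_units(pm_vet)$interdomain)
  expect_gte(raw_inter, vet_inter)         # vetting never adds interdomain
  expect_equal(vet_inter, truth_inter)     # and restores the truth exactly
})

test_that("recovery scoring validates its inputs", {
  s <- small_sim(seed = 9)
  asn <- assign_division(unique(s$annotations$taxon_id), s$index)
  pm <- build_presence(s$annotations, asn, "family", "domain")
  expect_error(score_recovery(pm, s$truth[0, ]), "empty ground truth")
  expect_error(score_recovery(pm, s$truth[1:5, ]), "absent from truth")
  # a constructed partial-recall case: drop 2 of the HGT families' second
  # domains and check recall arithmetic
  sc <- score_recovery(pm, s$truth)
  hgt_n <- sum(s$truth$class == "HGT_INTERDOMAIN")
  if (hgt_n > 0) {
    hit <- sc$confusion["HGT_INTERDOMAIN", "HGT_INTERDOMAIN"]
    expect_equal(unname(sc$accuracy["HGT_INTERDOMAIN"]), hit / hgt_n)
  }
})

test_that("stronger sampling bias yields fewer broad-distribution calls", {
  n_broad <- function(bias, sd) {
    s <- simulate_census_data(sim_params(
      seed = sd, divisions_per_domain = 6L, taxa_per_division = 5L,
      n_families = 80L, sampling_bias = bias, loss_prob = 0,
      root_gain_prob = 0.5))
    asn <- assign_division(unique(s$annotations$taxon_id), s$index)
    ds <- s$truth$family_accession[s$truth$class == "DOMAIN_SPECIFIC"]
    total <- 0L
    for (d in c("Archaea", "Bacteria", "Eukaryota")) {
      pm <- build_presence(s$annotations, asn, "family", "division",
                           domain = d,
                           division_levels = domain_divisions(s$index, d))
      calls <- broad_distribution(pm, domain = d)
      total <- total + sum(calls$broad & calls$unit_id %in% ds)
    }
    total
  }
  seeds <- 1:7
  unbiased <- vapply(seeds, function(sd) n_broad(0, sd), integer(1))
  biased <- vapply(seeds, function(sd) n_broad(4, sd), integer(1))
  expect_lt(stats::median(biased), stats::median(unbiased))
})
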