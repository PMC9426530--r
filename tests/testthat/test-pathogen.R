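test_that("keyword classification follows the documented field/keyword rules", {
  expect_equal(
    classify_pathogen(c(isolation_source = "blood of patient with sepsis")),
    list(label = "pathogen", trigger_field = "isolation_source",
         trigger_phrase = "patient with"))
  expect_equal(classify_pathogen(character(0))$label, "unassigned")
  expect_equal(
    classify_pathogen(c(environmental_medium = "forest soil"))$label,
    "unassigned")
  # fields outside the recognised six are never scanned
  expect_equal(
    classify_pathogen(c(strain_notes = "a known pathogen"))$label,
    "unassigned")
  # fixed field order: the first matching field wins
  two <- classify_pathogen(c(host = "diseased cattle",
                             general_description = "pathogenic strain"))
  expect_equal(two$trigger_field, "general_description")
  # case-insensitive
  expect_equal(classify_pathogen(c(host = "PATHOGENIC strain"))$label,
               "pathogen")
  # keyword config round-trips through YAML
  kw <- read_keyword_config(system.file("extdata", "pathogen_keywords.yaml",
                                        package = "prophagecomp"))
  expect_true("pathogen" %in% kw)
  expect_equal(classify_pathogen(c(host = "forest soil"),
                                 keywords = c("soil"))$label, "pathogen")
})

test_that("per-genus capping downsamples reproducibly and never inflates", {
  genus <- rep(c("a", "b", "c"), c(100, 150, 20))
  hosts <- mk_catalog(genus, rep(0, length(genus)))$hosts
  capped <- cap_per_genus(hosts, cap = 100, seed = 3)
  expect_equal(as.vector(table(capped$genus)[c("a", "b", "c")]),
               c(100, 100, 20))
  expect_identical(capped, cap_per_genus(hosts, cap = 100, seed = 3))
  other <- cap_per_genus(hosts, cap = 100, seed = 4)
  expect_equal(nrow(other), nrow(capped))
  expect_false(identical(other$genome_id, capped$genome_id))
  # total size is sum of min(n_g, cap)
  expect_equal(nrow(cap_per_genus(hosts, cap = 30, seed = 1)), 30 * 2 + 20)
  # catalog subsetting keeps tables consistent
  cat <- mk_catalog(genus, rep(1, length(genus)))
  cc <- cap_per_genus(cat, cap = 50, seed = 1)
  expect_true(all(cc$prophages$genome_id %in% cc$hosts$genome_id))
})

test_that("group enrichment matches the enumeration oracle and finds planted excess", {
  ge <- group_enrichment(c(5, 6, 7), c(1, 2, 3))
  expect_equal(ge$p_value, 0.05)
  expect_gte(group_enrichment(c(1, 2, 3), c(1, 2, 3))$p_value, 0.5)
  expect_error(group_enrichment(numeric(0), c(1)), "non-empty")
  # planted 1.5x pathogen multiplier, ~500 genomes per group
  cfg <- simulation_config(seed = 29, n_phyla = 1, families_per_phylum = 1,
                           genera_per_family = 5, genomes_per_genus = 200,
                           pathogen_fraction = 0.5,
                           pathogen_count_multiplier = 1.5,
                           sequences = FALSE)
  sim <- simulate_catalog(cfg)
  labs <- classify_pathogens(sim$catalog)
  counts <- per_genome_counts(sim$catalog$hosts, sim$catalog$prophages)
  p <- group_enrichment(counts[labs$label == "pathogen"],
                        counts[labs$label == "unassigned"])$p_value
  expect_lt(p, 0.01)
})

test_that("leave-one-out attributes a single-genus driver and spares uniform excess", {
  # one genus (g1) carries the entire pathogen excess
  set.seed(101)
  genus <- rep(c("g1", "g2", "g3", "g4"), each = 60)
  pathogen <- rep(rep(c(TRUE, FALSE), each = 30), 4)
  mu <- ifelse(genus == "g1" & pathogen, 10, 2)
  counts <- rnbinom(length(mu), size = 5, mu = mu)
  cat <- mk_catalog(genus, counts)
  labels <- data.frame(genome_id = cat$hosts$genome_id,
                       label = ifelse(pathogen, "pathogen", "unassigned"),
                       stringsAsFactors = FALSE)
  res <- loo_contribution(labels, cat)
  expect_lt(res$full_p, 0.05)
  loo <- res$loo
  expect_gte(loo$p_value[loo$left_out_genus == "g1"], 0.05)
  expect_true(all(loo$p_value[loo$left_out_genus != "g1"] < 0.05))
  expect_false(any(loo$undefined))

  # uniform excess: no single removal abolishes significance
  set.seed(102)
  mu_u <- ifelse(pathogen, 3.5, 2)
  cat_u <- mk_catalog(genus, rnbinom(length(mu_u), size = 5, mu = mu_u))
  res_u <- loo_contribution(labels, cat_u)
  expect_true(all(res_u$loo$p_value < 0.05))

  # a removal that empties one group is flagged undefined, not an error
  one <- mk_catalog(c("gA", "gA", "gB"), c(3, 4, 1))
  labs1 <- data.frame(genome_id = one$hosts$genome_id,
                      label = c("pathogen", "pathogen", "unassigned"),
                      stringsAsFactors = FALSE)
  res1 <- loo_contribution(labs1, one)
  expect_true(res1$loo$undefined[res1$loo$left_out_genus == "gB"])
})

test_that("shared-genus comparison tests only genera present in both groups", {
  set.seed(103)
  genus <- rep(sprintf("g%02d", 1:11), each = 60)
  pathogen <- c(rep(rep(c(TRUE, FALSE), each = 30), 10), rep(TRUE, 60))
  mu <- ifelse(genus == "g01" & pathogen, 8, 2) # planted excess in one genus
  cat <- mk_catalog(genus, rnbinom(length(mu), size = 5, mu = mu))
  labels <- data.frame(genome_id = cat$hosts$genome_id,
                       label = ifelse(pathogen, "pathogen", "unassigned"),
                       stringsAsFactors = FALSE)
  tab <- shared_genus_comparison(labels, cat)
  # g11 is pathogen-only: excluded
  expect_false("g11" %in% tab$genus)
  expect_equal(nrow(tab), 10)
  expect_lt(tab$p_adjusted[tab$genus == "g01"], 0.05)
  expect_true(all(tab$p_adjusted[tab$genus != "g01"] >= 0.05))
  expect_true(all(tab$p_adjusted >= tab$p_value))
  # identical distributions in a genus give p >= 0.5
  same <- mk_catalog(rep("s", 8), rep(2, 8))
  labs_s <- data.frame(genome_id = same$hosts$genome_id,
                       label = rep(c("pathogen", "unassigned"), 4),
                       stringsAsFactors = FALSE)
  expect_gte(shared_genus_comparison(labs_s, same)$p_value, 0.5)
  expect_error(shared_genus_comparison(labs1 <- data.frame(
    genome_id = same$hosts$genome_id,
    label = rep("pathogen", 8), stringsAsFactors = FALSE), same),
    "shared")
})
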