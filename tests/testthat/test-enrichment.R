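test_that("one-sided Wilcoxon p agrees with exhaustive enumeration (ties included)", {
  expect_equal(wilcox_greater(c(5, 6, 7), c(1, 2, 3)), 0.05)
  expect_gte(wilcox_greater(c(1, 2, 3), c(1, 2, 3)), 0.5)
  set.seed(11)
  for (n1 in c(2, 3, 5, 8)) {
    for (n2 in c(2, 4, 8)) {
      x <- rnbinom(n1, size = 1.4, mu = 2.5) # heavy ties
      y <- rnbinom(n2, size = 1.4, mu = 2.5)
      expect_equal(wilcox_greater(x, y), oracle_wilcox_greater(x, y),
                   info = sprintf("tied n1=%d n2=%d", n1, n2))
      xc <- rnorm(n1); yc <- rnorm(n2) # tie-free: stats::wilcox.test exact
      expect_equal(wilcox_greater(xc, yc),
                   wilcox.test(xc, yc, alternative = "greater",
                               exact = TRUE)$p.value,
                   info = sprintf("continuous n1=%d n2=%d", n1, n2))
    }
  }
  # large-sample path matches the tie-corrected normal approximation
  set.seed(12)
  x <- rnbinom(12, 1.4, mu = 3); y <- rnbinom(60, 1.4, mu = 2.5)
  expect_equal(wilcox_greater(x, y),
               wilcox.test(x, y, alternative = "greater", exact = FALSE,
                           correct = FALSE)$p.value)
})

test_that("size-abundance correlation reproduces hand-computed Spearman rho", {
  mk <- function(sizes_mb, counts) {
    cat <- mk_catalog(rep("g", length(sizes_mb)), counts)
    cat$hosts$genome_size_bp <- sizes_mb * 1e6
    cat
  }
  expect_equal(size_abundance(mk(c(1, 2, 3), c(1, 2, 3)))$rho, 1)
  expect_equal(size_abundance(mk(c(1, 2, 3), c(3, 2, 1)))$rho, -1)
  # ranks (1,2,3,4) vs (2,1,4,3): rho = 1 - 6*4/(4*15) = 0.6
  sa <- size_abundance(mk(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  expect_equal(sa$rho, 0.6)
  expect_true(sa$correlation_defined)
  # below 3 genomes the correlation is flagged undefined
  sa2 <- size_abundance(mk(c(1, 2), c(1, 2)))
  expect_false(sa2$correlation_defined)
  expect_true(is.na(sa2$rho))
  # per-bin series: long-prophage subset never exceeds the full series
  sim <- simulate_catalog(simulation_config(seed = 23, sequences = FALSE))
  sa3 <- size_abundance(sim$catalog)
  expect_true(all(sa3$bins$total_long <= sa3$bins$total))
})

test_that("rank enrichment recovers a planted enriched genus", {
  cfg <- simulation_config(seed = 11, n_phyla = 2, families_per_phylum = 2,
                           genera_per_family = 5, genomes_per_genus = 20,
                           enriched_genera = c(g07 = 4), sequences = FALSE)
  sim <- simulate_catalog(cfg)
  enr <- rank_enrichment(sim$catalog, "genus", seed = 1)
  expect_equal(enr$taxon[1], "g07")
  expect_lt(enr$p_adjusted[1], 0.05)
  expect_lte(sum(enr$p_adjusted < 0.05 & enr$taxon != "g07"), 1)
  # Bonferroni never shrinks a p-value
  expect_true(all(enr$p_adjusted >= enr$p_value))
  # excluding the planted genus's order removes its genera from the table
  ord <- sim$catalog$hosts$order[sim$catalog$hosts$genus == "g07"][1]
  enr2 <- rank_enrichment(sim$catalog, "genus", seed = 1,
                          exclude_taxon = ord)
  gone <- unique(sim$catalog$hosts$genus[sim$catalog$hosts$order == ord])
  expect_false(any(enr2$taxon %in% gone))
  # background including the focal taxon is also available and differs
  enr3 <- rank_enrichment(sim$catalog, "genus", seed = 1,
                          background = "include")
  expect_false(identical(enr3$p_value, enr$p_value))
})

test_that("taxa over the cap are downsampled deterministically", {
  cfg <- simulation_config(seed = 31, n_phyla = 1, families_per_phylum = 1,
                           genera_per_family = 3, genomes_per_genus = 60,
                           sequences = FALSE)
  sim <- simulate_catalog(cfg)
  e1 <- rank_enrichment(sim$catalog, "genus", cap_trigger = 50,
                        cap_sample = 10, seed = 4)
  expect_true(all(e1$n_genomes == 10))
  e2 <- rank_enrichment(sim$catalog, "genus", cap_trigger = 50,
                        cap_sample = 10, seed = 4)
  expect_identical(e1, e2)
  expect_error(rank_enrichment(sim$catalog, "phylum"), "fewer than 2 taxa")
})

test_that("bootstrap enrichment is calibrated under the null and detects plantings", {
  # null: 20 exchangeable genera at the eligibility size (50 genomes each)
  cfg0 <- simulation_config(seed = 12, n_phyla = 2, families_per_phylum = 2,
                            genera_per_family = 5, genomes_per_genus = 50,
                            pathogen_fraction = 0, sequences = FALSE)
  bt0 <- bootstrap_enrichment(simulate_catalog(cfg0)$catalog,
                              n_genomes = 10, n_iter = 100, seed = 5)
  expect_lt(abs(mean(bt0$p_matrix < 0.05) - 0.05), 0.02)
  expect_true(all(bt0$p_matrix >= 0 & bt0$p_matrix <= 1))
  expect_equal(ncol(bt0$p_matrix), 100)

  # planted 4x genus: low p across iterations
  cfg <- simulation_config(seed = 11, n_phyla = 2, families_per_phylum = 2,
                           genera_per_family = 5, genomes_per_genus = 50,
                           enriched_genera = c(g07 = 4), sequences = FALSE)
  bt <- bootstrap_enrichment(simulate_catalog(cfg)$catalog, 10, 100,
                             seed = 5)
  expect_lt(median(bt$p_matrix["g07", ]), 0.05)

  # genera under the eligibility size are reported as skipped
  cfgS <- simulation_config(seed = 2, n_phyla = 1, families_per_phylum = 1,
                            genera_per_family = 3, genomes_per_genus = 20,
                            sequences = FALSE)
  expect_error(bootstrap_enrichment(simulate_catalog(cfgS)$catalog),
               ">= 50")
  btS <- bootstrap_enrichment(simulate_catalog(cfgS)$catalog,
                              min_genus_genomes = 10, n_iter = 5, seed = 1)
  expect_length(btS$skipped, 0)
})

test_that("a single bootstrap iteration equals a direct test on its subsample", {
  cfg <- simulation_config(seed = 19, n_phyla = 1, families_per_phylum = 1,
                           genera_per_family = 4, genomes_per_genus = 15,
                           sequences = FALSE)
  sim <- simulate_catalog(cfg)
  bt <- bootstrap_enrichment(sim$catalog, n_genomes = 10, n_iter = 1,
                             seed = 77, min_genus_genomes = 10)
  # rebuild the iteration's subsample from the same substream and re-test
  hosts <- sim$catalog$hosts
  counts <- per_genome_counts(hosts, sim$catalog$prophages)
  idx <- split(seq_len(nrow(hosts)), hosts$genus)[rownames(bt$p_matrix)]
  sel <- prophagecomp:::with_seed(substream_seed(77, "boot.1"),
                                  lapply(idx, function(i) sample(i, 10)))
  pooled <- counts[unlist(sel)]
  for (g in seq_along(sel)) {
    focal <- counts[sel[[g]]]
    bg <- pooled[-(((g - 1) * 10 + 1):(g * 10))]
    expect_equal(unname(bt$p_matrix[g, 1]),
                 unname(wilcox_greater(focal, bg)))
  }
})

test_that("per-genus count correlations validate input and reuse Spearman", {
  expect_equal(count_count_correlation(c(1, 2, 3), c(1, 2, 3))$rho, 1)
  expect_equal(count_count_correlation(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  expect_equal(count_count_correlation(c(2, 1, 4, 3), c(1, 2, 3, 4))$rho, 0.6)
  expect_error(count_count_correlation(1:3, 1:4), "length")
  expect_error(count_count_correlation(1:2, 1:2), "at least 3")
})
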