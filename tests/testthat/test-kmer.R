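test_that("k-mer frequencies count overlapping windows and skip ambiguity", {
  f <- kmer_frequencies("AAAA", 2)
  expect_equal(unname(f[["AA"]]), 1)
  f2 <- kmer_frequencies("ACACAC", 2)
  expect_equal(unname(f2[c("AC", "CA")]), c(0.6, 0.4))
  f1 <- kmer_frequencies("ACACAC", 1)
  expect_equal(unname(f1[c("A", "C")]), c(0.5, 0.5))
  # windows containing N are skipped; remaining frequencies sum to 1
  fN <- kmer_frequencies("ACGTNACGT", 2)
  expect_equal(sum(fN), 1)
  expect_equal(unname(fN[["AC"]]), 2 / 6)
  expect_error(kmer_frequencies("A", 2), "shorter")
  # property: frequencies sum to 1 for random sequences at every k
  set.seed(41)
  for (k in 1:4) {
    expect_equal(sum(kmer_frequencies(random_dna(500), k)), 1,
                 tolerance = 1e-12)
  }
})

test_that("bias values reproduce hand computations under both models", {
  expect_equal(unname(kmer_bias("AAAA", 2)$bias[["AA"]]), 1)
  b <- kmer_bias("ACACAC", 2)
  expect_equal(unname(b$bias[["AC"]]), 0.6 / (0.5 * 0.5))
  b3 <- kmer_bias("ACACAC", 3, model = "markov_max")
  expect_equal(unname(b3$bias[["ACA"]]), 0.5 / (0.6 * 0.4 / 0.5),
               tolerance = 1e-12)
  b3l <- kmer_bias("ACACAC", 3, model = "literal_product")
  expect_equal(unname(b3l$bias[["ACA"]]), 0.5 / (0.6 * 0.4))
  # the two models coincide exactly at k = 2
  set.seed(42)
  s <- random_dna(2000)
  expect_equal(kmer_bias(s, 2, "markov_max")$bias,
               kmer_bias(s, 2, "literal_product")$bias)
  # zero expectation: bias undefined and reported as NA, not dropped
  bz <- kmer_bias("AAAACAAAA", 2)
  expect_true(is.na(bz$bias[["GG"]]))
  expect_length(bz$bias, 16)
})

test_that("bias is flat on composition-free sequence at the binomial scale", {
  set.seed(43)
  s <- random_dna(100000)
  L <- 100000
  b2 <- kmer_bias(s, 2)
  expect_lt(max(abs(b2$bias - 1)), 0.05)
  # k = 3, 4: max log-deviation within 4.5 analytic binomial sd of the
  # maximal-order Markov log-ratio
  for (k in 3:4) {
    bk <- kmer_bias(s, k)
    sd_k <- sqrt((4^k - 2 * 4^(k - 1) + 4^(k - 2)) / L)
    expect_lt(max(abs(bk$log_bias), na.rm = TRUE), 4.5 * sd_k)
    expect_lt(abs(mean(bk$bias, na.rm = TRUE) - 1), 0.01)
  }
})

test_that("both-strand counting makes bias strand-symmetric", {
  set.seed(44)
  s <- random_dna(3000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  b1 <- kmer_bias(s, 2, both_strands = TRUE)
  b2 <- kmer_bias(rc, 2, both_strands = TRUE)
  expect_equal(b1$bias, b2$bias)
  # single-strand profiles generally differ between strands
  expect_false(isTRUE(all.equal(kmer_bias(s, 2)$bias,
                                kmer_bias(rc, 2)$bias)))
})

test_that("profile distances are metric and respond to single entries", {
  set.seed(45)
  p1 <- kmer_bias(random_dna(1000), 2, id = "p1")
  expect_equal(bias_distance(p1, p1), 0)
  # differ only in B(AA): e vs 1 -> distance exactly 1
  q1 <- p1; q2 <- p1
  q1$bias["AA"] <- exp(1); q2$bias["AA"] <- 1
  q1$log_bias <- log(q1$bias); q2$log_bias <- log(q2$bias)
  expect_equal(bias_distance(q1, q2), 1)
  # triangle inequality on three hand-made profiles
  q3 <- p1
  q3$bias[] <- q3$bias * exp(runif(16, -0.5, 0.5))
  q3$log_bias <- log(q3$bias)
  d12 <- bias_distance(q1, q2); d13 <- bias_distance(q1, q3)
  d23 <- bias_distance(q2, q3)
  expect_lte(d12, d13 + d23 + 1e-12)
  expect_error(bias_distance(p1, kmer_bias("ACGTACGT", 3)), "word sizes")
})

test_that("co-clustering separates planted groups and ranks true hosts first", {
  # 3 identical profiles + 1 distant -> clusters {3}, {1}
  set.seed(46)
  s <- random_dna(2000)
  # bias profiles normalise composition away, so "distant" means different
  # dinucleotide structure, not different GC: use a homopolymer-blocky
  # sequence whose same-base dinucleotides are strongly over-represented
  far <- paste(vapply(1:400, function(i)
    strrep(sample(c("A", "C", "G", "T"), 1), sample(3:8, 1)),
    character(1)), collapse = "")
  prof <- list(kmer_bias(s, 2, id = "a"), kmer_bias(s, 2, id = "b"),
               kmer_bias(s, 2, id = "c"))
  hostp <- list(kmer_bias(far, 2, id = "h"))
  cc <- cocluster_profiles(prof, hostp, cut_height = 0.5)
  expect_equal(unname(cc$clusters[c("a", "b", "c")]), rep(1, 3))
  expect_false(cc$clusters[["h"]] == 1)

  # nearest-host recovery from the generator's planted composition signal
  acc <- function(w) {
    cfg <- simulation_config(seed = 31, n_phyla = 2, families_per_phylum = 1,
                             genera_per_family = 2, genomes_per_genus = 5,
                             composition_w = w, host_seq_bp = 30000,
                             count_mean = 2)
    sim <- simulate_catalog(cfg)
    pro <- sim$catalog$prophages
    pro <- pro[nchar(pro$sequence) >= 10000, ]
    pp <- lapply(seq_len(nrow(pro)), function(i) combine_bias_profiles(
      kmer_bias(pro$sequence[i], 2, id = pro$prophage_id[i]),
      kmer_bias(pro$sequence[i], 3, id = pro$prophage_id[i])))
    hosts <- sim$catalog$hosts
    rep_ids <- tapply(hosts$genome_id, hosts$phylum, `[`, 1)
    hp <- lapply(rep_ids, function(g) combine_bias_profiles(
      kmer_bias(sim$host_seqs[[g]], 2, id = g),
      kmer_bias(sim$host_seqs[[g]], 3, id = g)))
    cc <- cocluster_profiles(pp, hp)
    truth <- sim$truth$prophages$host_clade[
      match(cc$nearest_host$phage, sim$truth$prophages$prophage_id)]
    pred <- hosts$phylum[match(cc$nearest_host$host, hosts$genome_id)]
    mean(pred == truth)
  }
  a0 <- acc(0); a4 <- acc(0.4); a8 <- acc(0.8)
  expect_gte(a8, 0.9)          # strong host signal is recovered
  expect_lt(a0, 0.75)          # no signal: near the two-clade chance level
  expect_gte(a8 + 1e-9, a4)    # power grows with the composition weight
  expect_gte(a4, a0)
  expect_error(cocluster_profiles(prof[1], list()), "at least 3")
})
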