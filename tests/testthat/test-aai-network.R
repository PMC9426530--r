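mk_lineages <- function(ids, genus, family = NULL, order = NULL,
                        class = NULL, phylum = NULL) {
  data.frame(prophage_id = ids, genus = genus,
             family = family %||% genus, order = order %||% "o1",
             class = class %||% "c1", phylum = phylum %||% "p1",
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("AAI pairs track planted protein divergence", {
  set.seed(31)
  prots <- replicate(12, random_protein(sample(80:300, 1)))
  A <- mk_orf_set(prots, "a")
  expect_equal(aai_pair(A, mk_orf_set(prots, "b"))$aai, 100)
  B <- mk_orf_set(vapply(prots, mutate_protein, character(1), d = 0.10), "b")
  p <- aai_pair(A, B)
  expect_lt(abs(p$aai - 90), 2)
  expect_equal(p$n_orthologs, 12)
  # no passing ortholog: undefined, 0
  set.seed(32)
  C <- mk_orf_set(replicate(3, random_protein(90)), "c")
  D <- mk_orf_set(replicate(3, random_protein(90)), "d")
  out <- aai_pair(C, D)
  expect_true(is.na(out$aai))
  expect_equal(out$n_orthologs, 0)
  # symmetry within floating tolerance
  q <- aai_pair(B, A)
  expect_equal(q$aai, p$aai, tolerance = 1e-9)
})

test_that("the AAI network keeps edges above threshold and separates families", {
  set.seed(33)
  base <- replicate(8, random_protein(sample(100, 1) + 80))
  ids <- c("x", "y", "z")
  orfs <- setNames(lapply(ids, function(i) mk_orf_set(base, i)), ids)
  li <- mk_lineages(ids, genus = "g1")
  net <- build_network(orfs, li, threshold = 80)
  expect_equal(nrow(net$edges), 3) # triangle
  expect_true(all(net$edges$aai == 100))
  expect_equal(nrow(build_network(orfs, li, threshold = 101)$edges), 0)

  # two planted families: 5% intra, unrelated across -> two cliques
  set.seed(34)
  famA <- replicate(10, random_protein(150))
  famB <- replicate(10, random_protein(150))
  mk_member <- function(fam, id) mk_orf_set(
    vapply(fam, mutate_protein, character(1), d = 0.05), id)
  orfs2 <- list(a1 = mk_member(famA, "a1"), a2 = mk_member(famA, "a2"),
                a3 = mk_member(famA, "a3"), b1 = mk_member(famB, "b1"),
                b2 = mk_member(famB, "b2"))
  li2 <- mk_lineages(names(orfs2), genus = c("g1", "g1", "g1", "g2", "g2"))
  net2 <- build_network(orfs2, li2, threshold = 80)
  key <- paste(net2$edges$a, net2$edges$b)
  expect_setequal(key, c("a1 a2", "a1 a3", "a2 a3", "b1 b2"))
  # edge count is non-increasing in the threshold
  for (thr in c(85, 95, 99)) {
    expect_lte(nrow(build_network(orfs2, li2, threshold = thr)$edges),
               nrow(net2$edges))
  }
})

test_that("per-rank differ fractions are exact on a hand-built network and monotone", {
  ids <- sprintf("n%d", 1:6)
  li <- data.frame(
    prophage_id = ids,
    genus = c("g1", "g1", "g1", "g2", "g1", "g9"),
    family = c("f1", "f1", "f1", "f1", "f1", "f9"),
    order = c("o1", "o1", "o1", "o1", "o1", "o9"),
    class = c("c1", "c1", "c1", "c1", "c1", "c9"),
    phylum = c("p1", "p1", "p1", "p1", "p1", "p9"),
    stringsAsFactors = FALSE)
  edges <- data.frame(a = c("n1", "n1", "n2", "n1", "n1"),
                      b = c("n2", "n3", "n3", "n4", "n6"),
                      aai = 90, n_orthologs = c(2, 4, 3, 3, 3),
                      stringsAsFactors = FALSE)
  net <- structure(list(nodes = li, edges = edges, threshold = 80),
                   class = "aai_network")
  fr <- fraction_by_rank(net)
  # 3 same-genus edges, 1 cross-genus-same-family, 1 cross-phylum
  expect_equal(fr$fraction_different[fr$rank == "genus"], 0.4)
  expect_equal(fr$fraction_different[fr$rank == "family"], 0.2)
  expect_equal(fr$fraction_different[fr$rank == "phylum"], 0.2)
  expect_equal(fr$fraction_same, 1 - fr$fraction_different)
  # monotonicity on simulated nested taxonomies with random edges
  set.seed(35)
  for (rep in 1:5) {
    cfg <- simulation_config(seed = 100 + rep, sequences = FALSE)
    sim <- simulate_catalog(cfg)
    pro <- sim$catalog$prophages
    if (nrow(pro) < 10) next
    pick <- sample(nrow(pro), 10)
    li_r <- cbind(prophage_id = pro$prophage_id[pick],
                  sim$catalog$hosts[match(pro$genome_id[pick],
                                          sim$catalog$hosts$genome_id),
                                    c("phylum", "class", "order", "family",
                                      "genus")])
    pairs <- t(combn(li_r$prophage_id, 2))
    take <- sample(nrow(pairs), 15)
    net_r <- structure(list(
      nodes = li_r,
      edges = data.frame(a = pairs[take, 1], b = pairs[take, 2], aai = 85,
                         n_orthologs = 1, stringsAsFactors = FALSE),
      threshold = 80), class = "aai_network")
    fd <- fraction_by_rank(net_r)$fraction_different
    expect_true(all(diff(fd) <= 1e-12)) # genus >= family >= ... >= phylum
  }
  # all edges within one genus: zero at every rank
  net1 <- structure(list(nodes = li[1:3, ],
                         edges = edges[1:3, ], threshold = 80),
                    class = "aai_network")
  expect_true(all(fraction_by_rank(net1)$fraction_different == 0))
  expect_error(fraction_by_rank(structure(list(nodes = li,
                                               edges = edges[0, ]),
                                          class = "aai_network")),
               "no edges")
})

test_that("shared-ortholog means are taken over qualifying cross-phylum edges", {
  ids <- c("a", "b", "c", "d")
  li <- mk_lineages(ids, genus = c("g1", "g2", "g3", "g4"),
                    phylum = c("pA", "pB", "pB", "pC"))
  edges <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"),
                      aai = 85, n_orthologs = c(2L, 4L, 9L),
                      stringsAsFactors = FALSE)
  net <- structure(list(nodes = li, edges = edges, threshold = 80),
                   class = "aai_network")
  s <- shared_ortholog_summary(net, "pA", "pB")
  expect_equal(s$mean_orthologs, 3.0)
  expect_equal(s$n_edges, 2)
  none <- shared_ortholog_summary(net, "pA", "pC")
  expect_true(is.na(none$mean_orthologs))
  # planted constant k orthologs: mean is k
  edges$n_orthologs <- 7L
  net$edges <- edges
  expect_equal(shared_ortholog_summary(net, "pA", "pB")$mean_orthologs, 7)
})

test_that("ANI-AAI co-structure scores tracking, permuted and mixed assignments", {
  set.seed(36)
  rootA <- random_dna(15000); rootB <- random_dna(15000)
  hosts <- c(H1 = mutate_at(rootA, sample(15000, 150)),
             H2 = mutate_at(rootA, sample(15000, 150)),
             H3 = mutate_at(rootB, sample(15000, 150)),
             H4 = mutate_at(rootB, sample(15000, 150)))
  pa <- random_dna(10000); pb <- random_dna(10000)
  phage <- c(P1 = mutate_at(pa, sample(10000, 200)),
             P2 = mutate_at(pa, sample(10000, 200)),
             P3 = mutate_at(pb, sample(10000, 200)),
             P4 = mutate_at(pb, sample(10000, 200)))
  orfs <- setNames(lapply(names(phage), function(n)
    find_orfs(phage[[n]], id = n)), names(phage))
  tracking <- c(P1 = "H1", P2 = "H2", P3 = "H3", P4 = "H4")
  cs <- ani_aai_costructure(hosts, orfs, tracking)
  expect_equal(cs$congruence, 1)
  expect_equal(length(unique(cs$host_clusters)), 2)
  expect_equal(length(unique(cs$phage_clusters)), 2)

  # one phage family spanning both host subclades: mismatches identified
  mixed <- c(P1 = "H1", P2 = "H3", P3 = "H2", P4 = "H4")
  cs2 <- ani_aai_costructure(hosts, orfs, mixed)
  expect_lt(cs2$congruence, 1)
  expect_true(any(cs2$pairs$same_phage_cluster != cs2$pairs$same_host_cluster))

  # a label permutation drops congruence to the permutation-null chance
  # level (computed over sampled permutations), well below the tracking 1.0
  set.seed(37)
  null_congr <- replicate(12, ani_aai_costructure(
    hosts, orfs,
    setNames(sample(names(hosts)), names(phage)))$congruence)
  chance <- mean(null_congr)
  obs <- ani_aai_costructure(hosts, orfs,
                             setNames(c("H3", "H1", "H4", "H2"),
                                      names(phage)))$congruence
  expect_lt(abs(obs - chance), 2 * sd(null_congr) + 1e-9)
  expect_lt(chance, 1)
  expect_error(ani_aai_costructure(hosts[1:2], orfs[1:2],
                                   tracking[1:2]), "at least 3")
})
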