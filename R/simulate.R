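#' Configuration for the synthetic catalog generator
#'
#' Bundles every tunable of the generator with defaults that emulate the
#' structure of a large prophage survey at desk scale: a genus-structured host
#' population with heterogeneous genome sizes (1--10 Mb log-normal),
#' overdispersed per-genome prophage counts (negative binomial) with optional
#' planted enriched genera, bimodal prophage lengths (~30 kb and ~70 kb
#' modes), host-like nucleotide composition in prophage sequences (tunable
#' mixing weight `composition_w`), and Biosample-style free text with a
#' planted pathogen excess.
#'
#' @param seed master integer seed; fully determines the output.
#' @param n_phyla,families_per_phylum,genera_per_family,genomes_per_genus
#'   taxonomy shape (one class per phylum, one order per family's parent by
#'   construction, so nestedness holds).
#' @param genome_size_meanlog,genome_size_sdlog log-normal genome-size model
#'   in Mb; draws are clamped to `[1, 10]` Mb.
#' @param count_mean,count_dispersion negative-binomial per-genome prophage
#'   count model (mean and size/dispersion k).
#' @param enriched_genera named numeric vector mapping genus names (as
#'   generated: `g01`, `g02`, ...) to fold-enrichments of the count mean.
#' @param length_weights,length_means,length_sds two-component Gaussian
#'   mixture for prophage lengths in bp.
#' @param pathogen_fraction fraction of genomes labelled pathogenic in the
#'   Biosample text; `pathogen_count_multiplier` scales their count mean.
#' @param composition_w mixing weight in `[0,1]` of the host clade's
#'   dinucleotide composition in prophage sequences (the remainder follows a
#'   phage-family-specific composition); the planted signal k-mer bias
#'   profiling is expected to recover.
#' @param n_phage_families number of phage composition families.
#' @param sequences emit prophage (and host) sequences.
#' @param host_seq_bp length of the representative host sequence emitted per
#'   genome when `sequences` is `TRUE` (a composition proxy, not a full
#'   genome).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_phyla = 2L,
                              families_per_phylum = 2L,
                              genera_per_family = 5L,
                              genomes_per_genus = 20L,
                              genome_size_meanlog = log(4),
                              genome_size_sdlog = 0.35,
                              count_mean = 2.45,
                              count_dispersion = 1.4,
                              enriched_genera = numeric(0),
                              length_weights = c(0.7, 0.3),
                              length_means = c(30000, 70000),
                              length_sds = c(5000, 10000),
                              pathogen_fraction = 0.3,
                              pathogen_count_multiplier = 1.5,
                              composition_w = 0.8,
                              n_phage_families = 5L,
                              sequences = TRUE,
                              host_seq_bp = 20000L) {
  cfg <- as.list(environment())
  n_gen <- n_phyla * families_per_phylum * genera_per_family
  if (n_phyla < 1 || n_gen < 1 || genomes_per_genus < 1)
    stop_input("infeasible config: at least one phylum, genus and genome required")
  if (abs(sum(length_weights) - 1) > 1e-9)
    stop_input("length mixture weights must sum to 1")
  if (pathogen_fraction < 0 || pathogen_fraction > 1 ||
      composition_w < 0 || composition_w > 1)
    stop_input("probabilities and mixture weights must lie in [0, 1]")
  if (length(enriched_genera) &&
      (is.null(names(enriched_genera)) || any(enriched_genera <= 0)))
    stop_input("enriched_genera must be a named vector of positive folds")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a complete synthetic prophage catalog with ground truth
#'
#' Deterministic given `config$seed`. Genus-level counts follow the stated
#' negative binomial; planted enriched genera have their count mean scaled by
#' the configured fold; prophage lengths come from the bimodal mixture; when
#' sequences are requested, each prophage is drawn from a first-order Markov
#' model mixing its host clade's composition (weight `composition_w`) with a
#' phage-family composition, so the phage--host association is recoverable
#' from k-mer bias profiles.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory: writes `hosts.tsv`, `prophages.tsv`,
#'   `prophages.fasta`, `hosts.fasta` and `groundtruth.tsv`.
#' @return List with `catalog` (a `prophage_catalog`), `host_seqs` (named
#'   character vector, empty when sequences are off) and `truth` (list of
#'   data frames: `genera` with planted folds, `genomes` with pathogen labels
#'   and clade, `prophages` with source phage family and host clade).
#' @export
simulate_catalog <- function(config = simulation_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config

  taxa <- make_taxonomy(cfg)
  n_genomes <- nrow(taxa) * cfg$genomes_per_genus

  hosts <- with_seed(substream_seed(cfg$seed, "sim.hosts"), {
    gi <- rep(seq_len(nrow(taxa)), each = cfg$genomes_per_genus)
    size_mb <- pmin(10, pmax(1, stats::rlnorm(n_genomes,
                                              cfg$genome_size_meanlog,
                                              cfg$genome_size_sdlog)))
    data.frame(
      genome_id = sprintf("G%05d", seq_len(n_genomes)),
      phylum = taxa$phylum[gi], class = taxa$class[gi],
      order = taxa$order[gi], family = taxa$family[gi],
      genus = taxa$genus[gi],
      genome_size_bp = round(size_mb * 1e6),
      stringsAsFactors = FALSE
    )
  })

  pathogen <- with_seed(substream_seed(cfg$seed, "sim.pathogen"),
    stats::runif(n_genomes) < cfg$pathogen_fraction)
  hosts$biosample <- lapply(seq_len(n_genomes), function(i)
    simulate_biosample_text(if (pathogen[i]) "pathogen" else "unassigned",
                            seed = substream_seed(cfg$seed,
                                                  paste0("sim.bios.", i))))

  fold <- rep(1, n_genomes)
  if (length(cfg$enriched_genera)) {
    unknown <- setdiff(names(cfg$enriched_genera), taxa$genus)
    if (length(unknown))
      stop_input("enriched_genera names not in generated genera: %s",
                 paste(unknown, collapse = ", "))
    hit <- match(hosts$genus, names(cfg$enriched_genera))
    fold[!is.na(hit)] <- cfg$enriched_genera[hit[!is.na(hit)]]
  }
  mu <- cfg$count_mean * fold *
    ifelse(pathogen, cfg$pathogen_count_multiplier, 1)
  counts <- with_seed(substream_seed(cfg$seed, "sim.counts"),
    stats::rnbinom(n_genomes, size = cfg$count_dispersion, mu = mu))

  n_pro <- sum(counts)
  prophages <- with_seed(substream_seed(cfg$seed, "sim.prophages"), {
    gidx <- rep(seq_len(n_genomes), counts)
    comp <- sample.int(2L, n_pro, replace = TRUE, prob = cfg$length_weights)
    len <- round(stats::rnorm(n_pro, cfg$length_means[comp],
                              cfg$length_sds[comp]))
    len <- pmax(5000L, pmin(len, floor(hosts$genome_size_bp[gidx] / 3)))
    start <- 1L + floor(stats::runif(n_pro) *
                          (hosts$genome_size_bp[gidx] - len))
    fam <- sample.int(cfg$n_phage_families, n_pro, replace = TRUE)
    data.frame(
      prophage_id = sprintf("P%06d", seq_len(max(n_pro, 0))),
      genome_id = hosts$genome_id[gidx],
      replicon_id = "chr1",
      start = as.integer(start), end = as.integer(start + len - 1L),
      category = 1L, plasmid_flag = FALSE,
      length = as.integer(len), sequence = NA_character_,
      phage_family = fam,
      stringsAsFactors = FALSE
    )
  })

  host_seqs <- character(0)
  if (cfg$sequences) {
    mats <- composition_matrices(cfg)
    clade_of <- match(hosts$phylum, unique(taxa$phylum))
    host_seqs <- with_seed(substream_seed(cfg$seed, "sim.hostseq"), {
      s <- vapply(seq_len(n_genomes), function(i) {
        M <- mats$clade[[clade_of[i]]]
        markov_seq_cpp(cfg$host_seq_bp, M, stationary_freq(M))
      }, character(1))
      names(s) <- hosts$genome_id
      s
    })
    gidx <- match(prophages$genome_id, hosts$genome_id)
    prophages$sequence <- with_seed(
      substream_seed(cfg$seed, "sim.phageseq"),
      vapply(seq_len(nrow(prophages)), function(i) {
        M <- cfg$composition_w * mats$clade[[clade_of[gidx[i]]]] +
          (1 - cfg$composition_w) * mats$family[[prophages$phage_family[i]]]
        markov_seq_cpp(prophages$length[i], M, stationary_freq(M))
      }, character(1)))
  }

  replicons <- data.frame(genome_id = hosts$genome_id, replicon_id = "chr1",
                          replicon_length_bp = hosts$genome_size_bp,
                          stringsAsFactors = FALSE)
  catalog <- structure(
    list(hosts = hosts, replicons = replicons,
         prophages = prophages[, c("prophage_id", "genome_id", "replicon_id",
                                   "start", "end", "category", "plasmid_flag",
                                   "length", "sequence")]),
    class = "prophage_catalog")

  truth <- list(
    genera = data.frame(
      genus = taxa$genus,
      fold = ifelse(taxa$genus %in% names(cfg$enriched_genera),
                    cfg$enriched_genera[taxa$genus], 1),
      enriched = taxa$genus %in% names(cfg$enriched_genera),
      stringsAsFactors = FALSE),
    genomes = data.frame(genome_id = hosts$genome_id,
                         pathogen = pathogen,
                         clade = hosts$phylum,
                         stringsAsFactors = FALSE),
    prophages = data.frame(prophage_id = prophages$prophage_id,
                           phage_family = prophages$phage_family,
                           host_clade = hosts$phylum[
                             match(prophages$genome_id, hosts$genome_id)],
                           stringsAsFactors = FALSE)
  )

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_catalog(catalog, file.path(dir, "hosts.tsv"),
                  file.path(dir, "prophages.tsv"),
                  if (cfg$sequences) file.path(dir, "prophages.fasta"))
    if (cfg$sequences) {
      hs <- Biostrings::DNAStringSet(host_seqs)
      Biostrings::writeXStringSet(hs, file.path(dir, "hosts.fasta"),
                                  width = 80)
    }
    gt <- merge(truth$genomes,
                stats::aggregate(list(n_prophages = prophages$genome_id),
                                 by = list(genome_id = prophages$genome_id),
                                 FUN = length),
                by = "genome_id", all.x = TRUE)
    gt$n_prophages[is.na(gt$n_prophages)] <- 0L
    utils::write.table(gt, file.path(dir, "groundtruth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  list(catalog = catalog, host_seqs = host_seqs, truth = truth)
}

make_taxonomy <- function(cfg) {
  rows <- list()
  g <- 0L
  for (p in seq_len(cfg$n_phyla)) {
    for (f in seq_len(cfg$families_per_phylum)) {
      for (k in seq_len(cfg$genera_per_family)) {
        g <- g + 1L
        rows[[g]] <- data.frame(
          phylum = sprintf("p%02d", p),
          class = sprintf("p%02d_c1", p),
          order = sprintf("p%02d_o%02d", p, f),
          family = sprintf("p%02d_f%02d", p, f),
          genus = sprintf("g%02d", g),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Per-clade and per-phage-family first-order Markov composition models.
# Clades get evenly spaced GC contents plus a seeded dinucleotide
# perturbation, so clade compositions are distinct and recoverable.
composition_matrices <- function(cfg) {
  with_seed(substream_seed(cfg$seed, "sim.composition"), {
    n_clades <- cfg$n_phyla
    gc <- seq(0.35, 0.65, length.out = max(n_clades, 2))[seq_len(n_clades)]
    clade <- lapply(seq_len(n_clades), function(i)
      perturbed_markov(base_freq_gc(gc[i]), strength = 0.25))
    family <- lapply(seq_len(cfg$n_phage_families), function(i)
      perturbed_markov(base_freq_gc(stats::runif(1, 0.35, 0.65)),
                       strength = 0.25))
    list(clade = clade, family = family)
  })
}

base_freq_gc <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                               G = gc / 2, T = (1 - gc) / 2)

perturbed_markov <- function(freq, strength = 0.25) {
  M <- matrix(rep(freq, each = 4), nrow = 4,
              dimnames = list(names(freq), names(freq)))
  noise <- matrix(stats::rlnorm(16, 0, strength), 4, 4)
  M <- M * noise
  M / rowSums(M)
}

stationary_freq <- function(M) {
  e <- eigen(t(M))
  v <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
  v / sum(v)
}

#' Simulate prophage sequence families at controlled divergence
#'
#' Each family consists of a random ancestor (length drawn from the bimodal
#' length mixture unless `length_bp` is given) plus descendants obtained by
#' i.i.d. substitutions at the stated per-site divergence; indels are off by
#' default so pairwise identities are analytically predictable. The family
#' size `n_members` counts the ancestor, which is emitted first with the
#' lexicographically smallest member id. Optionally all family ancestors
#' descend from one common root mutated at `root_divergence / 2` per family,
#' so the expected inter-family divergence is about `root_divergence`.
#'
#' @param n_families number of families.
#' @param n_members members per family (ancestor included); scalar or vector.
#' @param divergence per-site substitution probability of each descendant
#'   from its family ancestor, in `[0, 0.5)`; scalar or per-family vector.
#' @param length_bp ancestor length(s); `NULL` draws from `config`'s length
#'   mixture.
#' @param root_divergence `NULL` for independent ancestors, or a pairwise
#'   inter-family divergence target.
#' @param indel_rate per-site probability of a 1-bp deletion in descendants
#'   (default 0).
#' @param seed integer seed.
#' @param config a [simulation_config()] supplying the length mixture.
#' @return List with `seqs` (named character vector, ids `F01_S00` for the
#'   ancestor of family 1, `F01_S01` ... for descendants) and `truth` (data
#'   frame `member_id`, `family`, `is_ancestor`).
#' @export
simulate_cluster_families <- function(n_families, n_members, divergence,
                                      length_bp = NULL, root_divergence = NULL,
                                      indel_rate = 0, seed = 1L,
                                      config = simulation_config()) {
  divergence <- rep_len(divergence, n_families)
  n_members <- rep_len(n_members, n_families)
  if (any(divergence < 0 | divergence >= 0.5))
    stop_input("divergence must lie in [0, 0.5)")
  with_seed(substream_seed(seed, "sim.families"), {
    lens <- if (is.null(length_bp)) {
      comp <- sample.int(2L, n_families, replace = TRUE,
                         prob = config$length_weights)
      pmax(5000L, round(stats::rnorm(n_families, config$length_means[comp],
                                     config$length_sds[comp])))
    } else rep_len(as.integer(length_bp), n_families)
    root <- if (!is.null(root_divergence))
      random_dna(max(lens)) else NULL
    seqs <- character(0)
    fam_id <- integer(0)
    anc_flag <- logical(0)
    for (f in seq_len(n_families)) {
      anc <- if (is.null(root)) random_dna(lens[f]) else
        mutate_dna(substr(root, 1, lens[f]), root_divergence / 2)
      members <- c(anc, vapply(seq_len(n_members[f] - 1L), function(i)
        mutate_dna(anc, divergence[f], indel_rate), character(1)))
      names(members) <- sprintf("F%02d_S%02d", f, seq_len(n_members[f]) - 1L)
      seqs <- c(seqs, members)
      fam_id <- c(fam_id, rep(f, n_members[f]))
      anc_flag <- c(anc_flag, c(TRUE, rep(FALSE, n_members[f] - 1L)))
    }
    list(seqs = seqs,
         truth = data.frame(member_id = names(seqs), family = fam_id,
                            is_ancestor = anc_flag, stringsAsFactors = FALSE))
  })
}

#' Uniform random DNA sequence (uses the current RNG state)
#' @param len length in bp.
#' @return A character scalar.
#' @export
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Mutate a DNA sequence by i.i.d. substitutions (and optional 1-bp deletions)
#'
#' Each site is substituted with probability `divergence` by one of the three
#' other bases, chosen uniformly; with `indel_rate > 0` sites are
#' independently deleted.
#'
#' @param seq character scalar.
#' @param divergence per-site substitution probability.
#' @param indel_rate per-site deletion probability.
#' @return Mutated character scalar (uses the current RNG state).
#' @export
mutate_dna <- function(seq, divergence, indel_rate = 0) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  hit <- which(stats::runif(n) < divergence)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1),
                   character(1))
    v[hit] <- repl
  }
  if (indel_rate > 0) {
    del <- stats::runif(length(v)) < indel_rate
    v <- v[!del]
  }
  paste(v, collapse = "")
}

#' Simulate Biosample-style free text for a pathogen or unassigned genome
#'
#' Pathogen labels always place at least one trigger phrase (e.g.
#' "pathogenic", "isolated from patient with pneumonia") in one of the six
#' metadata fields scanned by [classify_pathogen()]; unassigned labels place
#' none, so classification recovers the label by construction.
#'
#' @param label `"pathogen"` or `"unassigned"`.
#' @param seed integer seed.
#' @return Named character vector of Biosample fields.
#' @export
simulate_biosample_text <- function(label = c("pathogen", "unassigned"),
                                    seed = 1L) {
  label <- match.arg(label)
  neutral <- c("river water", "forest soil", "fermented food",
               "marine sediment", "rhizosphere sample", "dairy product",
               "activated sludge", "hot spring mat", "laboratory stock",
               "healthy adult volunteer")
  triggers <- c("pathogenic strain", "known pathogen",
                "isolated from patient with pneumonia",
                "blood of patient with sepsis",
                "diseased leaf tissue", "wound infection",
                "skin lesion swab", "clinical isolate from diseased cattle")
  fields <- c("general_description", "isolation_source", "isolation_site",
              "host", "environmental_medium", "sample_type")
  with_seed(seed, {
    n_fields <- sample(2:4, 1)
    chosen <- sample(fields, n_fields)
    txt <- sample(neutral, n_fields, replace = TRUE)
    names(txt) <- chosen
    if (label == "pathogen")
      txt[sample(seq_along(txt), 1)] <- sample(triggers, 1)
    txt
  })
}
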