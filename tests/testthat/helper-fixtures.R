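# Shared fixture builders and independent oracles.

# Independent one-sided Wilcoxon oracle: enumerate every assignment of the
# pooled values to the x-group and count pairwise wins directly (Mann-Whitney
# U via outer comparisons, not rank sums).
oracle_wilcox_greater <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(xv, yv) sum(outer(xv, yv, ">")) +
    0.5 * sum(outer(xv, yv, "=="))
  u_obs <- u_of(x, y)
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  mean(us >= u_obs - 1e-9)
}

# Hamming identity of two equal-length sequences (gap-free oracle).
hamming_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  mean(va == vb)
}

# Mutate a sequence at an exact set of positions (known mutation mask).
mutate_at <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in positions) v[p] <- sample(setdiff(bases, v[p]), 1)
  paste(v, collapse = "")
}

# Brute-force six-frame ORF counter, independent of find_orfs: translate each
# frame with Biostrings in one shot, then scan the protein string.
oracle_orf_count <- function(seq, min_aa = 33) {
  code <- Biostrings::getGeneticCode("11")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  total <- 0L
  for (s in c(seq, rc)) {
    for (off in 0:2) {
      sub <- substr(s, off + 1, nchar(s))
      sub <- substr(sub, 1, 3 * (nchar(sub) %/% 3))
      if (nchar(sub) < 3) next
      aa <- strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(sub), genetic.code = code,
        if.fuzzy.codon = "X")), "")[[1]]
      codons <- substring(sub, seq(1, nchar(sub) - 2, 3),
                          seq(3, nchar(sub), 3))
      stops <- which(aa == "*")
      for (m in which(codons == "ATG")) {
        nxt <- stops[stops > m]
        if (length(nxt) && nxt[1] - m >= min_aa) total <- total + 1L
      }
    }
  }
  total
}

# Build an orf_set directly from protein strings (bypasses DNA plumbing when
# testing protein-level operations).
mk_orf_set <- function(proteins, id) {
  structure(list(
    parent_id = id,
    proteins = data.frame(
      orf_id = sprintf("%s_orf%04d", id, seq_along(proteins)),
      frame = rep(1L, length(proteins)), start = rep(1L, length(proteins)),
      end = 3L * nchar(proteins), aa = proteins, stringsAsFactors = FALSE)),
    class = "orf_set")
}

amino_acids <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_protein <- function(n) paste(sample(amino_acids, n, TRUE),
                                    collapse = "")

mutate_protein <- function(p, d) {
  v <- strsplit(p, "")[[1]]
  hit <- which(stats::runif(length(v)) < d)
  for (i in hit) v[i] <- sample(setdiff(amino_acids, v[i]), 1)
  paste(v, collapse = "")
}

# Minimal in-memory catalog from per-genome counts; one 5 Mb replicon each.
mk_catalog <- function(genus, counts, biosample = NULL,
                       phylum = rep("pX", length(genus))) {
  n <- length(genus)
  hosts <- data.frame(
    genome_id = sprintf("G%04d", seq_len(n)),
    phylum = phylum, class = paste0(phylum, "_c"),
    order = paste0(phylum, "_o"), family = paste0(phylum, "_f"),
    genus = genus, genome_size_bp = 5e6, stringsAsFactors = FALSE)
  hosts$biosample <- if (is.null(biosample))
    replicate(n, character(0), simplify = FALSE) else biosample
  np <- sum(counts)
  pro <- data.frame(
    prophage_id = sprintf("P%05d", seq_len(np)),
    genome_id = rep(hosts$genome_id, counts),
    replicon_id = rep("chr1", np),
    start = rep(1000L, np), end = rep(30999L, np),
    category = rep(1L, np), plasmid_flag = rep(FALSE, np),
    length = rep(30000L, np), sequence = rep(NA_character_, np),
    stringsAsFactors = FALSE)
  structure(list(
    hosts = hosts,
    replicons = data.frame(genome_id = hosts$genome_id,
                           replicon_id = "chr1", replicon_length_bp = 5e6,
                           stringsAsFactors = FALSE),
    prophages = pro), class = "prophage_catalog")
}

# Write a small well-formed catalog (3 genomes, 5 prophages) to temp TSVs.
write_toy_tables <- function(dir = tempfile("toy_"),
                             bad_genome_ref = FALSE,
                             break_nestedness = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  host <- data.frame(
    genome_id = c("G1", "G1", "G2", "G3"),
    phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
               if (break_nestedness) "Firmicutes" else "Proteobacteria"),
    class = "Gammaproteobacteria",
    order = "Enterobacterales",
    family = "Enterobacteriaceae",
    genus = c("Escherichia", "Escherichia", "Salmonella",
              if (break_nestedness) "Escherichia" else "Salmonella"),
    genome_size_bp = c(5009000, 5009000, 4800000, 4500000),
    replicon_id = c("chr1", "plas1", "chr1", "chr1"),
    replicon_length_bp = c(5000000, 9000, 4800000, 4500000),
    biosample_json = c(
      '{"isolation_source":"blood of patient with sepsis"}',
      '{"isolation_source":"blood of patient with sepsis"}',
      "{}", '{"environmental_medium":"forest soil"}'),
    stringsAsFactors = FALSE)
  pro <- data.frame(
    prophage_id = paste0("P", 1:5),
    genome_id = c("G1", "G1", if (bad_genome_ref) "GX" else "G2",
                  "G2", "G3"),
    replicon_id = c("chr1", "plas1", "chr1", "chr1", "chr1"),
    start = c(1001, 1, 2001, 100001, 5001),
    end = c(41000, 8000, 52000, 130000, 35000),
    category = c(1, 1, 2, 3, 1),
    plasmid_flag = c("false", "true", "false", "false", "false"),
    stringsAsFactors = FALSE)
  hp <- file.path(dir, "hosts.tsv")
  pp <- file.path(dir, "prophages.tsv")
  write.table(host, hp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pro, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(hosts = hp, prophages = pp)
}

table1_fixture_path <- function() {
  system.file("extdata", "multihost_vc_hosts.tsv", package = "prophagecomp")
}
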