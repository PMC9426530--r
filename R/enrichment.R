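#' One-sided Wilcoxon rank-sum p-value (alternative: x greater)
#'
#' Exact p by exhaustive enumeration of all group assignments (ties included,
#' so it is the conditional permutation distribution of the rank sum) when
#' both groups have at most `exact_max` observations; otherwise the mid-rank
#' normal approximation with tie correction and no continuity correction.
#'
#' @param x,y numeric vectors; the alternative is that `x` tends greater.
#' @param exact_max largest group size for which enumeration is used
#'   (default 8).
#' @return p-value in `[0, 1]`.
#' @export
wilcox_greater <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop_input("both groups must be non-empty")
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    sums <- utils::combn(n1 + n2, n1, FUN = function(i) sum(r[i]))
    return(mean(sums >= obs - 1e-9))
  }
  n <- n1 + n2
  u <- obs - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  stats::pnorm((u - mu) / sqrt(sigma2), lower.tail = FALSE)
}

#' Host genome size versus prophage abundance
#'
#' Bins genomes on a fixed Mb grid and reports per-bin total and mean
#' prophage counts for all prophages and for the subset of length at least
#' `min_length_bp`, plus the Spearman correlation between genome size and
#' per-genome prophage count.
#'
#' @param catalog a filtered `prophage_catalog`.
#' @param bin_mb bin width in Mb.
#' @param min_length_bp length cutoff for the long-prophage series (set
#'   `NULL` to skip).
#' @return List with `bins` (data frame), `rho`, `p_value`, `n_genomes`, and
#'   `correlation_defined` (`FALSE`, with `rho = NA`, below 3 genomes).
#' @export
size_abundance <- function(catalog, bin_mb = 1, min_length_bp = 30000) {
  hosts <- catalog$hosts
  records <- catalog$prophages
  counts <- per_genome_counts(hosts, records)
  long_counts <- if (is.null(min_length_bp)) NULL else
    per_genome_counts(hosts, records[records$length >= min_length_bp, ,
                                     drop = FALSE])
  bin <- floor(hosts$genome_size_bp / 1e6 / bin_mb) * bin_mb
  agg <- function(v) c(total = sum(v), mean = mean(v))
  bins <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    row <- data.frame(bin_mb = b, n_genomes = sum(i),
                      total = sum(counts[i]), mean = mean(counts[i]))
    if (!is.null(long_counts)) {
      row$total_long <- sum(long_counts[i])
      row$mean_long <- mean(long_counts[i])
    }
    row
  }))
  ok <- nrow(hosts) >= 3
  ct <- if (ok) suppressWarnings(
    stats::cor.test(hosts$genome_size_bp, counts, method = "spearman",
                    exact = FALSE)) else NULL
  list(bins = bins,
       rho = if (ok) unname(ct$estimate) else NA_real_,
       p_value = if (ok) ct$p.value else NA_real_,
       n_genomes = nrow(hosts), correlation_defined = ok)
}

#' Taxon-level prophage enrichment at one taxonomy rank
#'
#' Tests every taxon at the given rank represented by at least `min_genomes`
#' genomes; taxa with more than `cap_trigger` genomes are first downsampled
#' to `cap_sample` genomes (deterministic given `seed`). Each taxon's
#' per-genome prophage counts are compared against the remaining retained
#' genomes' counts with a one-sided (greater) Wilcoxon rank-sum test, and
#' p-values are Bonferroni-adjusted across the taxa tested at that rank. The
#' background excludes the focal taxon's genomes by default
#' (`background = "include"` keeps them in, i.e. each group is compared
#' against the entire distribution).
#'
#' @param catalog a filtered `prophage_catalog`.
#' @param rank one of phylum, class, order, family, genus.
#' @param min_genomes minimum genomes for a taxon to be tested (default 5).
#' @param cap_trigger,cap_sample downsampling rule: taxa above `cap_trigger`
#'   genomes are subsampled to `cap_sample`.
#' @param seed integer seed for the subsampling.
#' @param exclude_taxon optional taxon name (any rank) whose genomes are
#'   removed before testing, e.g. to re-test without a dominant clade.
#' @param background `"exclude"` (default) or `"include"` the focal taxon in
#'   the background distribution.
#' @return Data frame with columns `taxon`, `rank`, `n_genomes`,
#'   `n_prophages`, `mean_count`, `p_value`, `p_adjusted`, `direction`.
#' @export
rank_enrichment <- function(catalog,
                            rank = c("genus", "family", "order", "class",
                                     "phylum"),
                            min_genomes = 5L, cap_trigger = 50L,
                            cap_sample = 10L, seed = 1L,
                            exclude_taxon = NULL,
                            background = c("exclude", "include")) {
  rank <- match.arg(rank)
  background <- match.arg(background)
  hosts <- catalog$hosts
  if (!is.null(exclude_taxon)) {
    drop <- hosts$phylum == exclude_taxon | hosts$class == exclude_taxon |
      hosts$order == exclude_taxon | hosts$family == exclude_taxon |
      hosts$genus == exclude_taxon
    hosts <- hosts[!drop, , drop = FALSE]
  }
  counts <- per_genome_counts(hosts, catalog$prophages)
  tax <- hosts[[rank]]
  sizes <- table(tax)
  tested <- names(sizes)[sizes >= min_genomes]
  if (length(tested) < 2)
    stop_input("rank '%s' has fewer than 2 taxa with >= %d genomes",
               rank, min_genomes)

  keep <- rep(FALSE, nrow(hosts))
  for (tx in tested) {
    i <- which(tax == tx)
    if (length(i) > cap_trigger) {
      i <- with_seed(substream_seed(seed, paste0("rank.cap.", rank, ".", tx)),
                     sample(i, cap_sample))
    }
    keep[i] <- TRUE
  }
  counts <- counts[keep]
  tax <- tax[keep]

  res <- do.call(rbind, lapply(tested, function(tx) {
    focal <- counts[tax == tx]
    bg <- if (background == "exclude") counts[tax != tx] else counts
    data.frame(taxon = tx, rank = rank,
               n_genomes = length(focal), n_prophages = sum(focal),
               mean_count = mean(focal),
               p_value = wilcox_greater(focal, bg),
               stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- pmin(1, res$p_value * nrow(res))
  res$direction <- "greater"
  res[order(res$p_value, res$taxon), ]
}

#' Bootstrap genus-level enrichment p-value distributions
#'
#' At each iteration, samples `n_genomes` genomes without replacement from
#' every eligible genus, then tests each genus's per-genome counts against
#' the pooled remainder of that iteration's sample with a one-sided Wilcoxon
#' test. Eligible genera have at least `min_genus_genomes` genomes (and at
#' least `n_genomes`); smaller genera are reported as skipped. Iterations use
#' independent substreams of the master seed, so the run is deterministic.
#'
#' @param catalog a filtered `prophage_catalog`.
#' @param n_genomes genomes sampled per genus per iteration (default 10).
#' @param n_iter number of iterations (default 100).
#' @param seed integer master seed.
#' @param min_genus_genomes eligibility threshold (default 50; lower it for
#'   small catalogs).
#' @return List of class `bootstrap_result`: `p_matrix` (genera x iterations),
#'   `summary` (per-genus quantiles of the p-values), `skipped` (ineligible
#'   genera), `n_genomes`, `n_iter`.
#' @export
bootstrap_enrichment <- function(catalog, n_genomes = 10L, n_iter = 100L,
                                 seed = 1L, min_genus_genomes = 50L) {
  hosts <- catalog$hosts
  counts <- per_genome_counts(hosts, catalog$prophages)
  sizes <- table(hosts$genus)
  need <- max(n_genomes, min_genus_genomes)
  eligible <- names(sizes)[sizes >= need]
  skipped <- setdiff(names(sizes), eligible)
  if (length(eligible) == 0)
    stop_input("no genus has >= %d genomes", need)
  idx_by_genus <- split(seq_len(nrow(hosts)), hosts$genus)[eligible]

  p <- matrix(NA_real_, nrow = length(eligible), ncol = n_iter,
              dimnames = list(eligible, NULL))
  for (it in seq_len(n_iter)) {
    sel <- with_seed(substream_seed(seed, paste0("boot.", it)),
      lapply(idx_by_genus, function(i) sample(i, n_genomes)))
    iter_counts <- lapply(sel, function(i) counts[i])
    pooled <- unlist(iter_counts, use.names = FALSE)
    for (g in seq_along(eligible)) {
      focal <- iter_counts[[g]]
      bg <- pooled[-(((g - 1) * n_genomes + 1):(g * n_genomes))]
      p[g, it] <- wilcox_greater(focal, bg)
    }
  }
  summary <- t(apply(p, 1, stats::quantile,
                     probs = c(0.05, 0.25, 0.5, 0.75, 0.95)))
  structure(list(p_matrix = p, summary = summary, skipped = skipped,
                 n_genomes = n_genomes, n_iter = n_iter),
            class = "bootstrap_result")
}

#' Spearman correlation between two per-genus count vectors
#'
#' For comparing prophages-per-genus against e.g. reported-phages-per-genus
#' or genomes-per-genus. Vectors must be aligned (same genera, same order).
#'
#' @param x_counts,y_counts numeric vectors of equal length (>= 3).
#' @return List with `rho`, `p_value`, `n`.
#' @export
count_count_correlation <- function(x_counts, y_counts) {
  if (length(x_counts) != length(y_counts))
    stop_input("count vectors differ in length (%d vs %d)",
               length(x_counts), length(y_counts))
  if (length(x_counts) < 3)
    stop_input("need at least 3 genera for a correlation")
  ct <- suppressWarnings(stats::cor.test(x_counts, y_counts,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x_counts))
}
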