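#' Average amino-acid identity between two proteomes
#'
#' AAI is 100 times the mean identity over the reciprocal-best-hit putative
#' homologs of the two ORF sets; it is undefined (`NA`) with zero homolog
#' pairs.
#'
#' @param orfs_a,orfs_b `orf_set` objects from [find_orfs()].
#' @param ... passed to [rbh_orthologs()].
#' @return List with `aai` (percent, `NA` when undefined) and `n_orthologs`.
#' @export
aai_pair <- function(orfs_a, orfs_b, ...) {
  hits <- rbh_orthologs(orfs_a, orfs_b, ...)
  if (nrow(hits) == 0) return(list(aai = NA_real_, n_orthologs = 0L))
  list(aai = 100 * mean(hits$identity), n_orthologs = nrow(hits))
}

#' Build the AAI relatedness network over a set of prophages
#'
#' Computes all-vs-all AAI (typically over cluster representatives, the
#' dereplicated set) and keeps edges with AAI at or above the threshold.
#' Nodes are restricted to prophages with at least one retained edge by
#' default, matching the usual "retrieved" network set; edges are
#' deduplicated unordered pairs and self-edges are never formed.
#'
#' @param orf_sets named list of `orf_set` objects (names = prophage ids).
#' @param lineages data frame with `prophage_id` plus host lineage columns
#'   `phylum` ... `genus`.
#' @param threshold minimum AAI percent for an edge (default 80).
#' @param connected_only drop isolated nodes (default `TRUE`).
#' @param ... passed to [rbh_orthologs()].
#' @return Object of class `aai_network`: list with `nodes` (data frame) and
#'   `edges` (data frame `a`, `b`, `aai`, `n_orthologs`).
#' @export
build_network <- function(orf_sets, lineages, threshold = 80,
                          connected_only = TRUE, ...) {
  ids <- names(orf_sets)
  if (length(ids) < 2) stop_input("need at least 2 prophages for a network")
  rows <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      p <- aai_pair(orf_sets[[i]], orf_sets[[j]], ...)
      if (!is.na(p$aai) && p$aai >= threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          a = ids[i], b = ids[j], aai = p$aai,
          n_orthologs = p$n_orthologs, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(0), b = character(0), aai = numeric(0),
               n_orthologs = integer(0), stringsAsFactors = FALSE)
  keep <- if (connected_only) ids[ids %in% c(edges$a, edges$b)] else ids
  nodes <- lineages[match(keep, lineages$prophage_id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "aai_network")
}

#' Fraction of network edges whose hosts differ at each taxonomy rank
#'
#' For every rank from genus up to phylum, the fraction of edges whose two
#' endpoint hosts differ at that rank (and the complementary same-rank
#' fraction). Under nested taxonomy the differ-at fractions are
#' non-increasing from genus to phylum.
#'
#' @param network an `aai_network` with lineages on every node; all-node
#'   lineage lookup uses the full lineage table passed at build time.
#' @param lineages optional lineage table overriding the network's node
#'   table (data frame with `prophage_id`, `phylum` ... `genus`).
#' @return Data frame `rank`, `n_edges`, `fraction_different`,
#'   `fraction_same`, ordered genus, family, order, class, phylum.
#' @export
fraction_by_rank <- function(network, lineages = NULL) {
  edges <- network$edges
  if (nrow(edges) == 0) stop_input("network has no edges")
  li <- lineages %||% network$nodes
  ia <- match(edges$a, li$prophage_id)
  ib <- match(edges$b, li$prophage_id)
  if (any(is.na(ia)) || any(is.na(ib)))
    stop_input("every edge endpoint needs a lineage")
  ranks <- c("genus", "family", "order", "class", "phylum")
  do.call(rbind, lapply(ranks, function(r) {
    diff <- li[[r]][ia] != li[[r]][ib]
    data.frame(rank = r, n_edges = nrow(edges),
               fraction_different = mean(diff),
               fraction_same = mean(!diff), stringsAsFactors = FALSE)
  }))
}

#' Mean shared-ortholog count over edges connecting two host phyla
#'
#' @param network an `aai_network`.
#' @param phylum_a,phylum_b host phylum names; qualifying edges have one
#'   endpoint hosted in each.
#' @param lineages optional lineage override as in [fraction_by_rank()].
#' @return List with `mean_orthologs` (`NA` with zero qualifying edges) and
#'   `n_edges`.
#' @export
shared_ortholog_summary <- function(network, phylum_a, phylum_b,
                                    lineages = NULL) {
  edges <- network$edges
  li <- lineages %||% network$nodes
  pa <- li$phylum[match(edges$a, li$prophage_id)]
  pb <- li$phylum[match(edges$b, li$prophage_id)]
  hit <- (pa == phylum_a & pb == phylum_b) |
    (pa == phylum_b & pb == phylum_a)
  if (!any(hit)) return(list(mean_orthologs = NA_real_, n_edges = 0L))
  list(mean_orthologs = round(mean(edges$n_orthologs[hit]), 2),
       n_edges = sum(hit))
}

#' Host-ANI versus prophage-AAI co-structure within one host genus
#'
#' Builds the host ANI matrix and the prophage AAI matrix, clusters both by
#' average linkage on (1 - similarity), cuts at the stated heights, and
#' scores congruence: the fraction of prophage pairs whose AAI-cluster
#' comembership matches their hosts' ANI-cluster comembership. A congruence
#' of 1 means the prophage relatedness structure exactly tracks the host
#' subclades.
#'
#' @param host_seqs named character vector of host genome sequences (>= 3
#'   hosts).
#' @param prophage_orfs named list of `orf_set` objects.
#' @param prophage_hosts named character vector mapping prophage id to host
#'   genome id (every host carries >= 1 prophage).
#' @param cut_host,cut_phage dissimilarity cut heights for the two
#'   dendrograms (defaults 0.05 and 0.2, i.e. 95% ANI / 80% AAI).
#' @param ... passed to [ani()] / [rbh_orthologs()] as named arguments via
#'   `ani_args` and `aai_args`.
#' @param ani_args,aai_args lists of extra arguments.
#' @return List with `ani_matrix` (percent), `aai_matrix` (percent),
#'   `host_clusters`, `phage_clusters`, `congruence`, and `pairs` (per
#'   prophage pair, the two comembership indicators).
#' @export
ani_aai_costructure <- function(host_seqs, prophage_orfs, prophage_hosts,
                                cut_host = 0.05, cut_phage = 0.2,
                                ani_args = list(), aai_args = list()) {
  if (length(host_seqs) < 3) stop_input("need at least 3 host genomes")
  hn <- names(host_seqs)
  if (!all(prophage_hosts %in% hn))
    stop_input("every prophage must map to a supplied host genome")
  if (!all(hn %in% prophage_hosts))
    stop_input("every host must carry at least one prophage")
  nh <- length(hn)
  ANI <- matrix(100, nh, nh, dimnames = list(hn, hn))
  for (i in seq_len(nh - 1)) for (j in (i + 1):nh) {
    v <- do.call(ani, c(list(host_seqs[[i]], host_seqs[[j]]), ani_args))
    ANI[i, j] <- ANI[j, i] <- ifelse(is.na(v), 0, v)
  }
  pn <- names(prophage_orfs)
  np <- length(pn)
  AAI <- matrix(100, np, np, dimnames = list(pn, pn))
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    p <- do.call(aai_pair, c(list(prophage_orfs[[i]], prophage_orfs[[j]]),
                             aai_args))
    AAI[i, j] <- AAI[j, i] <- ifelse(is.na(p$aai), 0, p$aai)
  }
  hc_host <- stats::hclust(stats::as.dist(1 - ANI / 100), method = "average")
  hc_phage <- stats::hclust(stats::as.dist(1 - AAI / 100), method = "average")
  host_cl <- stats::cutree(hc_host, h = cut_host)
  phage_cl <- stats::cutree(hc_phage, h = cut_phage)
  host_of <- prophage_hosts[pn]
  pair_idx <- utils::combn(np, 2)
  same_phage <- phage_cl[pair_idx[1, ]] == phage_cl[pair_idx[2, ]]
  same_host <- host_cl[host_of[pair_idx[1, ]]] ==
    host_cl[host_of[pair_idx[2, ]]]
  list(ani_matrix = ANI, aai_matrix = AAI,
       host_clusters = host_cl, phage_clusters = phage_cl,
       congruence = mean(same_phage == same_host),
       pairs = data.frame(a = pn[pair_idx[1, ]], b = pn[pair_idx[2, ]],
                          same_phage_cluster = same_phage,
                          same_host_cluster = same_host,
                          stringsAsFactors = FALSE))
}

#' Export an AAI network as plain-text edge and node tables
#'
#' @param network an `aai_network`.
#' @param edge_path,node_path output TSV paths.
#' @return Invisibly, the paths.
#' @export
write_network <- function(network, edge_path, node_path) {
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edge_path, node_path))
}
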