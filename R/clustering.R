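#' Greedy representative-based clustering of prophage sequences
#'
#' Sequences are processed by decreasing length (ties by id, lexicographic);
#' each sequence joins the first existing cluster whose representative it
#' matches at both the identity and coverage thresholds, otherwise it founds
#' a new cluster with itself as representative — the greedy incremental
#' semantics of cd-hit-style tools, which makes the result deterministic and
#' independent of input record order.
#'
#' @param seqs named character vector of nucleotide sequences, or a
#'   `prophage_catalog` whose prophages all carry sequences.
#' @param id_threshold minimum identity to the representative (default 0.90).
#' @param cov_threshold minimum coverage of the shorter sequence (default
#'   0.80).
#' @param min_sketch_hits candidate prefilter: a sequence is aligned against
#'   a representative only when their bottom-64 minhash sketches of 11-mers
#'   share at least this many values (default 3). Pairs anywhere near the
#'   default thresholds share tens of sketch values, while unrelated pairs
#'   share none, so the filter only skips hopeless alignments; set to 0 to
#'   align every pair.
#' @param min_seed_votes forwarded to [pairwise_identity()]; the clustering
#'   default (30) is higher than the alignment default because any pair near
#'   the 90%/80% thresholds seeds a diagonal with hundreds of shared words,
#'   while same-composition non-homologs reach only a handful.
#' @param ... passed to [pairwise_identity()].
#' @return Object of class `viral_clusters`: a list with `membership` (data
#'   frame `vc_id`, `member`, `representative`, `identity`, `coverage` — the
#'   stored evidence) and `thresholds`.
#' @export
greedy_cluster <- function(seqs, id_threshold = 0.90, cov_threshold = 0.80,
                           min_sketch_hits = 3L, min_seed_votes = 30L, ...) {
  if (inherits(seqs, "prophage_catalog")) {
    if (any(is.na(seqs$prophages$sequence)))
      stop_input("all prophages must carry sequences for clustering")
    seqs <- stats::setNames(seqs$prophages$sequence,
                            seqs$prophages$prophage_id)
  }
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  sketches <- lapply(seqs, kmer_sketch_cpp)
  reps <- character(0)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      if (min_sketch_hits > 0 &&
          sum(sketches[[i]] %in% sketches[[reps[ci]]]) < min_sketch_hits)
        next
      st <- pairwise_identity(seqs[[i]], seqs[[reps[ci]]],
                              min_seed_votes = min_seed_votes, ...)
      if (st$identity >= id_threshold && st$coverage >= cov_threshold) {
        rows[[i]] <- data.frame(vc = ci, member = names(seqs)[i],
                                identity = st$identity,
                                coverage = st$coverage,
                                stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, names(seqs)[i])
      rows[[i]] <- data.frame(vc = length(reps), member = names(seqs)[i],
                              identity = 1, coverage = 1,
                              stringsAsFactors = FALSE)
    }
  }
  mem <- do.call(rbind, rows)
  membership <- data.frame(
    vc_id = sprintf("VC_%04d", mem$vc),
    member = mem$member,
    representative = reps[mem$vc],
    identity = mem$identity, coverage = mem$coverage,
    stringsAsFactors = FALSE)
  structure(list(membership = membership,
                 thresholds = c(identity = id_threshold,
                                coverage = cov_threshold)),
            class = "viral_clusters")
}

#' @export
print.viral_clusters <- function(x, ...) {
  n <- length(unique(x$membership$vc_id))
  cat(sprintf("%d viral clusters over %d prophages (>=%.0f%% id, >=%.0f%% cov)\n",
              n, nrow(x$membership), 100 * x$thresholds["identity"],
              100 * x$thresholds["coverage"]))
  invisible(x)
}

host_ranks <- c("phylum", "class", "order", "family", "genus")

#' Classify the host range of one viral cluster
#'
#' Returns `"same-genus"` when all member hosts share the genus; otherwise
#' the highest taxonomy rank at which the member lineages differ — hosts in
#' different genera within one family classify as `"genus"`, different
#' families within one order as `"family"`, and so on up to `"phylum"`.
#'
#' @param lineages data frame of member-host lineages with columns `phylum`,
#'   `class`, `order`, `family`, `genus` (one row per member).
#' @return One of `"same-genus"`, `"genus"`, `"family"`, `"order"`,
#'   `"class"`, `"phylum"`.
#' @export
classify_host_range <- function(lineages) {
  need <- host_ranks
  if (!all(need %in% names(lineages)))
    stop_input("lineages must carry columns %s", paste(need, collapse = ", "))
  if (nrow(lineages) == 0 ||
      any(is.na(lineages[need]) | lineages[need] == ""))
    stop_input("every member host needs a complete lineage")
  for (r in host_ranks) {
    if (length(unique(lineages[[r]])) > 1) return(r)
  }
  "same-genus"
}

#' Host-range summary over a set of viral clusters
#'
#' Classifies every cluster's host range and reports the fraction of
#' clusters whose members all share the host genus (the headline fraction),
#' the same fraction counted over clustered prophages, per-rank counts, and
#' a table of the multi-genus clusters with their member composition and —
#' when host genome sequences are supplied — the mean fragment-ANI between
#' per-genus representative host genomes.
#'
#' @param clusters a `viral_clusters` object.
#' @param hosts host data frame with lineages (`genome_id`, `phylum` ...
#'   `genus`).
#' @param prophage_hosts named character vector mapping prophage id to
#'   `genome_id`.
#' @param host_seqs optional named character vector of host genome sequences
#'   for the ANI column.
#' @param ... passed to [ani()].
#' @return List with `n_vcs`, `n_multi_host`, `fraction_same_genus`,
#'   `fraction_same_genus_prophages`, `per_rank_counts`, `vc_ranks` (per-VC
#'   classification) and `multi_host_table`.
#' @export
host_range_report <- function(clusters, hosts, prophage_hosts,
                              host_seqs = NULL, ...) {
  mem <- clusters$membership
  gid <- prophage_hosts[mem$member]
  if (any(is.na(gid)))
    stop_input("missing host assignment for prophage(s): %s",
               paste(utils::head(mem$member[is.na(gid)], 3), collapse = ", "))
  li <- hosts[match(gid, hosts$genome_id), host_ranks]
  vcs <- split(seq_len(nrow(mem)), mem$vc_id)
  rank_of <- vapply(vcs, function(i) classify_host_range(li[i, , drop = FALSE]),
                    character(1))
  n_vcs <- length(vcs)
  same <- rank_of == "same-genus"
  n_members <- lengths(vcs)
  multi <- names(vcs)[!same]
  table_rows <- lapply(multi, function(vc) {
    i <- vcs[[vc]]
    comp <- sort(table(li$genus[i]), decreasing = TRUE)
    ani_val <- NA_real_
    if (!is.null(host_seqs)) {
      rep_genomes <- vapply(split(gid[i], li$genus[i]), `[`, character(1), 1)
      pairs <- utils::combn(unname(rep_genomes), 2)
      vals <- apply(pairs, 2, function(p)
        ani(host_seqs[[p[1]]], host_seqs[[p[2]]], ...))
      ani_val <- mean(vals, na.rm = TRUE)
    }
    data.frame(vc_id = vc,
               composition = paste(sprintf("%d %s", as.integer(comp),
                                           names(comp)), collapse = ", "),
               host_range_rank = rank_of[[vc]],
               n_members = length(i),
               host_ani = ani_val,
               stringsAsFactors = FALSE)
  })
  list(
    n_vcs = n_vcs,
    n_multi_host = sum(!same),
    fraction_same_genus = mean(same),
    fraction_same_genus_prophages = sum(n_members[same]) / sum(n_members),
    per_rank_counts = table(factor(rank_of,
                                   levels = c("same-genus", rev(host_ranks)))),
    vc_ranks = data.frame(vc_id = names(vcs), host_range_rank = unname(rank_of),
                          n_members = unname(n_members),
                          stringsAsFactors = FALSE),
    multi_host_table = if (length(table_rows)) do.call(rbind, table_rows) else
      data.frame(vc_id = character(0), composition = character(0),
                 host_range_rank = character(0), n_members = integer(0),
                 host_ani = numeric(0), stringsAsFactors = FALSE)
  )
}
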