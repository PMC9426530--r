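#' K-mer frequencies over all overlapping windows
#'
#' Counts every k-long window of the sequence (single strand) and divides by
#' the number of countable windows; windows containing non-ACGT symbols are
#' skipped and the denominator reduced accordingly, so the frequencies sum
#' to 1 over observed windows.
#'
#' @param seq nucleotide string of length >= k.
#' @param k word size.
#' @return Named numeric vector over all 4^k words (zeros included).
#' @export
kmer_frequencies <- function(seq, k) {
  if (nchar(seq) < k) stop_input("sequence shorter than k = %d", k)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(toupper(seq)), width = k, step = 1)
  tot <- sum(counts)
  if (tot == 0) stop_input("no countable ACGT window of width %d", k)
  counts / tot
}

#' K-mer usage bias profile
#'
#' The bias of a word is its observed frequency divided by an expectation
#' composed from sub-word frequencies of the same sequence. Two expectation
#' models are available: `markov_max` (default), the maximal-order Markov
#' expectation `f(w) = prod(f of (k-1)-subwords) / prod(f of interior
#' (k-2)-subwords)` — the standard contrast-word statistic — and
#' `literal_product`, the plain product of all (k-1)-subword frequencies.
#' The two coincide exactly at k = 2 (both reduce to `f(x) f(y)`). For k = 1
#' no sub-word expectation exists and the profile stores raw frequencies.
#' Words with zero expected frequency have undefined bias and are reported
#' as `NA`, not dropped.
#'
#' @param seq nucleotide string.
#' @param k word size, 1--4.
#' @param model `"markov_max"` or `"literal_product"`.
#' @param id profile label.
#' @param both_strands count the sequence and its reverse complement
#'   together (default `FALSE`: prophages are profiled in the reported
#'   orientation).
#' @return Object of class `kmer_bias_profile`: list with `id`, `k`,
#'   `model`, `bias` (named vector, `B(w) >= 0` or `NA`), `log_bias`
#'   (natural log; `-Inf` where `B = 0`).
#' @export
kmer_bias <- function(seq, k, model = c("markov_max", "literal_product"),
                      id = "seq", both_strands = FALSE) {
  model <- match.arg(model)
  if (!k %in% 1:4) stop_input("k must be 1, 2, 3 or 4")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(toupper(seq))))
    # counting both strands = averaging the two sequences' window counts;
    # join with a window-breaking separator
    seq <- paste(toupper(seq), rc, sep = "N")
  }
  f <- kmer_frequencies(seq, k)
  if (k == 1) {
    bias <- f
  } else {
    words <- names(f)
    sub1 <- kmer_frequencies(seq, k - 1)
    top <- vapply(words, function(w) {
      prod(sub1[substring(w, 1:2, (k - 1):k)])
    }, numeric(1))
    if (model == "markov_max" && k > 2) {
      sub2 <- kmer_frequencies(seq, k - 2)
      bottom <- vapply(words, function(w) {
        inner <- substring(w, 2, k - 1)
        sub2[[inner]]
      }, numeric(1))
      f_exp <- ifelse(bottom > 0, top / bottom, 0)
    } else {
      f_exp <- top
    }
    bias <- ifelse(f_exp > 0, f / f_exp, NA_real_)
    names(bias) <- words
  }
  structure(list(id = id, k = k, model = if (k == 1) "frequency" else model,
                 bias = bias, log_bias = suppressWarnings(log(bias))),
            class = "kmer_bias_profile")
}

#' Combine k-mer bias profiles of one sequence across word sizes
#'
#' Concatenates the log-bias vectors (names prefixed with the word size) so
#' distances can be taken over e.g. the joint di- plus tri-nucleotide usage.
#'
#' @param ... `kmer_bias_profile` objects for the same sequence.
#' @return A `kmer_bias_profile` with concatenated entries and `k` a vector.
#' @export
combine_bias_profiles <- function(...) {
  ps <- list(...)
  stopifnot(length(ps) >= 1)
  bias <- unlist(lapply(ps, function(p)
    stats::setNames(p$bias, paste0("k", p$k, ".", names(p$bias)))))
  structure(list(id = ps[[1]]$id, k = vapply(ps, `[[`, numeric(1), "k"),
                 model = ps[[1]]$model, bias = bias,
                 log_bias = suppressWarnings(log(bias))),
            class = "kmer_bias_profile")
}

#' Euclidean distance between two bias profiles
#'
#' Computed over the shared entries where both profiles have a finite log
#' bias; an error when no such entry exists. Symmetric, non-negative, zero
#' iff the shared entries are identical.
#'
#' @param p1,p2 `kmer_bias_profile` objects with the same word size(s).
#' @return Non-negative numeric distance.
#' @export
bias_distance <- function(p1, p2) {
  if (!identical(p1$k, p2$k))
    stop_input("profiles have different word sizes")
  shared <- intersect(names(p1$log_bias), names(p2$log_bias))
  ok <- shared[is.finite(p1$log_bias[shared]) &
                 is.finite(p2$log_bias[shared])]
  if (!length(ok)) stop_input("no shared defined bias entry")
  sqrt(sum((p1$log_bias[ok] - p2$log_bias[ok])^2))
}

#' Co-cluster phage and host bias profiles; rank candidate hosts per phage
#'
#' Agglomerative clustering (average linkage by default) of all profiles on
#' [bias_distance()], plus, for every phage, the candidate hosts sorted by
#' ascending profile distance — the profile-similarity heuristic for
#' phage--host association.
#'
#' @param phage_profiles,host_profiles lists of `kmer_bias_profile` objects
#'   (at least 3 profiles in total).
#' @param linkage hclust agglomeration method (default "average").
#' @param cut_height optional height for flat cluster labels.
#' @return List with `hclust`, `clusters` (or `NULL` without `cut_height`),
#'   `distance` (full dist matrix), `nearest_host` (data frame `phage`,
#'   `host`, `distance`) and `host_ranking` (phage x host distance matrix).
#' @export
cocluster_profiles <- function(phage_profiles, host_profiles,
                               linkage = "average", cut_height = NULL) {
  all_p <- c(phage_profiles, host_profiles)
  if (length(all_p) < 3) stop_input("need at least 3 profiles")
  ids <- vapply(all_p, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_input("profile ids must be unique")
  n <- length(all_p)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- bias_distance(all_p[[i]], all_p[[j]])
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  clusters <- if (!is.null(cut_height)) stats::cutree(hc, h = cut_height)
    else NULL
  pid <- vapply(phage_profiles, `[[`, character(1), "id")
  hid <- vapply(host_profiles, `[[`, character(1), "id")
  ranking <- D[pid, hid, drop = FALSE]
  nearest <- data.frame(
    phage = pid,
    host = hid[apply(ranking, 1, which.min)],
    distance = apply(ranking, 1, min),
    stringsAsFactors = FALSE)
  list(hclust = hc, clusters = clusters, distance = D,
       nearest_host = nearest, host_ranking = ranking)
}

#' Write a log-bias profile matrix as TSV
#'
#' @param profiles list of `kmer_bias_profile` objects with identical
#'   entries.
#' @param path output TSV (rows = sequences, columns = words, values = log
#'   bias).
#' @return Invisibly, the path.
#' @export
write_bias_matrix <- function(profiles, path) {
  M <- do.call(rbind, lapply(profiles, function(p) p$log_bias))
  rownames(M) <- vapply(profiles, `[[`, character(1), "id")
  utils::write.table(data.frame(sequence_id = rownames(M), M,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
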