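dna_score_matrix <- function(match = 2, mismatch = -3) {
  ab <- c("A", "C", "G", "T", "N")
  S <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(S)[1:4] <- match
  S["N", "N"] <- mismatch # ambiguity never rewards
  S
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Pairwise local nucleotide identity and coverage
#'
#' Local alignment with affine gaps (defaults: match +2, mismatch -3, gap of
#' length L costs 5 + 2L). Identity is matches over aligned columns, internal
#' gaps counted and terminal gaps excluded; coverage is the fraction of the
#' shorter sequence spanned by the alignment — the semantics used by common
#' greedy clustering tools. Small problems are solved with the full dynamic
#' program; long pairs are aligned in a band around the best shared-k-mer
#' diagonal (long unrelated pairs with no shared word report an empty
#' alignment). The result is symmetric in the two arguments.
#'
#' @param seq_a,seq_b non-empty nucleotide strings (A/C/G/T/N).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param band half-width of the banded alignment for long pairs.
#' @param max_full_cells full dynamic programming is used when the product of
#'   the lengths is at most this (default 4e6).
#' @param seed_k word size for diagonal seeding of long pairs.
#' @param min_seed_votes minimum shared-word count on the best diagonal for a
#'   long pair to be aligned at all; below it the pair reports an empty
#'   alignment. Unrelated long sequences share only scattered words (a few
#'   per diagonal), while pairs anywhere near a clustering threshold share
#'   hundreds, so the default 8 only skips hopeless alignments.
#' @return List of class `alignment_stats`: `identity`, `coverage`,
#'   `aligned_length`, `score`, and the 1-based alignment spans (`a_start`,
#'   `a_end`, `b_start`, `b_end`; zeros when no alignment scored above 0).
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 2, mismatch = -3,
                              gap_open = -5, gap_extend = -2, band = 200L,
                              max_full_cells = 4e6, seed_k = 11L,
                              min_seed_votes = 8L) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop_input("sequences must be non-empty")
  swapped <- (nchar(seq_a) > nchar(seq_b)) ||
    (nchar(seq_a) == nchar(seq_b) && seq_a > seq_b)
  a <- if (swapped) seq_b else seq_a
  b <- if (swapped) seq_a else seq_b
  S <- dna_score_matrix(match, mismatch)
  la <- nchar(a); lb <- nchar(b)
  if (as.double(la) * lb <= max_full_cells) {
    r <- align_local_cpp(a, b, S, "ACGTN", gap_open, gap_extend, -1L, 0L)
  } else {
    seed <- seed_best_diagonal_cpp(a, b, seed_k)
    if (seed[2] < min_seed_votes) {
      r <- list(found = FALSE, score = 0, matches = 0L, cols = 0L,
                a_start = 0L, a_end = 0L, b_start = 0L, b_end = 0L)
    } else {
      r <- align_local_cpp(a, b, S, "ACGTN", gap_open, gap_extend,
                           as.integer(band), seed[1])
    }
  }
  shorter <- min(la, lb) # a is never longer than b
  span <- if (r$found) r$a_end - r$a_start + 1L else 0L
  out <- list(
    identity = if (r$found && r$cols > 0) r$matches / r$cols else 0,
    coverage = span / shorter,
    aligned_length = r$cols,
    score = r$score,
    a_start = if (swapped) r$b_start else r$a_start,
    a_end = if (swapped) r$b_end else r$a_end,
    b_start = if (swapped) r$a_start else r$b_start,
    b_end = if (swapped) r$a_end else r$b_end
  )
  class(out) <- "alignment_stats"
  out
}

#' Fragment-based average nucleotide identity (ANI)
#'
#' Chops `genome_a` into non-overlapping fragments of `fragment_bp`, aligns
#' each fragment locally to `genome_b`, keeps fragments aligning with
#' identity >= `min_frag_identity` and coverage >= `min_frag_coverage` of the
#' fragment, and reports 100 times the mean identity of the kept fragments —
#' the classic fragment-ANI recipe. `NA` (undefined) when no fragment passes.
#'
#' @param genome_a,genome_b nucleotide strings, both at least `fragment_bp`.
#' @param fragment_bp fragment length (default 1000).
#' @param min_frag_identity,min_frag_coverage fragment filters (defaults
#'   0.30 and 0.70).
#' @param ... passed to [pairwise_identity()].
#' @return ANI in percent, or `NA` when undefined.
#' @export
ani <- function(genome_a, genome_b, fragment_bp = 1000L,
                min_frag_identity = 0.30, min_frag_coverage = 0.70, ...) {
  la <- nchar(genome_a); lb <- nchar(genome_b)
  if (la < fragment_bp || lb < fragment_bp)
    stop_input("both genomes must be at least fragment_bp (%d) long",
               fragment_bp)
  n_frag <- la %/% fragment_bp
  ids <- vapply(seq_len(n_frag), function(i) {
    frag <- substr(genome_a, (i - 1) * fragment_bp + 1, i * fragment_bp)
    st <- pairwise_identity(frag, genome_b, ...)
    if (st$identity >= min_frag_identity && st$coverage >= min_frag_coverage)
      st$identity else NA_real_
  }, numeric(1))
  kept <- ids[!is.na(ids)]
  if (!length(kept)) return(NA_real_)
  100 * mean(kept)
}

#' Extract open reading frames from all six frames
#'
#' An ORF runs from a start codon to the next in-frame stop codon (the stop
#' must be present) and is kept when its translation, start codon included,
#' is at least `min_aa` residues. Overlapping and nested ORFs are allowed:
#' every qualifying start codon yields an ORF. Coordinates are 1-based
#' inclusive on the forward strand; frames are +1,+2,+3,-1,-2,-3 and results
#' are ordered by (frame, start within frame).
#'
#' @param seq nucleotide string.
#' @param min_aa minimum protein length in residues (default 33).
#' @param genetic_code NCBI genetic code id (default "11", bacterial; its 64
#'   codon translations match the standard code — the codes differ only in
#'   permitted start codons).
#' @param start_codons allowed start codons (default ATG; add GTG/TTG for
#'   alternative starts).
#' @param id parent sequence id used to form ORF ids.
#' @return List of class `orf_set`: `parent_id` and `proteins` (data frame
#'   `orf_id`, `frame`, `start`, `end`, `aa`). Empty `proteins` is legal.
#' @export
find_orfs <- function(seq, min_aa = 33L, genetic_code = "11",
                      start_codons = "ATG", id = "seq") {
  code <- Biostrings::getGeneticCode(genetic_code)
  seq <- toupper(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  L <- nchar(seq)
  rows <- list()
  frames <- list(`1` = seq, `2` = seq, `3` = seq,
                 `-1` = rc, `-2` = rc, `-3` = rc)
  offs <- c(1L, 2L, 3L, 1L, 2L, 3L)
  fr_names <- c(1L, 2L, 3L, -1L, -2L, -3L)
  for (fi in seq_along(frames)) {
    s <- frames[[fi]]
    off <- offs[fi]
    n_cod <- (nchar(s) - off + 1L) %/% 3L
    if (n_cod < 1) next
    starts <- off + 3L * (seq_len(n_cod) - 1L)
    codons <- substring(s, starts, starts + 2L)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X" # codons containing ambiguity
    stop_pos <- which(aa == "*")
    start_pos <- which(codons %in% start_codons)
    if (!length(stop_pos) || !length(start_pos)) next
    # next in-frame stop after each start (starts are never stops)
    nxt <- findInterval(start_pos, stop_pos) + 1L
    ok <- nxt <= length(stop_pos)
    sp <- start_pos[ok]
    st <- stop_pos[nxt[ok]]
    keep <- (st - sp) >= min_aa
    sp <- sp[keep]; st <- st[keep]
    if (!length(sp)) next
    aa_str <- paste(aa, collapse = "")
    prot <- substring(aa_str, sp, st - 1L)
    # map codon indices back to forward-strand coordinates (ORF includes
    # its stop codon in the reported span)
    s1 <- starts[sp]; s2 <- starts[st] + 2L
    rows[[length(rows) + 1L]] <- data.frame(
      frame = fr_names[fi],
      start = if (fr_names[fi] > 0) s1 else L - s2 + 1L,
      end = if (fr_names[fi] > 0) s2 else L - s1 + 1L,
      aa = prot, stringsAsFactors = FALSE)
  }
  proteins <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), start = integer(0), end = integer(0),
               aa = character(0), stringsAsFactors = FALSE)
  ord <- order(match(proteins$frame, fr_names), proteins$start)
  proteins <- proteins[ord, , drop = FALSE]
  proteins <- cbind(orf_id = sprintf("%s_orf%04d", id,
                                     seq_len(nrow(proteins))),
                    proteins, stringsAsFactors = FALSE)
  rownames(proteins) <- NULL
  structure(list(parent_id = id, proteins = proteins), class = "orf_set")
}

#' Reciprocal-best-hit putative orthologs between two protein sets
#'
#' All-vs-all local protein alignment with BLOSUM62 scoring (gap of length L
#' costs 10 + L by default). A pair is a putative homolog when each protein
#' is the other's best hit by score and the pair passes the identity and
#' shorter-protein coverage thresholds. Score ties resolve to the higher
#' identity, then the lexicographically smaller partner `orf_id`.
#'
#' @param orfs_a,orfs_b `orf_set` objects (either may be empty).
#' @param min_identity,min_coverage homolog thresholds (defaults 0.30, 0.70).
#' @param gap_open,gap_extend protein gap scores.
#' @return Data frame `orf_a`, `orf_b`, `identity` (possibly empty).
#' @export
rbh_orthologs <- function(orfs_a, orfs_b, min_identity = 0.30,
                          min_coverage = 0.70, gap_open = -10,
                          gap_extend = -1) {
  pa <- orfs_a$proteins; pb <- orfs_b$proteins
  empty <- data.frame(orf_a = character(0), orf_b = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(empty)
  B <- blosum62_matrix()
  ab <- paste(rownames(B), collapse = "")
  m <- align_all_pairs_cpp(pa$aa, pb$aa, B, ab, gap_open, gap_extend)
  best_of <- function(score, ident, ids) {
    # best column per row: max score, ties by identity then lexicographic id
    apply_rows <- seq_len(nrow(score))
    vapply(apply_rows, function(i) {
      s <- score[i, ]; idn <- ident[i, ]
      cand <- which(s == max(s))
      if (length(cand) > 1) cand <- cand[idn[cand] == max(idn[cand])]
      if (length(cand) > 1) cand <- cand[order(ids[cand])][1]
      cand[1]
    }, integer(1))
  }
  best_a <- best_of(m$score, m$identity, pb$orf_id)
  best_b <- best_of(t(m$score), t(m$identity), pa$orf_id)
  pairs <- which(best_b[best_a] == seq_len(nrow(pa)))
  if (!length(pairs)) return(empty)
  j <- best_a[pairs]
  keep <- m$identity[cbind(pairs, j)] >= min_identity &
    m$coverage[cbind(pairs, j)] >= min_coverage
  out <- data.frame(orf_a = pa$orf_id[pairs][keep],
                    orf_b = pb$orf_id[j][keep],
                    identity = m$identity[cbind(pairs, j)][keep],
                    stringsAsFactors = FALSE)
  out[order(out$orf_a), , drop = FALSE]
}
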