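#' Load a prophage catalog from TSV tables and an optional FASTA
#'
#' Reads the host-genome table (one row per replicon) and the
#' prophage-prediction table, validates cross-references, taxonomy nestedness
#' and coordinate bounds, and returns a catalog object used by all downstream
#' stages.
#'
#' The host table columns are `genome_id, phylum, class, order, family, genus,
#' genome_size_bp, replicon_id, replicon_length_bp, biosample_json`; the
#' prophage table columns are `prophage_id, genome_id, replicon_id, start,
#' end, category, plasmid_flag` (1-based inclusive coordinates on the named
#' replicon). Higher taxonomy ranks may be `"NA"` but genus must always be
#' set: catalogs are restricted to genomes assigned at least to genus level.
#'
#' @param prophage_table path to the prophage prediction TSV.
#' @param host_table path to the host/replicon TSV.
#' @param fasta optional path to a multi-FASTA with prophage sequences keyed
#'   by `prophage_id`; sequences are attached when given.
#' @return An object of class `prophage_catalog`: a list with data frames
#'   `hosts` (one row per genome, `biosample` as a list column of named
#'   character vectors), `replicons`, and `prophages`.
#' @export
load_catalog <- function(prophage_table, host_table, fasta = NULL) {
  ht <- utils::read.delim(host_table, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  pt <- utils::read.delim(prophage_table, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  need_h <- c("genome_id", "phylum", "class", "order", "family", "genus",
              "genome_size_bp", "replicon_id", "replicon_length_bp",
              "biosample_json")
  need_p <- c("prophage_id", "genome_id", "replicon_id", "start", "end",
              "category", "plasmid_flag")
  if (!all(need_h %in% names(ht)))
    stop_input("host table is missing column(s): %s",
               paste(setdiff(need_h, names(ht)), collapse = ", "))
  if (!all(need_p %in% names(pt)))
    stop_input("prophage table is missing column(s): %s",
               paste(setdiff(need_p, names(pt)), collapse = ", "))

  replicons <- data.frame(
    genome_id = ht$genome_id,
    replicon_id = ht$replicon_id,
    replicon_length_bp = as.integer(ht$replicon_length_bp),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(replicons[c("genome_id", "replicon_id")])
  if (any(dup))
    stop_input("duplicated replicon id within genome: %s",
               paste(unique(replicons$replicon_id[dup]), collapse = ", "))

  first <- !duplicated(ht$genome_id)
  hosts <- data.frame(
    genome_id = ht$genome_id[first],
    phylum = ht$phylum[first], class = ht$class[first],
    order = ht$order[first], family = ht$family[first],
    genus = ht$genus[first],
    genome_size_bp = as.numeric(ht$genome_size_bp[first]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(hosts$genus) | hosts$genus == "" | hosts$genus == "NA"))
    stop_input("every genome must carry a genus-level assignment; missing for: %s",
               paste(hosts$genome_id[is.na(hosts$genus) | hosts$genus == "" |
                                       hosts$genus == "NA"], collapse = ", "))
  if (any(!is.finite(hosts$genome_size_bp)) || any(hosts$genome_size_bp < 1))
    stop_input("genome_size_bp must be >= 1 for every genome")
  hosts$biosample <- lapply(ht$biosample_json[first], parse_biosample_json)
  validate_taxonomy_nested(hosts)

  prophages <- data.frame(
    prophage_id = pt$prophage_id,
    genome_id = pt$genome_id,
    replicon_id = pt$replicon_id,
    start = as.integer(pt$start),
    end = as.integer(pt$end),
    category = as.integer(pt$category),
    plasmid_flag = as_flag(pt$plasmid_flag),
    stringsAsFactors = FALSE
  )
  miss <- setdiff(prophages$genome_id, hosts$genome_id)
  if (length(miss))
    stop_input("prophage row references unknown genome_id: %s",
               paste(unique(miss), collapse = ", "))
  key <- paste(prophages$genome_id, prophages$replicon_id)
  rkey <- paste(replicons$genome_id, replicons$replicon_id)
  bad <- !(key %in% rkey)
  if (any(bad))
    stop_input("prophage %s references unknown replicon %s in genome %s",
               prophages$prophage_id[bad][1], prophages$replicon_id[bad][1],
               prophages$genome_id[bad][1])
  if (any(prophages$start < 1L) || any(prophages$start > prophages$end))
    stop_input("prophage coordinates must satisfy 1 <= start <= end")
  rlen <- replicons$replicon_length_bp[match(key, rkey)]
  if (any(prophages$end > rlen))
    stop_input("prophage %s extends past the end of its replicon",
               prophages$prophage_id[which(prophages$end > rlen)[1]])
  prophages$length <- prophages$end - prophages$start + 1L
  prophages$sequence <- NA_character_

  if (!is.null(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    hit <- match(prophages$prophage_id, names(seqs))
    prophages$sequence[!is.na(hit)] <-
      as.character(seqs[hit[!is.na(hit)]])
  }

  structure(list(hosts = hosts, replicons = replicons, prophages = prophages),
            class = "prophage_catalog")
}

parse_biosample_json <- function(x) {
  if (is.na(x) || x == "" || x == "{}") return(character(0))
  out <- jsonlite::fromJSON(x)
  vapply(out, as.character, character(1))
}

as_flag <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- v %in% c("true", "t", "1", "yes")
  bad <- !(v %in% c("true", "t", "1", "yes", "false", "f", "0", "no"))
  if (any(bad)) stop_input("unparseable plasmid_flag value: %s", v[bad][1])
  out
}

#' Validate taxonomy nestedness
#'
#' Rank order is fixed phylum > class > order > family > genus; equality at a
#' lower rank must imply equality at all higher ranks within one table.
#' Violations are errors listing the conflicting lineages.
#'
#' @param hosts host data frame with columns `phylum, class, order, family,
#'   genus`.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validate_taxonomy_nested <- function(hosts) {
  ranks <- c("phylum", "class", "order", "family", "genus")
  for (lo in 5:2) {
    hi <- ranks[lo - 1L]
    tab <- unique(hosts[, c(ranks[lo], hi)])
    dup <- tab[[1]][duplicated(tab[[1]])]
    if (length(dup)) {
      bad <- tab[tab[[1]] %in% dup, ]
      stop_input(
        "taxonomy is not nested: %s '%s' maps to multiple %s values (%s)",
        ranks[lo], bad[[1]][1], hi,
        paste(unique(bad[[2]][bad[[1]] == bad[[1]][1]]), collapse = " vs "))
    }
  }
  invisible(TRUE)
}

#' Filter prophage predictions
#'
#' Applies the catalog's prediction-confidence filters: keep only prophages on
#' replicons of at least `min_replicon_bp`, with predictor category in
#' `keep_categories`, and (by default) not tagged as plasmids. Record order is
#' preserved and the operation is idempotent.
#'
#' @param catalog a `prophage_catalog` (or a prophage data frame, in which
#'   case `replicons` must be supplied).
#' @param min_replicon_bp minimum replicon length in bp (default 10000).
#' @param keep_categories integer vector of predictor categories to keep
#'   (default `c(1, 2)`, the high-confidence classes).
#' @param drop_plasmid drop records whose prediction was tagged as a plasmid.
#' @param replicons replicon table when `catalog` is a bare data frame.
#' @return Same type as `catalog`, with only passing prophage records.
#' @export
filter_predictions <- function(catalog, min_replicon_bp = 10000,
                               keep_categories = c(1L, 2L),
                               drop_plasmid = TRUE, replicons = NULL) {
  is_cat <- inherits(catalog, "prophage_catalog")
  records <- if (is_cat) catalog$prophages else catalog
  replicons <- if (is_cat) catalog$replicons else replicons
  if (is.null(replicons)) stop_input("replicon table required for filtering")
  rkey <- paste(replicons$genome_id, replicons$replicon_id)
  rlen <- replicons$replicon_length_bp[
    match(paste(records$genome_id, records$replicon_id), rkey)]
  keep <- rlen >= min_replicon_bp & records$category %in% keep_categories
  if (drop_plasmid) keep <- keep & !records$plasmid_flag
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (is_cat) { catalog$prophages <- out; catalog } else out
}

#' Summarize a (filtered) prophage catalog
#'
#' A lysogen is a host genome carrying at least one prophage record. The mean
#' prophage count uses lysogens as denominator by default (set
#' `denominator = "all"` for a per-all-genomes average); the mode is taken
#' over lysogen counts with ties resolved to the smallest count, and the
#' coefficient of variation is `100 * sd/mean` over lysogen counts using the
#' sample (n-1) standard deviation.
#'
#' @param catalog a `prophage_catalog` with already-filtered records.
#' @param denominator `"lysogens"` (default) or `"all"`.
#' @return A list of class `catalog_summary` with fields `n_genomes`,
#'   `n_lysogens`, `lysogen_fraction`, `n_prophages`, `mean_per_lysogen`,
#'   `mode_per_lysogen`, `cv_percent`. With zero lysogens the mean, mode and
#'   CV are `NA` (undefined), not errors.
#' @export
summarize_catalog <- function(catalog, denominator = c("lysogens", "all")) {
  denominator <- match.arg(denominator)
  hosts <- catalog$hosts
  records <- catalog$prophages
  counts <- per_genome_counts(hosts, records)
  lys <- counts[counts > 0]
  n_lys <- length(lys)
  denom <- if (denominator == "lysogens") n_lys else nrow(hosts)
  out <- list(
    n_genomes = nrow(hosts),
    n_lysogens = n_lys,
    lysogen_fraction = n_lys / nrow(hosts),
    n_prophages = sum(counts),
    mean_per_lysogen = if (denom > 0) sum(counts) / denom else NA_real_,
    mode_per_lysogen = if (n_lys > 0) count_mode(lys) else NA_integer_,
    cv_percent = if (n_lys > 1 && mean(lys) > 0)
      100 * stats::sd(lys) / mean(lys) else NA_real_
  )
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf(
    "Prophage catalog: %d genomes, %d lysogens (%.2f%%), %d prophages\n",
    x$n_genomes, x$n_lysogens, 100 * x$lysogen_fraction, x$n_prophages))
  cat(sprintf("  per-lysogen count: mean %.2f, mode %s, CV %s%%\n",
              x$mean_per_lysogen,
              format(x$mode_per_lysogen),
              ifelse(is.na(x$cv_percent), "NA",
                     sprintf("%.1f", x$cv_percent))))
  invisible(x)
}

#' Per-genome prophage counts
#'
#' @param hosts host data frame.
#' @param records prophage data frame.
#' @return Named integer vector, one entry per genome (zeros included).
#' @export
per_genome_counts <- function(hosts, records) {
  counts <- integer(nrow(hosts))
  names(counts) <- hosts$genome_id
  tab <- table(records$genome_id)
  counts[names(tab)] <- as.integer(tab)
  counts
}

count_mode <- function(x) {
  tab <- table(x)
  vals <- as.integer(names(tab))
  vals[tab == max(tab)][1] # ties resolve to the smallest count
}

#' Binned prophage length distribution
#'
#' Bins prophage lengths on a fixed-width kb grid and reports the overall mean
#' length and up to two modal bins: the local maxima of the histogram with the
#' highest counts (no formal bimodality test is attempted).
#'
#' @param records prophage data frame with a `length` column, or a
#'   `prophage_catalog`.
#' @param bin_kb bin width in kb (default 5).
#' @return List with `histogram` (data frame `bin_start_kb`, `bin_mid_kb`,
#'   `count`), `mean_length`, and `modal_bins_kb` (bin start positions of the
#'   top one or two local maxima, ascending).
#' @export
length_distribution <- function(records, bin_kb = 5) {
  if (inherits(records, "prophage_catalog")) records <- records$prophages
  if (nrow(records) == 0) stop_input("length_distribution: no records")
  len_kb <- records$length / 1000
  lo <- floor(min(len_kb) / bin_kb) * bin_kb
  hi <- (floor(max(len_kb) / bin_kb) + 1) * bin_kb
  breaks <- seq(lo, hi, by = bin_kb)
  counts <- as.integer(table(cut(len_kb, breaks, right = FALSE,
                                 include.lowest = FALSE)))
  hist <- data.frame(bin_start_kb = breaks[-length(breaks)],
                     bin_mid_kb = breaks[-length(breaks)] + bin_kb / 2,
                     count = counts)
  n <- length(counts)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) counts[i - 1] else -1L
    right <- if (i < n) counts[i + 1] else -1L
    counts[i] > 0 && counts[i] >= left && counts[i] >= right
  }, logical(1))
  cand <- which(is_max)
  cand <- cand[order(-counts[cand], hist$bin_start_kb[cand])]
  modal <- sort(hist$bin_start_kb[utils::head(cand, 2)])
  list(histogram = hist, mean_length = mean(records$length),
       modal_bins_kb = modal)
}

#' Write host and prophage tables in the catalog TSV dialects
#'
#' @param catalog a `prophage_catalog`.
#' @param host_table,prophage_table,fasta output paths (`fasta` optional;
#'   written only when sequences are present).
#' @return Invisibly, the paths written.
#' @export
write_catalog <- function(catalog, host_table, prophage_table, fasta = NULL) {
  hosts <- catalog$hosts
  repl <- catalog$replicons
  i <- match(repl$genome_id, hosts$genome_id)
  ht <- data.frame(
    genome_id = repl$genome_id,
    phylum = hosts$phylum[i], class = hosts$class[i], order = hosts$order[i],
    family = hosts$family[i], genus = hosts$genus[i],
    genome_size_bp = format(hosts$genome_size_bp[i], scientific = FALSE,
                            trim = TRUE),
    replicon_id = repl$replicon_id,
    replicon_length_bp = repl$replicon_length_bp,
    biosample_json = vapply(hosts$biosample[i], function(b) {
      if (length(b) == 0) "{}" else
        as.character(jsonlite::toJSON(as.list(b), auto_unbox = TRUE))
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(ht, host_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pt <- catalog$prophages
  out <- pt[, c("prophage_id", "genome_id", "replicon_id", "start", "end",
                "category")]
  out$plasmid_flag <- ifelse(pt$plasmid_flag, "true", "false")
  utils::write.table(out, prophage_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(host_table, prophage_table)
  if (!is.null(fasta)) {
    has <- !is.na(pt$sequence)
    seqs <- Biostrings::DNAStringSet(pt$sequence[has])
    names(seqs) <- pt$prophage_id[has]
    Biostrings::writeXStringSet(seqs, fasta, width = 80)
    paths <- c(paths, fasta)
  }
  invisible(paths)
}
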