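#' Default pathogen keyword list
#'
#' Case-insensitive substring patterns matched against Biosample free text.
#' The rule declares a genome pathogenic when any field mentions a pathogen
#' outright or describes isolation from a diseased patient, animal or plant.
#' The list ships as explicit configuration because manual curation of
#' Biosample records is not reproducible verbatim; it is a documented
#' approximation that users can replace (see [read_keyword_config()]).
#'
#' @return Character vector of patterns.
#' @export
default_pathogen_keywords <- function() {
  c("pathogen", "pathogenic", "patient with", "diseased", "disease",
    "infection", "infected", "lesion", "clinical isolate")
}

#' Read a pathogen keyword configuration from YAML
#'
#' @param path YAML file with a top-level `keywords` list.
#' @return Character vector of patterns.
#' @export
read_keyword_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  kw <- unlist(cfg$keywords)
  if (is.null(kw) || !length(kw))
    stop_input("keyword config has no 'keywords' entries")
  as.character(kw)
}

biosample_fields <- c("general_description", "isolation_source",
                      "isolation_site", "host", "environmental_medium",
                      "sample_type")

#' Classify a genome as pathogen or unassigned from Biosample text
#'
#' Scans the six recognised Biosample fields (general description, isolation
#' source, isolation site, host, environmental medium, sample type) in a
#' fixed order and reports the first case-insensitive keyword match as the
#' trigger; genomes with no match (or no metadata at all) are unassigned.
#'
#' @param biosample named character vector of Biosample fields.
#' @param keywords keyword patterns (default [default_pathogen_keywords()]).
#' @return List with `label` (`"pathogen"` or `"unassigned"`),
#'   `trigger_field`, `trigger_phrase` (both `""` when unassigned).
#' @export
classify_pathogen <- function(biosample,
                              keywords = default_pathogen_keywords()) {
  if (length(biosample)) {
    for (f in biosample_fields) {
      if (!f %in% names(biosample)) next
      txt <- tolower(biosample[[f]])
      for (kw in keywords) {
        if (grepl(tolower(kw), txt, fixed = TRUE))
          return(list(label = "pathogen", trigger_field = f,
                      trigger_phrase = kw))
      }
    }
  }
  list(label = "unassigned", trigger_field = "", trigger_phrase = "")
}

#' Classify every genome in a catalog
#'
#' @param catalog a `prophage_catalog`.
#' @param keywords keyword patterns.
#' @return Data frame `genome_id`, `label`, `trigger_field`,
#'   `trigger_phrase`.
#' @export
classify_pathogens <- function(catalog,
                               keywords = default_pathogen_keywords()) {
  res <- lapply(catalog$hosts$biosample, classify_pathogen,
                keywords = keywords)
  data.frame(genome_id = catalog$hosts$genome_id,
             label = vapply(res, `[[`, character(1), "label"),
             trigger_field = vapply(res, `[[`, character(1), "trigger_field"),
             trigger_phrase = vapply(res, `[[`, character(1),
                                     "trigger_phrase"),
             stringsAsFactors = FALSE)
}

#' Cap the number of genomes per genus by random downsampling
#'
#' Genera with at most `cap` genomes pass through intact; larger genera are
#' downsampled to `cap` uniformly without replacement, deterministically
#' given the seed.
#'
#' @param hosts host data frame (or a `prophage_catalog`, in which case the
#'   whole catalog is subset consistently).
#' @param cap maximum genomes per genus (default 100).
#' @param seed integer seed.
#' @return Subset of the input, same type.
#' @export
cap_per_genus <- function(hosts, cap = 100L, seed = 1L) {
  is_cat <- inherits(hosts, "prophage_catalog")
  h <- if (is_cat) hosts$hosts else hosts
  keep <- unlist(lapply(split(seq_len(nrow(h)), h$genus), function(i) {
    if (length(i) <= cap) i else
      with_seed(substream_seed(seed, paste0("pathogen.cap.", h$genus[i[1]])),
                sample(i, cap))
  }), use.names = FALSE)
  keep <- sort(keep)
  if (!is_cat) return(h[keep, , drop = FALSE])
  cat <- hosts
  cat$hosts <- h[keep, , drop = FALSE]
  ids <- cat$hosts$genome_id
  cat$replicons <- cat$replicons[cat$replicons$genome_id %in% ids, ,
                                 drop = FALSE]
  cat$prophages <- cat$prophages[cat$prophages$genome_id %in% ids, ,
                                 drop = FALSE]
  cat
}

#' Pathogen versus unassigned prophage-count enrichment
#'
#' @param pathogen_counts,unassigned_counts per-genome prophage counts of the
#'   two groups (both non-empty).
#' @return List with group means and medians and the one-sided Wilcoxon
#'   p-value for the pathogen-greater alternative.
#' @export
group_enrichment <- function(pathogen_counts, unassigned_counts) {
  if (!length(pathogen_counts) || !length(unassigned_counts))
    stop_input("both groups must be non-empty")
  list(mean_pathogen = mean(pathogen_counts),
       median_pathogen = stats::median(pathogen_counts),
       mean_unassigned = mean(unassigned_counts),
       median_unassigned = stats::median(unassigned_counts),
       n_pathogen = length(pathogen_counts),
       n_unassigned = length(unassigned_counts),
       p_value = wilcox_greater(pathogen_counts, unassigned_counts))
}

split_group_counts <- function(labels, catalog) {
  counts <- per_genome_counts(catalog$hosts, catalog$prophages)
  lab <- labels$label[match(catalog$hosts$genome_id, labels$genome_id)]
  if (any(is.na(lab)))
    stop_input("labels missing for genome(s): %s",
               paste(utils::head(catalog$hosts$genome_id[is.na(lab)], 3),
                     collapse = ", "))
  list(counts = counts, label = lab, genus = catalog$hosts$genus)
}

#' Leave-one-out genus contribution to the pathogen enrichment
#'
#' Recomputes the pathogen-versus-unassigned comparison with each genus (from
#' either group) removed in turn, reporting the leave-one-out p-value and its
#' change from the all-genera p-value. A removal that empties one group
#' yields an undefined (flagged) result rather than an error.
#'
#' @param labels data frame from [classify_pathogens()].
#' @param catalog a `prophage_catalog`.
#' @return List with `full_p` and `loo` (data frame `left_out_genus`,
#'   `p_value`, `delta_vs_full`, `undefined`).
#' @export
loo_contribution <- function(labels, catalog) {
  g <- split_group_counts(labels, catalog)
  if (length(unique(g$genus)) < 2)
    stop_input("need at least 2 genera for a leave-one-out analysis")
  full_p <- wilcox_greater(g$counts[g$label == "pathogen"],
                           g$counts[g$label == "unassigned"])
  loo <- do.call(rbind, lapply(sort(unique(g$genus)), function(gen) {
    keep <- g$genus != gen
    pa <- g$counts[keep & g$label == "pathogen"]
    un <- g$counts[keep & g$label == "unassigned"]
    if (!length(pa) || !length(un))
      return(data.frame(left_out_genus = gen, p_value = NA_real_,
                        delta_vs_full = NA_real_, undefined = TRUE,
                        stringsAsFactors = FALSE))
    p <- wilcox_greater(pa, un)
    data.frame(left_out_genus = gen, p_value = p,
               delta_vs_full = p - full_p, undefined = FALSE,
               stringsAsFactors = FALSE)
  }))
  list(full_p = full_p, loo = loo)
}

#' Per-genus pathogen versus unassigned comparison over shared genera
#'
#' Only genera with at least one genome in each group are tested. For every
#' shared genus the per-genome counts of the two groups are compared with a
#' one-sided (pathogen greater) Wilcoxon test; Bonferroni adjustment is
#' across the shared genera tested.
#'
#' @param labels data frame from [classify_pathogens()].
#' @param catalog a `prophage_catalog`.
#' @return Data frame, one row per shared genus: group sizes, prophage
#'   totals, standard deviations of the per-genome counts, `p_value`,
#'   `p_adjusted`.
#' @export
shared_genus_comparison <- function(labels, catalog) {
  g <- split_group_counts(labels, catalog)
  shared <- intersect(unique(g$genus[g$label == "pathogen"]),
                      unique(g$genus[g$label == "unassigned"]))
  if (!length(shared)) stop_input("no genus is shared between the groups")
  res <- do.call(rbind, lapply(sort(shared), function(gen) {
    pa <- g$counts[g$genus == gen & g$label == "pathogen"]
    un <- g$counts[g$genus == gen & g$label == "unassigned"]
    data.frame(genus = gen,
               n_pathogen = length(pa), n_unassigned = length(un),
               prophages_pathogen = sum(pa), prophages_unassigned = sum(un),
               sd_pathogen = stats::sd(pa), sd_unassigned = stats::sd(un),
               p_value = wilcox_greater(pa, un), stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- pmin(1, res$p_value * nrow(res))
  res
}
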