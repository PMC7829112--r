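# Sample- and ASV-level filters applied to denoised 16S count tables before
# community comparison.  The chain order is fixed: sample depth -> taxonomy
# -> prevalence/abundance; the chain is idempotent.

#' Filtering configuration
#'
#' Defaults encode the conventional 16S pre-processing rules: drop samples
#' with fewer than 1000 reads (a sample with exactly 1000 is retained),
#' drop ASVs whose lineage contains a contaminant/unassignable label, and
#' keep only ASVs observed in at least two samples overall whose group-mean
#' relative abundance reaches 1% in at least one of the compared groups.
#'
#' The abundance criterion uses the group MEAN of per-sample proportions:
#' requiring 1% in every sample of a group is so strict at realistic group
#' sizes that almost nothing survives, which contradicts the intent of
#' keeping the prevalent community members.  `abundance_scope = "every"`
#' switches to the per-sample reading.  Similarly the prevalence and
#' abundance criteria are combined with AND by default (both required to
#' keep an ASV); `logic = "OR"` keeps an ASV passing either.
#'
#' @param min_reads_per_sample Minimum column sum for a sample to be kept
#'   (strictly-below removal; default 1000).
#' @param excluded_taxon_labels Lineage labels that flag an ASV for removal
#'   (case-insensitive match against any rank).
#' @param min_prevalence_samples Minimum number of samples (count > 0)
#'   across the whole table (default 2).
#' @param min_group_mean_abundance Minimum group relative abundance
#'   (default 0.01) required in at least one group.
#' @param prevalence_abundance_logic `"AND"` or `"OR"`.
#' @param abundance_scope `"mean"` (group mean of per-sample proportions)
#'   or `"every"` (required in every sample of a group).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_reads_per_sample = 1000L,
                          excluded_taxon_labels = c("uncharacterized",
                                                    "Mitochondria",
                                                    "Chloroplast",
                                                    "Eukaryota"),
                          min_prevalence_samples = 2L,
                          min_group_mean_abundance = 0.01,
                          prevalence_abundance_logic = c("AND", "OR"),
                          abundance_scope = c("mean", "every")) {
  stopifnot(min_reads_per_sample >= 0,
            min_group_mean_abundance >= 0, min_group_mean_abundance <= 1,
            min_prevalence_samples >= 0)
  structure(list(min_reads_per_sample = min_reads_per_sample,
                 excluded_taxon_labels = excluded_taxon_labels,
                 min_prevalence_samples = min_prevalence_samples,
                 min_group_mean_abundance = min_group_mean_abundance,
                 prevalence_abundance_logic = match.arg(prevalence_abundance_logic),
                 abundance_scope = match.arg(abundance_scope)),
            class = "filter_config")
}

filter_report <- function(axis, removed_ids, reasons, n_before, n_after) {
  stopifnot(n_before - length(removed_ids) == n_after)
  structure(list(axis = axis,
                 removed = data.frame(id = as.character(removed_ids),
                                      reason = as.character(reasons),
                                      stringsAsFactors = FALSE),
                 n_before = n_before, n_after = n_after),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report (", x$axis, "): ", x$n_before, " -> ", x$n_after,
      " (", nrow(x$removed), " removed)\n", sep = "")
  if (nrow(x$removed)) {
    tab <- table(x$removed$reason)
    for (r in names(tab)) cat("  ", tab[[r]], " x ", r, "\n", sep = "")
  }
  invisible(x)
}

#' Remove samples below a sequencing-depth threshold
#'
#' Removes samples whose total read count is strictly below
#' `min_reads_per_sample`; a sample exactly at the threshold is retained.
#'
#' @param table An [asv_table].
#' @param config A [filter_config].
#' @return A list with elements `table` (filtered [asv_table]) and
#'   `report` (a `filter_report`).
#' @export
filter_samples_by_depth <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "asv_table"))
  depths <- colSums(table)
  drop <- depths < config$min_reads_per_sample
  if (all(drop) && ncol(table) > 0)
    stop("all samples fall below ", config$min_reads_per_sample, " reads")
  out <- table[, !drop, drop = FALSE]
  rep <- filter_report("samples", colnames(table)[drop],
                       sprintf("depth %d < %d", as.integer(depths[drop]),
                               as.integer(config$min_reads_per_sample)),
                       ncol(table), ncol(out))
  list(table = out, report = rep)
}

lineage_excluded <- function(lineage, labels) {
  length(lineage) == 0L ||
    any(tolower(trimws(lineage)) %in% tolower(labels))
}

#' Remove ASVs with contaminant or unassignable taxonomy
#'
#' An ASV is removed iff any rank of its lineage matches one of
#' `excluded_taxon_labels` case-insensitively.  ASVs absent from the
#' taxonomy table (or with an empty lineage) are treated as
#' "uncharacterized" and removed.
#'
#' @param table An [asv_table].
#' @param taxonomy A `taxonomy_table` (see [read_taxonomy()]).
#' @inheritParams filter_samples_by_depth
#' @return A list with elements `table` and `report`.
#' @export
filter_taxa <- function(table, taxonomy, config = filter_config()) {
  stopifnot(inherits(table, "asv_table"), inherits(taxonomy, "taxonomy_table"))
  ids <- rownames(table)
  missing <- !(ids %in% names(taxonomy))
  excl <- vapply(ids, function(a) {
    if (!(a %in% names(taxonomy))) TRUE
    else lineage_excluded(taxonomy[[a]], config$excluded_taxon_labels)
  }, TRUE)
  reason <- ifelse(missing[excl], "missing taxonomy (uncharacterized)",
                   "excluded taxon label")
  out <- table[!excl, , drop = FALSE]
  rep <- filter_report("asvs", ids[excl], reason, nrow(table), nrow(out))
  list(table = out, report = rep)
}

relative_abundance <- function(table) {
  depths <- colSums(table)
  if (any(depths == 0)) stop("sample with zero total count: ",
                             colnames(table)[which(depths == 0)[1L]])
  sweep(unclass(table), 2L, depths, "/")
}

#' Remove rare and low-abundance ASVs
#'
#' Applies the prevalence and group-abundance criteria described in
#' [filter_config()] with respect to a pair of sample groups.
#'
#' @param table An [asv_table].
#' @param metadata A `sample_metadata` covering every sample in `table`.
#' @param group_pair Character vector of the two group labels compared.
#' @inheritParams filter_samples_by_depth
#' @return A list with elements `table` and `report`.
#' @export
filter_prevalence_abundance <- function(table, metadata, group_pair,
                                        config = filter_config()) {
  stopifnot(inherits(table, "asv_table"), length(group_pair) == 2L)
  samples <- colnames(table)
  if (!all(samples %in% names(metadata)))
    stop("samples missing from metadata: ",
         paste(setdiff(samples, names(metadata)), collapse = ", "))
  grp <- as.character(metadata[samples])
  for (g in group_pair)
    if (!any(grp == g)) stop("group '", g, "' has no samples")

  prev <- rowSums(table > 0)
  prev_ok <- prev >= config$min_prevalence_samples

  rel <- relative_abundance(table)
  ab_ok <- rep(FALSE, nrow(table))
  for (g in group_pair) {
    cols <- rel[, grp == g, drop = FALSE]
    gstat <- if (config$abundance_scope == "mean") rowMeans(cols)
             else apply(cols, 1L, min)
    ab_ok <- ab_ok | (gstat >= config$min_group_mean_abundance)
  }

  keep <- if (config$prevalence_abundance_logic == "AND") prev_ok & ab_ok
          else prev_ok | ab_ok
  reason <- character(sum(!keep))
  reason[!prev_ok[!keep] & !ab_ok[!keep]] <- "low prevalence and abundance"
  reason[!prev_ok[!keep] & ab_ok[!keep]] <- "low prevalence"
  reason[prev_ok[!keep] & !ab_ok[!keep]] <- "low abundance"
  out <- table[keep, , drop = FALSE]
  rep <- filter_report("asvs", rownames(table)[!keep], reason,
                       nrow(table), nrow(out))
  list(table = out, report = rep)
}

#' Apply the full filter chain
#'
#' Fixed order: sample depth, then taxonomy, then prevalence/abundance.
#' Applying the chain to its own output removes nothing further.
#'
#' @inheritParams filter_prevalence_abundance
#' @param taxonomy A `taxonomy_table`.
#' @return A list with elements `table` (the filtered [asv_table]) and
#'   `reports` (list of the three `filter_report`s).
#' @export
filter_chain <- function(table, taxonomy, metadata, group_pair,
                         config = filter_config()) {
  s1 <- filter_samples_by_depth(table, config)
  s2 <- filter_taxa(s1$table, taxonomy, config)
  s3 <- filter_prevalence_abundance(s2$table, metadata, group_pair, config)
  list(table = s3$table,
       reports = list(depth = s1$report, taxa = s2$report,
                      prevalence_abundance = s3$report))
}
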