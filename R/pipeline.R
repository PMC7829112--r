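# End-to-end pipeline: (optionally) simulate -> filter -> overlap
# partition -> permutation null -> report, with every artifact listed in a
# checksummed manifest so that identical configuration and seed give
# identical manifests.

#' Pipeline configuration
#'
#' Either `simulate` (a [community_spec()]) or the three input paths
#' (`table_path`, `taxonomy_path`, `metadata_path`) must be supplied.
#'
#' @param out_dir Output directory (created if missing; must not contain
#'   the input files).
#' @param seed Integer seed recorded in every artifact and used for the
#'   null splits (and simulation unless the spec carries its own).
#' @param simulate Optional [community_spec()].
#' @param table_path,taxonomy_path,metadata_path Input TSV paths, used
#'   when `simulate` is `NULL`.
#' @param groups Two group labels to compare.
#' @param filter A [filter_config()].
#' @param null `NULL` to skip the permutation null, or a list with
#'   `group`, `n_splits`, `split_size` (see [random_split_null()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = NULL,
                            table_path = NULL, taxonomy_path = NULL,
                            metadata_path = NULL, groups = c("SD", "WD"),
                            filter = filter_config(),
                            null = list(group = "WD", n_splits = 100L,
                                        split_size = 5L)) {
  if (is.null(simulate) &&
      (is.null(table_path) || is.null(taxonomy_path) || is.null(metadata_path)))
    stop("supply either a simulation spec or all three input paths")
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full comparison pipeline
#'
#' Executes the configured stages and writes the artifacts to
#' `config$out_dir`: the (simulated or copied) input TSVs, the filtered
#' table, filter report, partition table, per-split null values, a JSON
#' summary, and `manifest.tsv` with an MD5 checksum per artifact.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the `overlap_comparison` object and the
#'   manifest data frame.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- character(0)

  if (!is.null(config$simulate)) {
    sim <- pipeline_stage("simulate", simulate_community(config$simulate))
    table <- sim$table; taxonomy <- sim$taxonomy; metadata <- sim$metadata
    pipeline_stage("simulate", {
      write_asv_table(table, out("counts.tsv"))
      write_taxonomy(taxonomy, out("taxonomy.tsv"))
      write_metadata(metadata, out("metadata.tsv"))
    })
    artifacts <- c(artifacts, "counts.tsv", "taxonomy.tsv", "metadata.tsv")
  } else {
    for (p in c(config$table_path, config$taxonomy_path, config$metadata_path))
      if (normalizePath(dirname(p), mustWork = FALSE) ==
          normalizePath(config$out_dir, mustWork = FALSE))
        stop("outputs must not overwrite inputs: ", p)
    table <- pipeline_stage("read", read_asv_table(config$table_path))
    taxonomy <- pipeline_stage("read", read_taxonomy(config$taxonomy_path))
    metadata <- pipeline_stage("read", read_metadata(config$metadata_path))
  }

  null_spec <- config$null
  if (!is.null(null_spec) && is.null(null_spec$seed))
    null_spec$seed <- config$seed
  cmp <- pipeline_stage("compare",
    compare_groups(table, taxonomy, metadata, config$groups,
                   config = config$filter, null = null_spec))

  pipeline_stage("report", {
    write_asv_table(cmp$table, out("filtered_counts.tsv"))
    rep_df <- do.call(rbind, lapply(names(cmp$filter_reports), function(nm) {
      r <- cmp$filter_reports[[nm]]
      if (nrow(r$removed) == 0L) return(NULL)
      data.frame(stage = nm, axis = r$axis, r$removed,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(rep_df))
      rep_df <- data.frame(stage = character(0), axis = character(0),
                           id = character(0), reason = character(0))
    utils::write.table(rep_df, out("filter_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(cmp$partition), out("partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cmp$null))
      utils::write.table(data.frame(split = seq_along(cmp$null$shared_pct),
                                    shared_pct = cmp$null$shared_pct),
                         out("null_splits.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    summary_list <- list(
      seed = config$seed, groups = config$groups,
      group_sizes = as.list(cmp$group_sizes),
      n_asvs_retained = nrow(cmp$table),
      partition = as.data.frame(cmp$partition))
    if (!is.null(cmp$null))
      summary_list$null <- list(mean = cmp$null$mean, sd = cmp$null$sd,
                                n_splits = cmp$null$n_splits,
                                split_size = cmp$null$split_size,
                                seed = cmp$null$seed)
    jsonlite::write_json(summary_list, out("summary.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  artifacts <- c(artifacts, "filtered_counts.tsv", "filter_report.tsv",
                 "partition.tsv",
                 if (!is.null(cmp$null)) "null_splits.tsv", "summary.json")

  manifest <- data.frame(
    file = artifacts,
    md5 = unname(tools::md5sum(file.path(config$out_dir, artifacts))),
    seed = config$seed, stringsAsFactors = FALSE)
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(comparison = cmp, manifest = manifest))
}
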