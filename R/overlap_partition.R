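# The community-overlap partition: each group's mean community is split
# into abundance that is unique to the group, abundance shared with the
# other group (per-ASV minimum of the two group means, a symmetric
# quantity), and the remaining "increased" abundance.  The three close to
# 100% for each group.  A random-split permutation null re-computes the
# shared fraction between two pseudo-groups drawn within one biological
# group.

#' Mean relative-abundance profile of a sample group
#'
#' Each sample column is normalized to proportions, then the proportions
#' are averaged with equal weight per sample (pooling raw counts instead
#' would let deep samples dominate; see `weighting`).
#'
#' @param table An [asv_table].
#' @param metadata A `sample_metadata` covering the table's samples.
#' @param group Group label to profile.
#' @param weighting `"equal"` (mean of per-sample proportions, default) or
#'   `"pooled"` (proportions of summed counts).
#' @return An object of class `group_profile`: list with `group`,
#'   `n_samples`, and `abundance` (named numeric summing to 1).
#' @export
group_profile <- function(table, metadata, group,
                          weighting = c("equal", "pooled")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(table, "asv_table"))
  samples <- colnames(table)
  if (!all(samples %in% names(metadata)))
    stop("samples missing from metadata: ",
         paste(setdiff(samples, names(metadata)), collapse = ", "))
  cols <- samples[metadata[samples] == group]
  if (length(cols) == 0L) stop("group '", group, "' has no samples")
  sub <- table[, cols, drop = FALSE]
  depths <- colSums(sub)
  if (all(depths == 0)) stop("group '", group, "' has no reads")
  ab <- if (weighting == "equal") {
    if (any(depths == 0))
      stop("sample with zero total count: ", cols[which(depths == 0)[1L]])
    rowMeans(sweep(unclass(sub), 2L, depths, "/"))
  } else {
    rowSums(sub) / sum(depths)
  }
  structure(list(group = group, n_samples = length(cols),
                 abundance = ab),
            class = "group_profile")
}

#' @export
print.group_profile <- function(x, ...) {
  cat("Group profile '", x$group, "': ", length(x$abundance), " ASVs over ",
      x$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Partition two group profiles into unique / shared / increased abundance
#'
#' Profiles are aligned on the union of their ASV ids (missing = 0).  For
#' each co-occurring ASV (positive mean abundance in both groups) the
#' shared contribution is the minimum of the two group means, and each
#' group's excess above the minimum is its "increased" contribution.
#' Abundance in ASVs absent from the other group is "unique".  All three
#' are reported as percentages and close to 100 per group; the shared
#' component is identical from either group's perspective.
#'
#' @param profile_a,profile_b `group_profile` objects (see
#'   [group_profile()]).
#' @param tol Tolerance for the requirement that each profile sums to 1.
#' @return An object of class `overlap_partition`: list with `groups`,
#'   `unique_pct` (named length-2), `shared_pct`, `increased_pct` (named
#'   length-2), and `co_occurring_asvs`.
#' @export
partition_overlap <- function(profile_a, profile_b, tol = 1e-9) {
  stopifnot(inherits(profile_a, "group_profile"),
            inherits(profile_b, "group_profile"))
  for (p in list(profile_a, profile_b))
    if (abs(sum(p$abundance) - 1) > tol)
      stop("profile '", p$group, "' is not normalized (sum = ",
           format(sum(p$abundance)), ")")
  ids <- union(names(profile_a$abundance), names(profile_b$abundance))
  pa <- pb <- stats::setNames(numeric(length(ids)), ids)
  pa[names(profile_a$abundance)] <- profile_a$abundance
  pb[names(profile_b$abundance)] <- profile_b$abundance

  co <- pa > 0 & pb > 0
  shared <- sum(pmin(pa[co], pb[co]))
  unique_a <- sum(pa[pb == 0])
  unique_b <- sum(pb[pa == 0])
  inc_a <- sum(pa[co] - pmin(pa[co], pb[co]))
  inc_b <- sum(pb[co] - pmin(pa[co], pb[co]))

  groups <- c(profile_a$group, profile_b$group)
  structure(list(groups = groups,
                 unique_pct = stats::setNames(100 * c(unique_a, unique_b),
                                              groups),
                 shared_pct = 100 * shared,
                 increased_pct = stats::setNames(100 * c(inc_a, inc_b),
                                                 groups),
                 co_occurring_asvs = ids[co]),
            class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, digits = 2L, ...) {
  cat("Community overlap partition (", x$groups[1L], " vs ", x$groups[2L],
      ")\n", sep = "")
  m <- rbind(Unique = x$unique_pct,
             Shared = rep(x$shared_pct, 2L),
             Increased = x$increased_pct)
  m <- rbind(m, Total = colSums(m))
  print(round(m, digits))
  cat(length(x$co_occurring_asvs), "co-occurring ASVs\n")
  invisible(x)
}

#' @export
as.data.frame.overlap_partition <- function(x, ...) {
  data.frame(group = x$groups,
             unique_pct = as.numeric(x$unique_pct),
             shared_pct = x$shared_pct,
             increased_pct = as.numeric(x$increased_pct),
             stringsAsFactors = FALSE)
}

#' Random-split permutation null for the shared fraction
#'
#' Draws `n_splits` random partitions of one group's samples into two
#' pseudo-groups of `split_size` each (samples beyond `2 * split_size` are
#' left out of that split), treats the pseudo-groups exactly like real
#' groups — including, by default, re-applying the prevalence/abundance
#' filter within the split — and records the shared percentage of each
#' split.  Splits are drawn independently across iterations (duplicates
#' allowed) unless `unique_splits = TRUE`.
#'
#' @param table An [asv_table]; pass the table already filtered for depth
#'   and taxonomy (as in [compare_groups()]).
#' @param metadata A `sample_metadata`.
#' @param group Group label whose samples are split.
#' @param n_splits Number of random splits (default 100).
#' @param split_size Samples per pseudo-group (default 5).
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @param config [filter_config()] used when `refilter = TRUE`.
#' @param refilter Re-apply the prevalence/abundance filter within each
#'   split's pseudo-groups (default TRUE).
#' @param unique_splits Require all sampled split configurations to be
#'   distinct (only 126 distinct 5+5 splits of 10 samples exist).
#' @param weighting Passed to [group_profile()].
#' @return An object of class `overlap_null`: list with `shared_pct`
#'   (length `n_splits`), `mean`, `sd`, `n_splits`, `split_size`, `seed`.
#' @export
random_split_null <- function(table, metadata, group, n_splits = 100L,
                              split_size = 5L, seed = 1L,
                              config = filter_config(), refilter = TRUE,
                              unique_splits = FALSE,
                              weighting = "equal") {
  stopifnot(inherits(table, "asv_table"), n_splits >= 1L, split_size >= 1L)
  samples <- colnames(table)
  cols <- samples[metadata[samples] == group]
  if (length(cols) < 2L * split_size)
    stop("group '", group, "' has ", length(cols), " samples; need at least ",
         2L * split_size)
  set.seed(seed)
  shared <- numeric(n_splits)
  seen <- character(0)
  i <- 1L
  attempts <- 0L
  while (i <= n_splits) {
    pick <- sample(cols, 2L * split_size)
    a <- pick[seq_len(split_size)]
    b <- pick[split_size + seq_len(split_size)]
    if (unique_splits) {
      key <- paste(sort(c(paste(sort(a), collapse = ","),
                          paste(sort(b), collapse = ","))), collapse = "|")
      attempts <- attempts + 1L
      if (attempts > 100L * n_splits)
        stop("cannot draw ", n_splits, " distinct splits")
      if (key %in% seen) next
      seen <- c(seen, key)
    }
    sub <- table[, c(a, b), drop = FALSE]
    meta <- sample_metadata(stats::setNames(
      rep(c("splitA", "splitB"), each = split_size), c(a, b)))
    if (refilter) {
      keep <- rowSums(sub) > 0  # drop all-zero rows before normalizing
      sub <- sub[keep, , drop = FALSE]
      sub <- filter_prevalence_abundance(sub, meta, c("splitA", "splitB"),
                                         config)$table
    }
    if (nrow(sub) == 0L) {
      shared[i] <- 0
    } else {
      pa <- group_profile(sub, meta, "splitA", weighting)
      pb <- group_profile(sub, meta, "splitB", weighting)
      shared[i] <- partition_overlap(pa, pb)$shared_pct
    }
    i <- i + 1L
  }
  structure(list(shared_pct = shared, mean = mean(shared),
                 sd = stats::sd(shared), n_splits = n_splits,
                 split_size = split_size, seed = seed, group = group,
                 refilter = refilter, unique_splits = unique_splits),
            class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, digits = 2L, ...) {
  cat("Random-split null for group '", x$group, "': ", x$n_splits,
      " splits of ", x$split_size, "+", x$split_size, " samples\n", sep = "")
  cat("  shared%: mean ", round(x$mean, digits), ", sd ",
      round(x$sd, digits), ", range [", round(min(x$shared_pct), digits),
      ", ", round(max(x$shared_pct), digits), "]\n", sep = "")
  invisible(x)
}

#' Compare two groups' communities end to end
#'
#' The package's main entry point: applies the filter chain (sample depth,
#' taxonomy, prevalence/abundance), computes both group profiles, partitions
#' them into unique / shared / increased abundance, and optionally attaches
#' a within-group random-split null for the shared fraction.
#'
#' @param table An [asv_table] of raw counts.
#' @param taxonomy A `taxonomy_table`.
#' @param metadata A `sample_metadata`.
#' @param group_pair Character vector of the two group labels to compare.
#' @param config A [filter_config()].
#' @param null `NULL`, or a list of arguments for [random_split_null()]
#'   (`group`, `n_splits`, `split_size`, `seed`, and optionally `refilter`,
#'   `unique_splits`); the null is computed on the depth- and
#'   taxonomy-filtered table.
#' @param weighting Passed to [group_profile()].
#' @return An object of class `overlap_comparison`: list with `partition`
#'   (an `overlap_partition`), `profiles`, `filter_reports`, `null`
#'   (possibly `NULL`), `table` (the fully filtered [asv_table]), and
#'   `group_sizes`.
#' @examples
#' fx <- make_toy_fixture()
#' cmp <- compare_groups(fx$table, fx$taxonomy, fx$metadata, c("SD", "WD"))
#' cmp
#' @export
compare_groups <- function(table, taxonomy, metadata, group_pair,
                           config = filter_config(), null = NULL,
                           weighting = "equal") {
  stopifnot(length(group_pair) == 2L)
  chain <- filter_chain(table, taxonomy, metadata, group_pair, config)
  pa <- group_profile(chain$table, metadata, group_pair[1L], weighting)
  pb <- group_profile(chain$table, metadata, group_pair[2L], weighting)
  part <- partition_overlap(pa, pb)
  nul <- NULL
  if (!is.null(null)) {
    pre <- filter_taxa(filter_samples_by_depth(table, config)$table,
                       taxonomy, config)$table
    nul <- do.call(random_split_null,
                   c(list(table = pre, metadata = metadata, config = config,
                          weighting = weighting), null))
  }
  structure(list(partition = part,
                 profiles = list(pa, pb),
                 filter_reports = chain$reports,
                 null = nul,
                 table = chain$table,
                 group_sizes = stats::setNames(
                   c(pa$n_samples, pb$n_samples), group_pair)),
            class = "overlap_comparison")
}

#' @export
print.overlap_comparison <- function(x, digits = 2L, ...) {
  cat("Community overlap comparison\n")
  cat("  groups: ", x$partition$groups[1L], " (n = ", x$group_sizes[1L],
      "), ", x$partition$groups[2L], " (n = ", x$group_sizes[2L], ")\n",
      sep = "")
  cat("  ASVs retained after filtering: ", nrow(x$table), "\n", sep = "")
  print(x$partition, digits = digits)
  if (!is.null(x$null)) print(x$null, digits = digits)
  invisible(x)
}

#' @export
summary.overlap_comparison <- function(object, ...) {
  part <- as.data.frame(object$partition)
  out <- list(partition = part,
              n_asvs_retained = nrow(object$table),
              group_sizes = object$group_sizes,
              filter_reports = object$filter_reports)
  if (!is.null(object$null)) {
    out$null_mean <- object$null$mean
    out$null_sd <- object$null$sd
    out$shared_z <- (object$partition$shared_pct - object$null$mean) /
      object$null$sd
  }
  class(out) <- "summary.overlap_comparison"
  out
}

#' @export
print.summary.overlap_comparison <- function(x, digits = 2L, ...) {
  print(x$partition, digits = digits)
  cat("ASVs retained:", x$n_asvs_retained, "\n")
  if (!is.null(x$null_mean))
    cat("null shared%: mean ", round(x$null_mean, digits), ", sd ",
        round(x$null_sd, digits), "; observed z = ",
        round(x$shared_z, digits), "\n", sep = "")
  invisible(x)
}

#' Stacked-bar display of an overlap comparison
#'
#' One stacked bar per group (unique / increased / shared), plus one for
#' the null mean when a null is attached.
#'
#' @param x An `overlap_comparison`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.overlap_comparison <- function(x, ...) {
  p <- x$partition
  m <- cbind(c(p$shared_pct, p$increased_pct[1L], p$unique_pct[1L]),
             c(p$shared_pct, p$increased_pct[2L], p$unique_pct[2L]))
  colnames(m) <- p$groups
  if (!is.null(x$null)) {
    m <- cbind(m, c(x$null$mean, (100 - x$null$mean) / 2,
                    (100 - x$null$mean) / 2))
    colnames(m)[3L] <- paste0("null(", x$null$group, ")")
  }
  rownames(m) <- c("Shared", "Increased", "Unique")
  graphics::barplot(m, col = c("grey40", "grey70", "grey90"),
                    ylab = "% of community abundance", legend.text = TRUE,
                    args.legend = list(x = "topright", bty = "n"), ...)
  invisible(x)
}
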