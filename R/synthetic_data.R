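# Synthetic two-group ASV communities with known ground truth, standing in
# for raw 16S sequencing data.  Sample compositions follow a
# Dirichlet-multinomial: a group mean composition, per-sample Dirichlet
# draws around it (spread set by a concentration parameter), and multinomial
# counts at a per-sample sequencing depth.

#' Specification of a synthetic two-group ASV community
#'
#' Defaults describe a strong dietary contrast between a small
#' standard-diet group (SD, n = 4) and a larger western-diet group
#' (WD, n = 10): 150 ASVs of which 20% have non-zero expected abundance in
#' both groups, moderate within-group compositional variability
#' (concentration 50), sequencing depths around 20,000 reads with a floor
#' of 1,000 (the conventional sample-exclusion boundary), and 5% of ASVs
#' carrying contaminant taxonomy labels.
#'
#' @param n_asvs Total number of ASVs.
#' @param group_sizes Integer vector of two group sizes.
#' @param group_names Labels for the two groups.
#' @param overlap_fraction Fraction of ASVs with non-zero expected
#'   abundance in both groups (rounded to a whole number of ASVs).
#' @param concentration Dirichlet concentration; larger values pull samples
#'   closer to their group mean composition.
#' @param depth_mean,depth_min Mean and floor of per-sample sequencing
#'   depth; depth is `depth_min + Poisson(depth_mean - depth_min)`.
#' @param contaminant_fraction Fraction of ASVs assigned a contaminant
#'   lineage (mitochondria, chloroplast, Eukaryota, or uncharacterized).
#' @param identical_groups If `TRUE` both groups use one common mean
#'   composition (requires `overlap_fraction = 1`); this is the
#'   no-difference condition for null calibration.
#' @param sdlog Log-normal spread of per-ASV abundance weights.
#' @param seed Integer seed; the same spec and seed give bit-identical
#'   output.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(n_asvs = 150L, group_sizes = c(4L, 10L),
                           group_names = c("SD", "WD"),
                           overlap_fraction = 0.2, concentration = 50,
                           depth_mean = 20000L, depth_min = 1000L,
                           contaminant_fraction = 0.05,
                           identical_groups = FALSE, sdlog = 1.5,
                           seed = 1L) {
  stopifnot(n_asvs >= 2L, length(group_sizes) == 2L, all(group_sizes >= 1L),
            overlap_fraction >= 0, overlap_fraction <= 1,
            concentration > 0, depth_min >= 1L, depth_mean >= depth_min,
            contaminant_fraction >= 0, contaminant_fraction < 1)
  if (identical_groups && overlap_fraction < 1)
    stop("identical_groups requires overlap_fraction = 1")
  structure(as.list(environment()), class = "community_spec")
}

rdirichlet1 <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  x[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (sum(x) == 0) stop("degenerate Dirichlet draw")
  x / sum(x)
}

contaminant_lineages <- function(n) {
  pool <- list(c("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                 "Rickettsiales", "Mitochondria"),
               c("Bacteria", "Cyanobacteria", "Oxyphotobacteria",
                 "Chloroplast"),
               c("Eukaryota"),
               c("uncharacterized"))
  pool[1L + (seq_len(n) - 1L) %% length(pool)]
}

bacterial_lineage <- function(i) {
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Verrucomicrobia")
  p <- phyla[1L + (i - 1L) %% length(phyla)]
  c("Bacteria", p, paste0("Class", i), paste0("Order", i),
    paste0("Family", i), paste0("Genus", i))
}

#' Simulate a two-group ASV community
#'
#' Draws group mean compositions with the support overlap requested by the
#' spec (exactly `round(overlap_fraction * n_asvs)` ASVs have non-zero
#' expectation in both groups; the remainder is split between the groups),
#' then per-sample Dirichlet-multinomial counts.  Contaminant ASVs go
#' through the same abundance machinery and are flagged only in the
#' taxonomy, so removing them is the taxonomy filter's job.
#'
#' @param spec A [community_spec()].
#' @return A list with elements `table` ([asv_table]), `taxonomy`
#'   (`taxonomy_table`), `metadata` (`sample_metadata`), and `truth` (list
#'   with per-group expectation vectors `expected`, `contaminants`, and
#'   `true_shared_fraction` = sum of per-ASV minima of the two expectation
#'   vectors).
#' @export
simulate_community <- function(spec = community_spec()) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  n <- spec$n_asvs
  n_shared <- round(spec$overlap_fraction * n)
  if (spec$overlap_fraction > 0 && n_shared == 0L)
    stop("n_asvs too small to honor overlap_fraction ", spec$overlap_fraction)
  n_uniq <- n - n_shared
  n_a <- ceiling(n_uniq / 2)
  n_b <- n_uniq - n_a
  if (n_shared + n_a == 0L || n_shared + n_b == 0L)
    stop("a group would have an empty community; increase n_asvs or overlap")

  asv_ids <- sprintf("ASV_%03d", seq_len(n))
  membership <- rep(c("shared", "A", "B"), c(n_shared, n_a, n_b))
  membership <- membership[sample.int(n)]  # shuffle support over ids

  draw_weights <- function(sel) {
    w <- numeric(n)
    w[sel] <- stats::rlnorm(sum(sel), meanlog = 0, sdlog = spec$sdlog)
    w / sum(w)
  }
  p_a <- draw_weights(membership %in% c("shared", "A"))
  p_b <- if (spec$identical_groups) p_a
         else draw_weights(membership %in% c("shared", "B"))

  sizes <- spec$group_sizes
  groups <- rep(spec$group_names, sizes)
  sample_ids <- unlist(lapply(seq_along(sizes), function(g)
    sprintf("%s_%02d", spec$group_names[g], seq_len(sizes[g]))))
  counts <- matrix(0, n, sum(sizes), dimnames = list(asv_ids, sample_ids))
  means <- list(p_a, p_b)
  for (j in seq_len(sum(sizes))) {
    p <- means[[match(groups[j], spec$group_names)]]
    comp <- rdirichlet1(spec$concentration * p)
    depth <- spec$depth_min +
      stats::rpois(1L, spec$depth_mean - spec$depth_min)
    counts[, j] <- stats::rmultinom(1L, depth, comp)
  }

  n_cont <- round(spec$contaminant_fraction * n)
  cont_idx <- if (n_cont > 0) sample.int(n, n_cont) else integer(0)
  lineages <- lapply(seq_len(n), bacterial_lineage)
  if (n_cont > 0) lineages[cont_idx] <- contaminant_lineages(n_cont)
  names(lineages) <- asv_ids

  list(table = asv_table(counts, asv_ids, sample_ids),
       taxonomy = taxonomy_table(lineages),
       metadata = sample_metadata(stats::setNames(groups, sample_ids)),
       truth = list(
         expected = stats::setNames(
           list(stats::setNames(p_a, asv_ids), stats::setNames(p_b, asv_ids)),
           spec$group_names),
         contaminants = asv_ids[sort(cont_idx)],
         true_shared_fraction = sum(pmin(p_a, p_b))))
}

#' Simulate sequence evolution along a tree
#'
#' Evolves site-independent nucleotide sequences along a phylogeny under a
#' Tamura-Nei substitution model, starting from stationary frequencies at
#' the root.  Branch lengths are in expected substitutions per site.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param length Number of alignment columns (positive).
#' @param model A [tn93_model()].
#' @param seed Integer seed.
#' @return A [dna_alignment] with one row per tip, in tip-label order.
#' @export
simulate_alignment <- function(tree, length, model = tn93_model(),
                               seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (length <= 0) stop("alignment length must be positive")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_nodes <- n_tip + tree$Nnode
  seqs <- matrix(NA_integer_, n_nodes, length)
  seqs[root, ] <- sample.int(4L, length, replace = TRUE, prob = model$pi)
  tree <- ape::reorder.phylo(tree, "cladewise")  # edges in preorder
  edges <- tree$edge
  lens <- tree$edge.length
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]; child <- edges[e, 2L]
    P <- tn93_prob_matrix(lens[e], model)
    ps <- seqs[parent, ]
    cs <- integer(length)
    for (s in 1:4) {
      at <- which(ps == s)
      if (length(at))
        cs[at] <- sample.int(4L, length(at), replace = TRUE, prob = P[s, ])
    }
    seqs[child, ] <- cs
  }
  m <- matrix(bases[seqs[seq_len(n_tip), , drop = FALSE]], n_tip, length)
  rownames(m) <- tree$tip.label
  dna_alignment(m)
}

#' Hand-specified toy community fixture
#'
#' A six-ASV, five-sample two-group table small enough that every
#' downstream number can be checked by hand.  After removing the one
#' contaminant ASV (`tox1`, mitochondrial), per-sample proportions are
#' exact fractions and the SD-vs-WD partition is: unique 18.75 / 35,
#' shared 65, increased 16.25 / 0 (percent).  The same data ship as TSV
#' files under `inst/extdata/toy/`.
#'
#' @return A list with `table`, `taxonomy`, and `metadata`.
#' @export
make_toy_fixture <- function() {
  counts <- cbind(
    SD_1 = c(500, 500,   0,   0, 1000, 100),
    SD_2 = c(250, 750,   0,   0, 1000, 100),
    WD_1 = c(  0, 400, 400, 200, 1000, 100),
    WD_2 = c(  0, 200, 600, 200, 1000, 100),
    WD_3 = c(  0, 300, 500, 200, 1000, 100))
  asv_ids <- c("asv1", "asv2", "asv3", "asv4", "asv5", "tox1")
  rownames(counts) <- asv_ids
  lineages <- list(
    asv1 = c("Bacteria", "Firmicutes", "Clostridia"),
    asv2 = c("Bacteria", "Firmicutes", "Bacilli"),
    asv3 = c("Bacteria", "Bacteroidetes", "Bacteroidia"),
    asv4 = c("Bacteria", "Proteobacteria", "Gammaproteobacteria"),
    asv5 = c("Bacteria", "Verrucomicrobia", "Verrucomicrobiae"),
    tox1 = c("Bacteria", "Proteobacteria", "Alphaproteobacteria",
             "Rickettsiales", "Mitochondria"))
  list(table = asv_table(counts),
       taxonomy = taxonomy_table(lineages),
       metadata = sample_metadata(c(SD_1 = "SD", SD_2 = "SD", WD_1 = "WD",
                                    WD_2 = "WD", WD_3 = "WD")))
}
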