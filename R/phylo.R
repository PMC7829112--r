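# Distance phylogenetics: complete deletion of gapped/ambiguous columns,
# Tamura-Nei (TN93) pairwise distances with model parameters estimated once
# by maximizing the sum of pairwise log-likelihoods (composite likelihood),
# and classical Saitou-Nei neighbor joining.  Trees are ape "phylo"
# objects; Newick I/O goes through ape.

BASES <- c("A", "C", "G", "T")

#' Tamura-Nei (TN93) substitution model
#'
#' Parameterized by stationary base frequencies and the two
#' transition/transversion rate ratios: `k1` for the purine transition
#' (A<->G) and `k2` for the pyrimidine transition (C<->T), both relative
#' to the transversion rate.  `k1 = k2 = 1` with equal frequencies is
#' Jukes-Cantor.
#'
#' @param pi Stationary frequencies, order A, C, G, T (normalized
#'   internally; all must be positive).
#' @param k1,k2 Purine and pyrimidine transition/transversion rate ratios.
#' @return A list of class `tn93_model`.
#' @export
tn93_model <- function(pi = c(0.25, 0.25, 0.25, 0.25), k1 = 1, k2 = 1) {
  stopifnot(length(pi) == 4L, all(pi > 0), k1 > 0, k2 > 0)
  pi <- pi / sum(pi)
  names(pi) <- BASES
  structure(list(pi = pi, k1 = k1, k2 = k2), class = "tn93_model")
}

# Expected substitutions per site per unit time (transversion rate = 1).
tn93_rate <- function(model) {
  pi <- model$pi
  2 * (pi["A"] * pi["G"] * model$k1 + pi["C"] * pi["T"] * model$k2 +
         (pi["A"] + pi["G"]) * (pi["C"] + pi["T"]))
}

#' TN93 transition-probability matrix
#'
#' Closed-form `P(d)` for a branch of length `d` expected substitutions
#' per site under a [tn93_model()].
#'
#' @param d Branch length in expected substitutions/site.
#' @param model A [tn93_model()].
#' @return A 4x4 row-stochastic matrix in base order A, C, G, T.
#' @export
tn93_prob_matrix <- function(d, model) {
  pi <- model$pi
  pR <- pi["A"] + pi["G"]; pY <- pi["C"] + pi["T"]
  t <- d / tn93_rate(model)                     # time at transversion rate 1
  e2 <- exp(-t)
  e3 <- exp(-(pR * model$k1 + pY) * t)
  e4 <- exp(-(pY * model$k2 + pR) * t)
  P <- matrix(0, 4L, 4L, dimnames = list(BASES, BASES))
  P["A", "A"] <- pi["A"] + pi["A"] * pY / pR * e2 + pi["G"] / pR * e3
  P["A", "G"] <- pi["G"] + pi["G"] * pY / pR * e2 - pi["G"] / pR * e3
  P["G", "A"] <- pi["A"] + pi["A"] * pY / pR * e2 - pi["A"] / pR * e3
  P["G", "G"] <- pi["G"] + pi["G"] * pY / pR * e2 + pi["A"] / pR * e3
  P["C", "C"] <- pi["C"] + pi["C"] * pR / pY * e2 + pi["T"] / pY * e4
  P["C", "T"] <- pi["T"] + pi["T"] * pR / pY * e2 - pi["T"] / pY * e4
  P["T", "C"] <- pi["C"] + pi["C"] * pR / pY * e2 - pi["C"] / pY * e4
  P["T", "T"] <- pi["T"] + pi["T"] * pR / pY * e2 + pi["C"] / pY * e4
  for (x in c("A", "G")) for (y in c("C", "T")) P[x, y] <- pi[y] * (1 - e2)
  for (x in c("C", "T")) for (y in c("A", "G")) P[x, y] <- pi[y] * (1 - e2)
  P
}

#' Remove all columns containing gaps or missing data
#'
#' Complete deletion: any alignment column holding `-`, `N`, or an IUPAC
#' ambiguity code in any sequence is removed from all sequences; column
#' order is otherwise preserved.  The number of retained positions is
#' attached as attribute `n_positions`.
#'
#' @param alignment A [dna_alignment].
#' @return The column-filtered [dna_alignment].
#' @export
complete_deletion <- function(alignment) {
  stopifnot(inherits(alignment, "dna_alignment"))
  keep <- apply(alignment, 2L, function(col) all(col %in% BASES))
  if (!any(keep)) stop("no alignment columns remain after complete deletion")
  out <- alignment[, keep, drop = FALSE]
  class(out) <- class(alignment)
  attr(out, "n_positions") <- sum(keep)
  out
}

pair_count_table <- function(alignment, i, j) {
  xi <- factor(alignment[i, ], levels = BASES)
  xj <- factor(alignment[j, ], levels = BASES)
  table(xi, xj)
}

# Log-likelihood of one pair's 4x4 count table at branch length t
# (time units of transversion rate 1), given frequencies and ratios.
tn93_pair_loglik <- function(t, N, pi, k1, k2) {
  m <- tn93_model(pi, k1, k2)
  t <- t * unname(tn93_rate(m))  # tn93_prob_matrix takes substitutions/site
  P <- tn93_prob_matrix(t, m)
  J <- pi * P            # joint P(x, y); rows scaled by stationary freqs
  J[J < .Machine$double.xmin] <- .Machine$double.xmin
  sum(N * log(J))
}

# The joint distribution J(t) = pi_x P_xy(t) is linear in the three
# exponentials exp(-t), exp(-(pR k1 + pY) t), exp(-(pY k2 + pR) t); the
# coefficient matrices depend only on (pi, k1, k2) and are precomputed so
# profiling t over many pairs is cheap.
tn93_loglik_consts <- function(pi, k1, k2) {
  pA <- pi[1L]; pC <- pi[2L]; pG <- pi[3L]; pT <- pi[4L]
  pR <- pA + pG; pY <- pC + pT
  B0 <- outer(pi, pi)
  B2 <- outer(pi, pi)
  B2[c(1L, 3L), c(1L, 3L)] <- B2[c(1L, 3L), c(1L, 3L)] * pY / pR
  B2[c(2L, 4L), c(2L, 4L)] <- B2[c(2L, 4L), c(2L, 4L)] * pR / pY
  B2[c(1L, 3L), c(2L, 4L)] <- -B2[c(1L, 3L), c(2L, 4L)]
  B2[c(2L, 4L), c(1L, 3L)] <- -B2[c(2L, 4L), c(1L, 3L)]
  B3 <- matrix(0, 4L, 4L)
  B3[1L, 1L] <- B3[3L, 3L] <- pA * pG / pR
  B3[1L, 3L] <- B3[3L, 1L] <- -pA * pG / pR
  B4 <- matrix(0, 4L, 4L)
  B4[2L, 2L] <- B4[4L, 4L] <- pC * pT / pY
  B4[2L, 4L] <- B4[4L, 2L] <- -pC * pT / pY
  list(B0 = B0, B2 = B2, B3 = B3, B4 = B4,
       r3 = pR * k1 + pY, r4 = pY * k2 + pR)
}

tn93_loglik_fast <- function(t, N, cs) {
  J <- cs$B0 + cs$B2 * exp(-t) + cs$B3 * exp(-cs$r3 * t) +
    cs$B4 * exp(-cs$r4 * t)
  J[J < .Machine$double.xmin] <- .Machine$double.xmin
  sum(N * log(J))
}

#' Pairwise TN93 distances by maximum composite likelihood
#'
#' The TN93 parameters shared by all pairs — base frequencies (empirical)
#' and the two transition/transversion ratios — are estimated once by
#' maximizing the sum over all sequence pairs of the pairwise
#' log-likelihoods, with each pair's divergence time profiled out by 1-D
#' optimization.  Pairwise distances are then computed under the common
#' parameters, in expected substitutions per site.  With a single pair the
#' composite likelihood is the full likelihood.
#'
#' @param alignment A gap-free [dna_alignment] (run [complete_deletion()]
#'   first); at least two sequences, A/C/G/T only.
#' @param d_max Upper bound on a pairwise distance; a pair whose estimate
#'   hits the bound is reported as saturated and raises an error naming
#'   the pair.
#' @return A symmetric matrix of class `dist_matrix` with zero diagonal
#'   and attributes `model` (the fitted [tn93_model()]) and `logCL`.
#' @export
composite_likelihood_distances <- function(alignment, d_max = 10) {
  stopifnot(inherits(alignment, "dna_alignment"))
  if (nrow(alignment) < 2L) stop("need at least 2 sequences")
  if (!all(alignment %in% BASES))
    stop("alignment contains gaps or ambiguity codes; run complete_deletion")
  ids <- rownames(alignment)
  n <- nrow(alignment)
  freq <- table(factor(alignment, levels = BASES))
  pi <- as.numeric(freq) / sum(freq)
  names(pi) <- BASES
  if (any(pi == 0) || (pi["A"] + pi["G"]) == 0 || (pi["C"] + pi["T"]) == 0)
    stop("degenerate base composition: every base must be observed")

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  Ns <- lapply(seq_len(nrow(pairs)), function(r)
    pair_count_table(alignment, pairs[r, 1L], pairs[r, 2L]))
  identical_pair <- vapply(Ns, function(N) sum(N) == sum(diag(N)), TRUE)
  t_max <- d_max  # generous bound in time units (rate is O(1))

  profile_t <- function(N, cs) {
    stats::optimize(tn93_loglik_fast, c(0, t_max), N = N, cs = cs,
                    maximum = TRUE, tol = 1e-9)
  }
  comp_loglik <- function(logk) {
    cs <- tn93_loglik_consts(pi, exp(logk[1L]), exp(logk[2L]))
    tot <- 0
    for (r in seq_along(Ns)) {
      if (identical_pair[r]) {
        tot <- tot + tn93_loglik_fast(0, Ns[[r]], cs)
      } else {
        tot <- tot + profile_t(Ns[[r]], cs)$objective
      }
    }
    -tot
  }
  fit <- stats::optim(c(0, 0), comp_loglik, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500L))
  k1 <- exp(fit$par[1L]); k2 <- exp(fit$par[2L])
  model <- tn93_model(pi, k1, k2)
  rate <- unname(tn93_rate(model))
  cs <- tn93_loglik_consts(pi, k1, k2)

  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    d <- if (identical_pair[r]) 0 else profile_t(Ns[[r]], cs)$maximum * rate
    if (d > 0.999 * d_max)
      stop("saturated pair: ", ids[i], " vs ", ids[j],
           " (distance estimate at bound)")
    D[i, j] <- D[j, i] <- d
  }
  structure(D, class = c("dist_matrix", "matrix", "array"),
            model = model, logCL = -fit$value)
}

#' @export
print.dist_matrix <- function(x, digits = 6L, ...) {
  cat("Pairwise distance matrix (", nrow(x), " taxa)\n", sep = "")
  print(round(unclass(x)[seq_len(min(6L, nrow(x))),
                         seq_len(min(6L, ncol(x))), drop = FALSE], digits))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration with the standard Q-criterion.
#' Deterministic: ties in Q are broken by the lexicographically lowest
#' taxon-index pair.  Negative branch lengths, which NJ can produce, are
#' retained (with a warning) unless `clamp_negative = TRUE`.
#'
#' @param dm Symmetric numeric matrix with zero diagonal and row/column
#'   names (e.g. from [composite_likelihood_distances()]), at least 3 taxa.
#' @param clamp_negative Replace negative branch lengths with zero.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm, clamp_negative = FALSE) {
  D <- unclass(as.matrix(dm))
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", 1:n)
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  fmt <- function(x) sprintf("%.17g", x)
  labels <- rownames(D)       # current newick substring per active node
  neg <- FALSE

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest (i, j) with i < j among minimizers, comparing with tolerance
    qmin <- min(Q[upper.tri(Q)])
    best <- NULL
    for (i in seq_len(m - 1L)) {
      js <- which(Q[i, (i + 1L):m] <= qmin + 1e-12) + i
      if (length(js)) { best <- c(i, js[1L]); break }
    }
    i <- best[1L]; j <- best[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0 || lj < 0) neg <- TRUE
    if (clamp_negative) { li <- max(li, 0); lj <- max(lj, 0) }
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    newlab <- paste0("(", labels[i], ":", fmt(li), ",",
                     labels[j], ":", fmt(lj), ")")
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    labels <- c(labels[keep], newlab)
    rownames(D2) <- colnames(D2) <- seq_len(m - 1L)
    D <- D2
  }
  l1 <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
  l2 <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
  l3 <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
  if (any(c(l1, l2, l3) < 0)) neg <- TRUE
  if (clamp_negative) { l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0) }
  if (neg && !clamp_negative)
    warning("neighbor joining produced negative branch lengths")
  nwk <- paste0("(", labels[1L], ":", fmt(l1), ",", labels[2L], ":",
                fmt(l2), ",", labels[3L], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

#' Sum of all branch lengths of a tree
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return The arithmetic sum of the edge lengths.
#' @export
total_branch_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  sum(tree$edge.length)
}

#' Build a neighbor-joining tree from an aligned FASTA file
#'
#' Convenience wrapper for the full chain: read alignment, complete
#' deletion, composite-likelihood TN93 distances, neighbor joining,
#' Newick output.
#'
#' @param fasta_in Path to an aligned FASTA file.
#' @param newick_out Optional path for the Newick tree.
#' @param report_out Optional path for a JSON run report.
#' @return Invisibly, a list with `tree`, `distances`, `n_sequences`,
#'   `n_positions` (columns surviving complete deletion), and
#'   `total_branch_length`.
#' @export
build_nj_tree <- function(fasta_in, newick_out = NULL, report_out = NULL) {
  aln <- read_fasta(fasta_in)
  aln <- complete_deletion(aln)
  dm <- composite_likelihood_distances(aln)
  tree <- neighbor_joining(dm)
  res <- list(tree = tree, distances = dm,
              n_sequences = nrow(aln),
              n_positions = attr(aln, "n_positions"),
              total_branch_length = total_branch_length(tree))
  if (!is.null(newick_out)) ape::write.tree(tree, newick_out)
  if (!is.null(report_out))
    jsonlite::write_json(list(n_sequences = res$n_sequences,
                              n_positions = res$n_positions,
                              total_branch_length = res$total_branch_length),
                         report_out, auto_unbox = TRUE, digits = NA)
  invisible(res)
}
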