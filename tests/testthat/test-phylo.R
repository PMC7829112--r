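test_that("complete deletion removes exactly the columns with gaps or ambiguity", {
  clean <- dna_alignment(c(a = "ACGTACGT", b = "ACGTACGA"))
  expect_identical(unclass(complete_deletion(clean))[, ],
                   unclass(clean)[, ])

  gapped <- dna_alignment(c(a = "AC-TA", b = "ACGTN"))
  out <- complete_deletion(gapped)
  expect_equal(attr(out, "n_positions"), 3L)
  expect_equal(paste(out["a", ], collapse = ""), "ACT")

  # brute-force column scan oracle on a random degenerate alignment
  set.seed(20)
  chars <- c("A", "C", "G", "T", "-", "N", "R")
  m <- matrix(sample(chars, 8 * 60, replace = TRUE, prob = c(rep(0.22, 4),
                                                             .04, .04, .04)),
              8, 60, dimnames = list(paste0("s", 1:8), NULL))
  aln <- dna_alignment(m)
  keep <- vapply(seq_len(60), function(j)
    all(aln[, j] %in% c("A", "C", "G", "T")), TRUE)
  out <- complete_deletion(aln)
  expect_equal(attr(out, "n_positions"), sum(keep))
  stripped <- unclass(out); attr(stripped, "n_positions") <- NULL
  expect_identical(unname(stripped), unname(unclass(aln)[, keep]))

  all_gapped <- dna_alignment(c(a = "A-", b = "-A"))
  expect_error(complete_deletion(all_gapped), "no alignment columns")
})

test_that("identical sequences get distance zero", {
  aln <- dna_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                         c = "ACGTACGTTT"))
  d <- composite_likelihood_distances(aln)
  expect_equal(d["a", "b"], 0)
  expect_gt(d["a", "c"], 0)
  expect_equal(unclass(d), t(unclass(d)))
})

test_that("distance reduces to the Jukes-Cantor closed form under symmetry", {
  # 120 positions, uniform base composition, p = 0.1 spread evenly over all
  # 12 ordered substitution types -> the ML solution is k1 = k2 = 1 with
  # d = -(3/4) log(1 - 4p/3)
  b <- c("A", "C", "G", "T")
  s1 <- rep(b, each = 30)
  s2 <- s1
  for (x in 1:4) for (yi in 1:3) s2[(x - 1) * 30 + yi] <- b[setdiff(1:4, x)][yi]
  aln <- dna_alignment(c(seq1 = paste(s1, collapse = ""),
                         seq2 = paste(s2, collapse = "")))
  d <- composite_likelihood_distances(aln)
  expect_equal(d[1, 2], -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-6)
  expect_equal(d[1, 2], 0.107326, tolerance = 1e-5)
  m <- attr(d, "model")
  expect_equal(m$k1, 1, tolerance = 1e-3)
  expect_equal(m$k2, 1, tolerance = 1e-3)
})

test_that("JC-reduced distance grows monotonically with the mismatch fraction", {
  jc_aln <- function(n_mut) {
    b <- c("A", "C", "G", "T")
    s1 <- rep(b, each = 30 * 3)   # 360 positions
    s2 <- s1
    k <- 0
    for (x in 1:4) for (yi in 1:3) for (rep in seq_len(n_mut)) {
      k <- (x - 1) * 90 + (yi - 1) * n_mut + rep
      s2[k] <- b[setdiff(1:4, x)][yi]
    }
    dna_alignment(c(a = paste(s1, collapse = ""),
                    b = paste(s2, collapse = "")))
  }
  ds <- vapply(1:6, function(nm)
    composite_likelihood_distances(jc_aln(nm))[1, 2], 1)
  ps <- (1:6) * 12 / 360
  expect_true(all(diff(ds) > 0))
  expect_true(all(ds >= ps))     # model distance is at least the p-distance
})

test_that("single-pair composite likelihood equals a direct joint ML fit", {
  mod <- tn93_model(pi = c(0.35, 0.15, 0.2, 0.3), k1 = 4, k2 = 7)
  two <- ape::read.tree(text = "(a:0.12,b:0.12);")
  aln <- simulate_alignment(two, 3000, mod, seed = 31)
  d <- composite_likelihood_distances(aln)

  # independent oracle: eigen-decomposed rate matrix, joint 3-parameter fit
  bases <- c("A", "C", "G", "T")
  N <- table(factor(aln[1, ], levels = bases),
             factor(aln[2, ], levels = bases))
  pi <- as.numeric(table(factor(aln, levels = bases))) / length(aln)
  negll <- function(par) {
    k1 <- exp(par[2]); k2 <- exp(par[3]); d <- exp(par[1])
    Q <- matrix(0, 4, 4)
    for (x in 1:4) for (y in 1:4) if (x != y) {
      r <- if (sort(c(x, y))[1] == 1 && sort(c(x, y))[2] == 3) k1
           else if (sort(c(x, y))[1] == 2 && sort(c(x, y))[2] == 4) k2
           else 1
      Q[x, y] <- r * pi[y]
    }
    diag(Q) <- -rowSums(Q)
    scale <- -sum(pi * diag(Q))
    e <- eigen(Q / scale)
    P <- e$vectors %*% diag(exp(e$values * d)) %*% solve(e$vectors)
    J <- pmax(pi * P, 1e-300)
    -sum(N * log(J))
  }
  fit <- optim(c(log(0.1), 0, 0), negll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  expect_equal(d[1, 2], exp(fit$par[1]), tolerance = 1e-5)
  # and the closed-form TN93 distance implemented in ape agrees closely
  dn <- ape::dist.dna(ape::as.DNAbin(apply(unclass(aln), 1:2, tolower)),
                      model = "TN93")
  expect_equal(d[1, 2], as.numeric(dn), tolerance = 0.01)
})

test_that("distances recover the generating divergence of an external simulator", {
  skip_if_not_installed("phangorn")
  # phangorn::simSeq is an independent TN93 route: GTR rates (AC,AG,AT,CG,CT,GT)
  # = (1, k1, 1, 1, k2, 1) with the same stationary frequencies
  pi <- c(0.3, 0.2, 0.2, 0.3); k1 <- 4; k2 <- 6
  tree <- ape::read.tree(text = "(a:0.08,b:0.08);")
  set.seed(55)
  dat <- phangorn::simSeq(tree, l = 50000, Q = c(1, k1, 1, 1, k2, 1),
                          bf = pi, type = "DNA")
  m <- toupper(as.character(dat))
  d <- composite_likelihood_distances(dna_alignment(m))
  expect_equal(d["a", "b"], 0.16, tolerance = 0.02)
  fit <- attr(d, "model")
  expect_equal(fit$k1, k1, tolerance = 0.15)
  expect_equal(fit$k2, k2, tolerance = 0.15)
})

test_that("saturated pairs raise an error naming the pair", {
  set.seed(33)
  b <- c("A", "C", "G", "T")
  m <- rbind(sat1 = sample(b, 400, replace = TRUE),
             sat2 = sample(b, 400, replace = TRUE))
  # force mismatch fraction beyond the stationary expectation
  m[2, ] <- vapply(m[1, ], function(x) sample(setdiff(b, x), 1), "")
  expect_error(composite_likelihood_distances(dna_alignment(m)),
               "saturated pair: sat1 vs sat2")
})

test_that("three-taxon NJ solves the three-point formulas exactly", {
  D <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(D)
  expect_equal(total_branch_length(tr), 0.6)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[["x"]], (0.3 + 0.4 - 0.5) / 2)
  expect_equal(lens[["y"]], (0.3 + 0.5 - 0.4) / 2)
  expect_equal(lens[["z"]], (0.4 + 0.5 - 0.3) / 2)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "at least 3")
  Dbad <- D; Dbad[1, 2] <- 0.31
  expect_error(neighbor_joining(Dbad), "not symmetric")
})

test_that("NJ recovers additive five-taxon trees exactly, taxon order irrelevant", {
  tr <- ape::read.tree(
    text = "(A:0.1,B:0.2,(C:0.15,(D:0.3,E:0.05):0.2):0.1);")
  D <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(D)
  expect_equal(ape::dist.topo(nj, tr), setNames(0, "PH85"),
               ignore_attr = TRUE)
  expect_lt(max(abs(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)] - D)),
            1e-10)
  expect_equal(total_branch_length(nj), sum(tr$edge.length),
               tolerance = 1e-12)
  perm <- sample(5)
  njp <- neighbor_joining(D[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(njp, tr)), 0)
})

test_that("NJ is exact on random additive matrices and matches ape's NJ topology", {
  set.seed(90)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    tr <- random_metric_tree(n)
    D <- ape::cophenetic.phylo(tr)
    nj <- suppressWarnings(neighbor_joining(D))
    expect_equal(as.numeric(ape::dist.topo(nj, tr)), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)] -
                        D)), 1e-10)
    ref <- ape::nj(D)
    expect_equal(as.numeric(ape::dist.topo(nj, ref)), 0)
  }
})

test_that("negative branch lengths are kept with a warning unless clamped", {
  D <- matrix(c(0, 0.1, 5, 5,
                0.1, 0, 0.1, 0.1,
                5, 0.1, 0, 0.1,
                5, 0.1, 0.1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(tr <- neighbor_joining(D), "negative branch lengths")
  expect_true(any(tr$edge.length < 0))
  tr2 <- neighbor_joining(D, clamp_negative = TRUE)
  expect_true(all(tr2$edge.length >= 0))
})

test_that("Newick serialization round-trips topology and branch lengths", {
  tr <- suppressWarnings(neighbor_joining(
    ape::cophenetic.phylo(random_metric_tree(7))))
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_equal(as.numeric(ape::dist.topo(tr, back)), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
})

test_that("the fasta-to-newick chain writes tree and report", {
  mod <- tn93_model(pi = c(.3, .2, .2, .3), k1 = 3, k2 = 5)
  tree <- random_metric_tree(6, 0.05, 0.3)
  aln <- simulate_alignment(tree, 800, mod, seed = 41)
  fa <- withr::local_tempfile(fileext = ".fasta")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  rep <- withr::local_tempfile(fileext = ".json")
  write_fasta(aln, fa)
  res <- build_nj_tree(fa, newick_out = nwk, report_out = rep)
  expect_equal(res$n_sequences, 6L)
  expect_equal(res$n_positions, 800L)
  info <- jsonlite::read_json(rep)
  expect_equal(info$total_branch_length, res$total_branch_length)
  expect_s3_class(ape::read.tree(nwk), "phylo")
})
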