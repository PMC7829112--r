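# Shared helpers: small random objects built in code under fixed seeds.

random_asv_table <- function(n_asvs, n_samples, max_count = 50L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(rpois(n_asvs * n_samples, max_count / 2), n_asvs,
                   n_samples)
  asv_table(counts, sprintf("asv%03d", seq_len(n_asvs)),
            sprintf("s%02d", seq_len(n_samples)))
}

random_profile <- function(n, group, seed = NULL, zero_frac = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  w <- rexp(n)
  w[sample.int(n, round(zero_frac * n))] <- 0
  if (sum(w) == 0) w[1L] <- 1
  structure(list(group = group, n_samples = 1L,
                 abundance = setNames(w / sum(w),
                                      sprintf("asv%03d", seq_len(n)))),
            class = "group_profile")
}

# random unrooted tree with positive branch lengths (ape)
random_metric_tree <- function(n, min_bl = 0.05, max_bl = 0.5) {
  ape::unroot(ape::rtree(n, br = function(k) runif(k, min_bl, max_bl)))
}
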