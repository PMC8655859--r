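# Shared fixtures and independent oracles used across test files.

# Minimal annotation covering a probe-id vector, all autosomal by default.
tiny_annotation <- function(probe_ids, chrom = "1", genes = "",
                            region_class = "open_sea", enhancer = FALSE) {
  data.frame(probe_id = probe_ids, chrom = chrom,
             pos = seq_along(probe_ids), genes = genes,
             region_class = region_class, enhancer = enhancer,
             stringsAsFactors = FALSE)
}

tiny_sheet <- function(outcome, sex = "M", ...) {
  n <- length(outcome)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)), outcome = outcome,
             sex = rep_len(sex, n), recorded_sex = rep_len(sex, n), ...,
             stringsAsFactors = FALSE)
}

rand_beta <- function(n_probes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(runif(n_probes * n_samples, 0.05, 0.95), n_probes, n_samples,
         dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

# Exact Wallenius urn probabilities by sequential-draw dynamic programming:
# g[j+1] = P(X = j) after n biased draws without replacement.
wallenius_urn_pmf <- function(m1, m2, n, w) {
  g <- matrix(0, n + 1, n + 1)
  g[1, 1] <- 1
  for (i in 0:(n - 1)) for (j in 0:i) {
    if (g[i + 1, j + 1] == 0) next
    r1 <- m1 - j
    r2 <- m2 - (i - j)
    tot <- w * r1 + r2
    if (r1 > 0) g[i + 2, j + 2] <- g[i + 2, j + 2] + g[i + 1, j + 1] * w * r1 / tot
    if (r2 > 0) g[i + 2, j + 1] <- g[i + 2, j + 1] + g[i + 1, j + 1] * r2 / tot
  }
  g[n + 1, ]
}
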