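# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))

expit <- function(x) 1 / (1 + exp(-x))

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' @noRd
# Split semicolon-separated gene annotations into deduplicated symbol vectors.
split_genes <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(g) unique(trimws(g[nzchar(trimws(g))])))
}

# Chromosome labels counted as sex chromosomes (manifest styles vary).
is_sex_chrom <- function(chrom) {
  chrom %in% c("X", "Y", "chrX", "chrY", "23", "24")
}

# Inverse of trigamma by Newton iteration on 1/trigamma (convex, monotone).
trigamma_inverse <- function(y) {
  stopifnot(is.numeric(y), length(y) == 1L)
  if (!is.finite(y)) return(if (y > 0) 0 else Inf)
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}
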