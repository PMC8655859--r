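#' Build the gene universe from analyzed probes
#'
#' Splits semicolon-separated gene annotations, deduplicates symbols per
#' probe, restricts to probes present in the result table, and counts
#' analyzed CpGs per gene. Probes missing from the annotation are counted as
#' unannotated and excluded.
#'
#' @param res Site-wise result table (needs `probe_id`).
#' @param ann CpG annotation.
#' @return List of class `gene_universe`: `genes` (character), `cpgs_per_gene`
#'   (named integer), `probe_genes` (list probe -> symbols),
#'   `n_unannotated`.
#' @export
build_universe <- function(res, ann) {
  idx <- match(res$probe_id, ann$probe_id)
  genes_per_probe <- vector("list", nrow(res))
  known <- !is.na(idx)
  genes_per_probe[known] <- split_genes(ann$genes[idx[known]])
  names(genes_per_probe) <- res$probe_id
  counts <- table(unlist(genes_per_probe, use.names = FALSE))
  if (!length(counts)) stop2("no annotated probes: gene universe is empty")
  structure(list(
    genes = names(counts),
    cpgs_per_gene = stats::setNames(as.integer(counts), names(counts)),
    probe_genes = genes_per_probe,
    n_unannotated = sum(!known | lengths(genes_per_probe) == 0)
  ), class = "gene_universe")
}

#' Genes with at least one CpG below a p-value threshold
#'
#' Strict inequality `p < threshold`; a gene qualifies if any of its
#' analyzed CpGs passes.
#'
#' @param res Site-wise result table (`probe_id`, `p_value`).
#' @param ann CpG annotation (or a prebuilt `gene_universe`).
#' @param threshold P-value threshold in (0, 1\].
#' @return Character vector of gene symbols.
#' @export
nominal_gene_set <- function(res, ann, threshold) {
  if (threshold <= 0 || threshold > 1) stop2("threshold must be in (0, 1]")
  uni <- if (inherits(ann, "gene_universe")) ann else build_universe(res, ann)
  hit <- res$probe_id[!is.na(res$p_value) & res$p_value < threshold]
  out <- unlist(uni$probe_genes[hit], use.names = FALSE)
  sort(unique(as.character(out %||% character(0))))
}

#' Risk-gene enrichment curve over a p-value threshold grid
#'
#' At each threshold, builds the gene-level 2x2 table (risk vs non-risk by
#' selected vs not, over the gene universe), tests it with the Pearson
#' chi-square (no continuity correction), and records the expected overlap
#' `|risk| * |selected| / |universe|`. As a negative control the curve is
#' recomputed for `n_perm` random gene sets of the same size as the risk set
#' drawn uniformly without replacement from the universe. Optionally the
#' analysis is first restricted to a probe subset (e.g. meQTL-target CpGs),
#' rebuilding the universe from the restricted probes.
#'
#' @param res Site-wise result table.
#' @param ann CpG annotation.
#' @param risk Gene set (list with `genes`) of risk genes.
#' @param grid Threshold grid (default the standard 15-point grid
#'   0.0001 ... 0.99).
#' @param n_perm Number of random-gene-set permutation curves (default 10).
#' @param seed Seed for the permutation draws.
#' @param restrict_cpgs Optional probe-id vector to restrict the analysis to.
#' @return List of class `enrichment_curve` with `curve` (data frame:
#'   `threshold`, `selected_genes`, `observed`, `expected`, `chi2`,
#'   `p_value`), `perm_p` (n_perm x thresholds matrix of permutation-control
#'   chi-square p-values), `universe_size`, `risk_in_universe`, `restricted`.
#' @export
enrichment_curve <- function(res, ann, risk,
                             grid = enrichment_thresholds(),
                             n_perm = 10, seed = 1, restrict_cpgs = NULL) {
  restricted <- !is.null(restrict_cpgs)
  if (restricted) res <- res[res$probe_id %in% restrict_cpgs, , drop = FALSE]
  uni <- build_universe(res, ann)
  risk_in <- intersect(risk$genes, uni$genes)
  if (!length(risk_in)) stop2("no risk genes present in the gene universe")
  sel_sets <- lapply(grid, function(th) nominal_gene_set(res, uni, th))

  one_curve <- function(risk_genes) {
    t(vapply(seq_along(grid), function(i) {
      enrichment_cells(sel_sets[[i]], risk_genes, uni$genes)
    }, numeric(5)))
  }
  obs <- one_curve(risk_in)
  curve <- data.frame(threshold = grid,
                      selected_genes = lengths(sel_sets),
                      observed = obs[, 1], expected = obs[, 2],
                      chi2 = obs[, 3], p_value = obs[, 4])
  set.seed(as.integer(seed))
  perm_p <- matrix(NA_real_, n_perm, length(grid),
                   dimnames = list(NULL, paste0("t", grid)))
  for (b in seq_len(n_perm)) {
    rnd <- sample(uni$genes, length(risk_in))
    perm_p[b, ] <- one_curve(rnd)[, 4]
  }
  structure(list(curve = curve, perm_p = perm_p,
                 universe_size = length(uni$genes),
                 risk_in_universe = length(risk_in),
                 restricted = restricted, seed = seed),
            class = "enrichment_curve")
}

# observed, expected, chi2, p, selected for one threshold
enrichment_cells <- function(selected, risk_genes, universe) {
  a <- length(intersect(risk_genes, selected))
  b <- length(risk_genes) - a
  c_ <- length(selected) - a
  d <- length(universe) - a - b - c_
  expected <- length(risk_genes) * length(selected) / length(universe)
  tab <- matrix(c(a, c_, b, d), 2)
  chi2 <- NA_real_; p <- NA_real_
  if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    tst <- chi_square_test(tab)
    chi2 <- tst$chi2; p <- tst$p_value
  }
  c(a, expected, chi2, p, length(selected))
}

#' The standard enrichment threshold grid
#' @return Numeric vector of 15 p-value thresholds.
#' @export
enrichment_thresholds <- function() {
  c(0.0001, 0.001, 0.005, 0.01, 0.02, 0.03, 0.04, 0.05,
    0.1, 0.15, 0.2, 0.3, 0.5, 0.7, 0.99)
}

#' Cross-tissue overlap of nominal gene sets
#'
#' Inclusion-exclusion (Venn) partition of gene membership across tissues,
#' tabulated separately for risk and non-risk genes.
#'
#' @param nominal_sets Named list of per-tissue gene vectors (>= 2 tissues).
#' @param risk Risk gene set.
#' @return List with `risk_counts` and `nonrisk_counts` (named by membership
#'   pattern, e.g. `"110"` = in tissues 1 and 2 only), `all_tissue_risk` and
#'   `all_tissue_nonrisk` (counts in every tissue).
#' @export
cross_tissue_overlap <- function(nominal_sets, risk) {
  if (length(nominal_sets) < 2L) stop2("need at least 2 tissues")
  genes <- sort(unique(unlist(nominal_sets)))
  memb <- vapply(nominal_sets, function(s) genes %in% s, logical(length(genes)))
  pattern <- apply(memb, 1L, function(r) paste(as.integer(r), collapse = ""))
  is_risk <- genes %in% risk$genes
  count_patterns <- function(pp) {
    if (!length(pp)) return(stats::setNames(integer(0), character(0)))
    tab <- table(pp)
    stats::setNames(as.integer(tab), names(tab))
  }
  all_pat <- strrep("1", length(nominal_sets))
  risk_counts <- count_patterns(pattern[is_risk])
  nonrisk_counts <- count_patterns(pattern[!is_risk])
  list(risk_counts = risk_counts, nonrisk_counts = nonrisk_counts,
       all_tissue_risk = sum(pattern == all_pat & is_risk),
       all_tissue_nonrisk = sum(pattern == all_pat & !is_risk))
}

#' Gene ontology enrichment with probe-count bias correction
#'
#' Tests each category for over-representation among genes with a nominally
#' significant CpG, using the Wallenius noncentral hypergeometric
#' distribution. Genes with many analyzed CpGs are more likely to be
#' selected by chance; the per-gene selection probability is estimated as a
#' smoothed (lowess) function of log probe count, converted to sampling
#' odds, and each category's odds parameter is the mean odds of its genes
#' relative to the rest of the universe.
#'
#' @param res Site-wise result table.
#' @param ann CpG annotation.
#' @param go_map Data frame mapping `gene` to `category`.
#' @param threshold Nominal p-value threshold for gene selection.
#' @param min_genes Minimum universe genes per category (smaller categories
#'   are skipped).
#' @return Data frame `category`, `n_genes`, `n_selected`, `odds`,
#'   `p_value`, sorted by p-value.
#' @export
ontology_enrichment <- function(res, ann, go_map, threshold = 0.05, min_genes = 5) {
  if (!all(c("gene", "category") %in% colnames(go_map))) {
    stop2("go_map needs 'gene' and 'category' columns")
  }
  uni <- build_universe(res, ann)
  selected <- nominal_gene_set(res, uni, threshold)
  sel_flag <- uni$genes %in% selected
  ncpg <- uni$cpgs_per_gene[uni$genes]
  prob <- gene_selection_bias(ncpg, sel_flag)
  odds <- prob / (1 - prob)
  names(odds) <- uni$genes

  go_map <- go_map[go_map$gene %in% uni$genes, , drop = FALSE]
  cats <- split(go_map$gene, go_map$category)
  cats <- lapply(cats, unique)
  cats <- cats[lengths(cats) >= min_genes]
  if (!length(cats)) stop2("no categories with at least ", min_genes, " universe genes")
  rows <- lapply(names(cats), function(cat) {
    g <- cats[[cat]]
    in_cat <- uni$genes %in% g
    w <- if (all(in_cat)) 1 else mean(odds[in_cat]) / mean(odds[!in_cat])
    p <- wallenius_test(sum(in_cat & sel_flag), sum(in_cat),
                        sum(sel_flag), length(uni$genes), odds = w)
    data.frame(category = cat, n_genes = sum(in_cat),
               n_selected = sum(in_cat & sel_flag), odds = w, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$category), ]
  rownames(out) <- NULL
  out
}

# Smoothed probability of gene selection as a function of probe count.
gene_selection_bias <- function(ncpg, selected) {
  x <- log(ncpg)
  if (stats::sd(x) == 0) {
    # no probe-count variation: flat bias, Wallenius reduces to hypergeometric
    return(rep(mean(selected), length(x)))
  }
  fit <- stats::lowess(x, as.numeric(selected), f = 2 / 3)
  # lowess returns one fitted value per distinct x; ties collapse by design
  prob <- suppressWarnings(stats::approx(fit$x, fit$y, xout = x, rule = 2)$y)
  pmin(pmax(prob, 1e-4), 1 - 1e-4)
}

#' Aggregate ontology results across tissues by rank sum
#'
#' Ranks categories by p-value within each tissue (ties get average ranks)
#' and sums the ranks across tissues; categories missing from a tissue are
#' flagged and get a missing rank.
#'
#' @param per_tissue_go_tables Named list of [ontology_enrichment()] tables.
#' @return Data frame `category`, per-tissue rank columns, `rank_sum`,
#'   `complete` (present in all tissues), sorted by rank sum.
#' @export
rank_sum_across_tissues <- function(per_tissue_go_tables) {
  if (is.null(names(per_tissue_go_tables))) {
    names(per_tissue_go_tables) <- paste0("tissue", seq_along(per_tissue_go_tables))
  }
  cats <- sort(unique(unlist(lapply(per_tissue_go_tables, `[[`, "category"))))
  ranks <- sapply(per_tissue_go_tables, function(tab) {
    r <- rank(tab$p_value)   # average ranks on ties
    r[match(cats, tab$category)]
  })
  ranks <- matrix(ranks, nrow = length(cats),
                  dimnames = list(NULL, names(per_tissue_go_tables)))
  out <- data.frame(category = cats, ranks,
                    rank_sum = rowSums(ranks),
                    complete = !apply(is.na(ranks), 1L, any),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$rank_sum), ]
  rownames(out) <- NULL
  out
}
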