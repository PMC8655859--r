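#' Validate a beta-value matrix
#'
#' A beta matrix is a numeric CpG-by-sample matrix of methylation proportions
#' with unique probe ids as row names and unique sample ids as column names.
#' All values must be finite and in \[0, 1\].
#'
#' @param b Numeric matrix to validate.
#' @param what Label used in error messages.
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_beta_matrix <- function(b, what = "beta matrix") {
  if (!is.matrix(b) || !is.numeric(b)) {
    stop2(what, " must be a numeric matrix")
  }
  if (is.null(rownames(b)) || is.null(colnames(b))) {
    stop2(what, " must have probe ids as rownames and sample ids as colnames")
  }
  dup <- unique(rownames(b)[duplicated(rownames(b))])
  if (length(dup)) {
    stop2(what, " has duplicated probe ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  dup <- unique(colnames(b)[duplicated(colnames(b))])
  if (length(dup)) {
    stop2(what, " has duplicated sample ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  bad <- which(!is.finite(b) | b < 0 | b > 1)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(b))
    stop2(what, " has ", length(bad), " value(s) outside [0,1] or non-finite; ",
          "first at probe '", rownames(b)[i[1]], "', sample '", colnames(b)[i[2]],
          "' (value ", format(b[bad[1]]), ")")
  }
  invisible(b)
}

#' Read a CpG-by-sample matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of probe ids; the
#' delimiter (tab or comma) is detected from the header line.
#'
#' @param path File path.
#' @param check_range If `TRUE` (the beta-matrix contract) values outside
#'   \[0,1\] are rejected; use `FALSE` for unbounded matrices such as
#'   detection p-values stored on other scales or M-values.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_beta_matrix <- function(path, check_range = TRUE) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2L) stop2("matrix file must have a probe-id column plus data columns")
  ids <- as.character(tab[[1L]])
  for (j in seq(2L, ncol(tab))) {
    col <- tab[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(col))
      if (length(bad)) {
        stop2("non-numeric cell at row '", ids[bad[1]], "', column '",
              colnames(tab)[j], "' (value '", col[bad[1]], "')")
      }
      tab[[j]] <- num
    }
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (check_range) validate_beta_matrix(m) else {
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) stop2("duplicated probe ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  m
}

#' Write a CpG-by-sample matrix as tab-delimited text
#'
#' @param b Matrix with probe rownames and sample colnames.
#' @param path Output file path.
#' @param id_col Name of the probe-id column in the header.
#' @export
write_beta_matrix <- function(b, path, id_col = "probe_id") {
  df <- data.frame(rownames(b), b, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert beta values to M-values
#'
#' M = log2((beta + offset) / (1 - beta + offset)), the log2 ratio of
#' methylated to unmethylated signal. A small positive offset keeps the
#' transform finite at beta of exactly 0 or 1.
#'
#' @param b Beta matrix (or numeric vector) of values in \[0,1\].
#' @param offset Nonnegative stabilizing offset (default 0.01).
#' @return Matrix (or vector) of M-values.
#' @export
beta_to_m <- function(b, offset = 0.01) {
  if (offset < 0) stop2("offset must be nonnegative")
  if (offset == 0 && any(b == 0 | b == 1, na.rm = TRUE)) {
    stop2("beta values of exactly 0 or 1 give non-finite M-values; use a positive offset")
  }
  log2((b + offset) / (1 - b + offset))
}

#' Convert M-values back to beta values
#'
#' Exact inverse of [beta_to_m()] only when `offset = 0`; with a positive
#' offset the mapping is the offset-free inverse applied to the same scale.
#'
#' @param m M-value matrix.
#' @return Beta matrix.
#' @export
m_to_beta <- function(m) {
  x <- 2^m
  x / (1 + x)
}

#' Read a 450k-manifest-style CpG annotation table
#'
#' Accepts either Illumina manifest column names (`IlmnID`, `CHR`, `MAPINFO`,
#' `UCSC_RefGene_Name`, `Relation_to_UCSC_CpG_Island`, `Enhancer`) or the
#' standardized names used throughout this package (`probe_id`, `chrom`,
#' `pos`, `genes`, `region_class`, `enhancer`). Island relation labels
#' `N_Shore`/`S_Shore` collapse to `shore`, `N_Shelf`/`S_Shelf` to `shelf`,
#' `Island` to `island`, and anything absent to `open_sea`; `enhancer` is an
#' overlapping (non-exclusive) flag. Positions are 1-based manifest
#' coordinates.
#'
#' @param path File path (tab-delimited, header row).
#' @return `data.frame` with columns `probe_id`, `chrom`, `pos` (integer),
#'   `genes` (semicolon-separated symbols, possibly empty), `region_class`
#'   (one of island/shore/shelf/open_sea) and `enhancer` (logical).
#' @export
read_cpg_annotation <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character")
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% colnames(tab)) return(tab[[nm]])
    NULL
  }
  probe_id <- pick("IlmnID", "probe_id")
  chrom <- pick("CHR", "chrom")
  pos <- pick("MAPINFO", "pos")
  genes <- pick("UCSC_RefGene_Name", "genes") %||% rep("", nrow(tab))
  rel <- pick("Relation_to_UCSC_CpG_Island", "region_class") %||% rep("", nrow(tab))
  enh <- pick("Enhancer", "enhancer") %||% rep("", nrow(tab))
  if (is.null(probe_id) || is.null(chrom) || is.null(pos)) {
    stop2("annotation must provide probe id, chromosome and position columns")
  }
  ann <- data.frame(
    probe_id = probe_id,
    chrom = chrom,
    pos = as.integer(pos),
    genes = vapply(split_genes(genes), paste, "", collapse = ";"),
    region_class = normalize_region_class(rel),
    enhancer = toupper(trimws(enh)) %in% c("TRUE", "1", "T", "YES"),
    stringsAsFactors = FALSE
  )
  validate_cpg_annotation(ann)
}

normalize_region_class <- function(x) {
  x <- trimws(as.character(x))
  out <- rep("open_sea", length(x))
  out[grepl("island", x, ignore.case = TRUE)] <- "island"
  out[grepl("shore", x, ignore.case = TRUE)] <- "shore"
  out[grepl("shelf", x, ignore.case = TRUE)] <- "shelf"
  out[x %in% c("open_sea", "OpenSea")] <- "open_sea"
  out
}

#' Validate a CpG annotation table
#' @param ann Data frame as produced by [read_cpg_annotation()].
#' @return The validated annotation, invisibly usable.
#' @export
validate_cpg_annotation <- function(ann) {
  need <- c("probe_id", "chrom", "pos", "genes", "region_class", "enhancer")
  miss <- setdiff(need, colnames(ann))
  if (length(miss)) stop2("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id)) stop2("annotation has duplicated probe ids")
  bad <- setdiff(unique(ann$region_class), c("island", "shore", "shelf", "open_sea"))
  if (length(bad)) stop2("unknown region class: ", paste(bad, collapse = ", "))
  ann
}

#' Write a CpG annotation table with Illumina-manifest column names
#' @param ann Annotation data frame.
#' @param path Output path.
#' @export
write_cpg_annotation <- function(ann, path) {
  rel <- c(island = "Island", shore = "N_Shore", shelf = "N_Shelf", open_sea = "")
  out <- data.frame(
    IlmnID = ann$probe_id,
    CHR = ann$chrom,
    MAPINFO = ann$pos,
    UCSC_RefGene_Name = ann$genes,
    Relation_to_UCSC_CpG_Island = rel[ann$region_class],
    Enhancer = ifelse(ann$enhancer, "TRUE", ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' One row per sample; must contain `sample_id` and a 3-level `outcome`
#' column coded `TD`, `nonTD`, `ASD` (typically developing, non-typically
#' developing, autism spectrum disorder at the 36-month assessment).
#'
#' @param path File path (tab-delimited).
#' @return Data frame, outcome as a factor with levels TD, nonTD, ASD.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE, comment.char = "")
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet
#' @param sheet Data frame with `sample_id` and `outcome`.
#' @return The sheet with `outcome` as factor TD/nonTD/ASD.
#' @export
validate_sample_sheet <- function(sheet) {
  if (!all(c("sample_id", "outcome") %in% colnames(sheet))) {
    stop2("sample sheet needs 'sample_id' and 'outcome' columns")
  }
  if (anyDuplicated(sheet$sample_id)) stop2("sample sheet has duplicated sample ids")
  bad <- setdiff(unique(as.character(sheet$outcome)), c("TD", "nonTD", "ASD"))
  if (length(bad)) stop2("outcome must be TD/nonTD/ASD; found: ", paste(bad, collapse = ", "))
  sheet$outcome <- factor(as.character(sheet$outcome), levels = c("TD", "nonTD", "ASD"))
  sheet
}

#' Write a sample sheet as tab-delimited text
#' @param sheet Sample sheet data frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list as a gene set
#'
#' One symbol per line; symbols are whitespace-trimmed, matched
#' case-sensitively and deduplicated.
#'
#' @param path File path.
#' @param name Label for the set (default: file base name).
#' @return List with `name` and `genes` (character vector).
#' @export
read_gene_set <- function(path, name = NULL) {
  genes <- unique(trimws(readLines(path)))
  genes <- genes[nzchar(genes)]
  gene_set(genes, name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct a gene set
#' @param genes Character vector of gene symbols.
#' @param name Label.
#' @return List with `name` and deduplicated `genes`.
#' @export
gene_set <- function(genes, name = "gene_set") {
  genes <- unique(trimws(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop2("gene set '", name, "' is empty")
  list(name = name, genes = genes)
}
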