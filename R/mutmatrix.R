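# Binary mutation-by-sample matrix: construction, filtering, trunk removal.

#' Validate a binary mutation-by-sample matrix
#'
#' Wraps an m x n 0/1 matrix (rows = mutations, columns = samples) after
#' checking identifiers and entries. Rows that are zero in every sample carry
#' no tree information and are dropped; their count is kept in the
#' `"dropped"` attribute so that mutation accounting stays exact.
#'
#' @param x Matrix or data frame of 0/1 entries with row names (mutation ids)
#'   and column names (sample ids).
#' @return An integer matrix of class `mutation_matrix` with attribute
#'   `dropped` (number of all-zero rows removed).
#' @export
mutation_matrix <- function(x) {
  if (inherits(x, "mutation_matrix")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("expected a matrix of 0/1 entries")
  if (is.null(colnames(x))) stop("sample ids (column names) are required")
  if (is.null(rownames(x))) rownames(x) <- paste0("r", seq_len(nrow(x)))
  colnames(x) <- trimws(colnames(x)); rownames(x) <- trimws(rownames(x))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample id: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyDuplicated(rownames(x)))
    stop("duplicate mutation_id: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  storage.mode(x) <- "integer"
  if (anyNA(x) || !all(x == 0L | x == 1L)) stop("entries must all be 0 or 1")
  keep <- rowSums(x) > 0L
  dropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) == 0L) stop("no mutations: every row is absent in all samples")
  structure(x, dropped = dropped, class = c("mutation_matrix", class(x)))
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat("Binary mutation matrix:", nrow(x), "mutations x", ncol(x), "samples",
      sprintf("(%d all-zero rows dropped)\n", attr(x, "dropped")))
  invisible(x)
}

# A VAF table is a data.frame with columns mutation_id, optionally gene,
# then one numeric column per sample. Missing VAFs are treated as 0.
vaf_parts <- function(records) {
  stopifnot(is.data.frame(records))
  if (!"mutation_id" %in% names(records)) stop("column 'mutation_id' is required")
  meta <- intersect(c("mutation_id", "gene"), names(records))
  samp <- names(records)[!(names(records) %in% meta)]
  if (length(samp) == 0L) stop("no sample columns found")
  if (anyDuplicated(samp))
    stop("duplicate sample column: ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "))
  v <- as.matrix(records[samp])
  storage.mode(v) <- "double"
  v[is.na(v)] <- 0
  if (any(v < 0 | v > 1)) stop("VAF values must lie in [0, 1]")
  rownames(v) <- trimws(as.character(records$mutation_id))
  list(vaf = v,
       gene = if ("gene" %in% meta) trimws(as.character(records$gene)) else NULL)
}

#' Binarize variant allele frequencies into a mutation matrix
#'
#' A mutation is called present in a sample when its VAF is greater than or
#' equal to `vaf_threshold` (equality counts as present); missing values are
#' treated as absent. Rows absent in every sample are dropped with a count.
#'
#' @param records Data frame with a `mutation_id` column, an optional `gene`
#'   column, and one numeric VAF column per sample; or a numeric VAF matrix
#'   with mutation row names and sample column names.
#' @param samples Optional character vector restricting/ordering the sample
#'   columns used.
#' @param vaf_threshold Presence threshold in \[0, 1\]. Default 0.01, the
#'   permissive setting appropriate when input mutations are already
#'   confidently called somatic.
#' @return A [mutation_matrix()]. When a `gene` column is present a named
#'   `gene_map` attribute (mutation id -> gene symbol) is attached.
#' @export
build_binary_matrix <- function(records, samples = NULL, vaf_threshold = 0.01) {
  stopifnot(is.numeric(vaf_threshold), length(vaf_threshold) == 1L,
            vaf_threshold >= 0, vaf_threshold <= 1)
  gene <- NULL
  if (is.data.frame(records)) {
    parts <- vaf_parts(records)
    v <- parts$vaf; gene <- parts$gene
  } else if (is.matrix(records)) {
    v <- records
    storage.mode(v) <- "double"
    v[is.na(v)] <- 0
  } else stop("records must be a data frame or numeric matrix")
  if (nrow(v) == 0L) stop("no mutations")
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing)) stop("unknown sample: ", paste(missing, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  if (anyDuplicated(rownames(v)))
    stop("duplicate mutation_id: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  m <- (v >= vaf_threshold) * 1L
  M <- mutation_matrix(m)
  if (!is.null(gene)) {
    names(gene) <- trimws(as.character(records$mutation_id))
    attr(M, "gene_map") <- gene[rownames(M)]
  }
  M
}

#' Optional pre-filter of mutations by allele frequency
#'
#' Keeps a mutation when its maximum VAF across samples is at least
#' `af_cutoff`, so a mutation confidently seen in any one sample is retained
#' in all samples and the binary presence pattern stays intact. Intended for
#' patients with very large mutation burdens; default cutoff 0.1.
#'
#' @param records VAF table (data frame) or numeric VAF matrix, as in
#'   [build_binary_matrix()].
#' @param af_cutoff Minimum per-mutation maximum VAF in \[0, 1\].
#' @return The filtered records, same type and row order as the input.
#' @export
apply_af_filter <- function(records, af_cutoff = 0.1) {
  stopifnot(is.numeric(af_cutoff), length(af_cutoff) == 1L,
            af_cutoff >= 0, af_cutoff <= 1)
  v <- if (is.data.frame(records)) vaf_parts(records)$vaf else records
  v[is.na(v)] <- 0
  keep <- apply(v, 1L, max) >= af_cutoff
  if (is.data.frame(records)) records[keep, , drop = FALSE]
  else records[keep, , drop = FALSE]
}

#' Extract the root trunk of a mutation matrix
#'
#' Mutations present in every sample are the intersection across biopsies:
#' they predate the divergence of all samples and form the root trunk of the
#' tree, with the trunk length equal to their number. They are removed
#' before split finding.
#'
#' @param M A [mutation_matrix()] (or coercible matrix) with >= 2 samples.
#' @return A list of class `trunk_result` with `trunk_mutations` (character),
#'   `trunk_length`, and `filtered` (the matrix without trunk rows; may have
#'   zero rows).
#' @export
extract_root_trunk <- function(M) {
  M <- mutation_matrix(M)
  if (ncol(M) < 2L) stop("at least two samples are required")
  trunk <- rownames(M)[rowSums(M) == ncol(M)]
  filtered <- M[setdiff(rownames(M), trunk), , drop = FALSE]
  structure(list(trunk_mutations = trunk, trunk_length = length(trunk),
                 filtered = filtered),
            class = "trunk_result")
}

#' @export
print.trunk_result <- function(x, ...) {
  cat("Root trunk:", x$trunk_length, "mutations shared by all samples;",
      nrow(x$filtered), "rows remain after removal\n")
  invisible(x)
}
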