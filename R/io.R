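# Readers and writers for the tab-separated table dialects, multi-sample
# VCF ingestion, and Newick / report output.

#' Read a per-mutation per-sample VAF table
#'
#' Expected header: `mutation_id<TAB>gene<TAB><sample1>...<sampleN>` (the
#' `gene` column is optional), VAFs as decimals in \[0, 1\]. Identifiers are
#' whitespace-trimmed and case-sensitive.
#'
#' @param path Path to the TSV file.
#' @return Data frame suitable for [build_binary_matrix()] / [pti()].
#' @export
read_vaf_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"mutation_id" %in% names(df))
    stop("first column must be named 'mutation_id' (line 1 of ", path, ")")
  names(df) <- trimws(names(df))
  df$mutation_id <- trimws(as.character(df$mutation_id))
  samp <- names(df)[!(names(df) %in% c("mutation_id", "gene"))]
  if (anyDuplicated(samp))
    stop("duplicate sample column: ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "))
  for (s in samp) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    bad <- which(is.na(v) & !is.na(df[[s]]) & nzchar(trimws(df[[s]])))
    if (length(bad))
      stop("non-numeric VAF in column '", s, "' at data line ", bad[1L])
    df[[s]] <- v
  }
  df
}

#' Read a pre-binarized mutation-by-sample table
#'
#' Same shape as the VAF table but with 0/1 entries.
#'
#' @param path Path to the TSV file.
#' @return A [mutation_matrix()].
#' @export
read_binary_matrix <- function(path) {
  df <- read_vaf_table(path)
  parts <- vaf_parts(df)
  v <- parts$vaf
  if (!all(v %in% c(0, 1)))
    stop("binary input contains entries other than 0/1")
  M <- mutation_matrix(v)
  if (!is.null(parts$gene)) {
    gm <- parts$gene
    names(gm) <- trimws(as.character(df$mutation_id))
    attr(M, "gene_map") <- gm[rownames(M)]
  }
  M
}

#' Derive per-sample VAFs from a multi-sample VCF
#'
#' Uses the per-sample `AF` FORMAT field when present; otherwise computes
#' `VAF = alt_depth / (ref_depth + alt_depth)` from the `AD` field. Sites
#' with neither field are rejected. Mutation ids are `CHROM:POS:REF:ALT`.
#'
#' @param path Path to a VCF (v4.x) file.
#' @return VAF table data frame as from [read_vaf_table()].
#' @export
read_vcf_vafs <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required to read VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  ids <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
               sep = ":")
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF has no per-sample genotype columns")
  format_keys <- unique(unlist(strsplit(gt[, 1L], ":", fixed = TRUE)))
  if ("AF" %in% format_keys) {
    af <- vcfR::extract.gt(v, element = "AF", as.numeric = TRUE)
  } else if ("AD" %in% format_keys) {
    ad <- vcfR::extract.gt(v, element = "AD")
    split2 <- function(x) {
      p <- strsplit(x, ",", fixed = TRUE)
      vapply(p, function(q) {
        if (length(q) < 2L || anyNA(suppressWarnings(as.numeric(q[1:2]))))
          return(NA_real_)
        d <- as.numeric(q[1L]) + as.numeric(q[2L])
        if (d == 0) 0 else as.numeric(q[2L]) / d
      }, numeric(1))
    }
    af <- apply(ad, 2L, split2)
    if (is.null(dim(af))) af <- matrix(af, nrow = nrow(gt),
                                       dimnames = list(NULL, colnames(gt)[-1L]))
  } else {
    stop("VCF lacks both AF and AD FORMAT fields; cannot derive VAFs")
  }
  af[is.na(af)] <- 0
  df <- data.frame(mutation_id = ids, stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (s in colnames(af)) df[[s]] <- as.numeric(af[, s])
  df
}

#' Write a tree as Newick
#'
#' Branch lengths are mutation counts; the trunk is written as the root
#' edge.
#'
#' @param tree A `pti_tree`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pti_newick <- function(tree, path) {
  ph <- as.phylo.pti_tree(as_pti_tree(tree))
  ape::write.tree(ph, file = path)
  invisible(path)
}
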