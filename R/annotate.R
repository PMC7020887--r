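# Driver-gene annotation of tree branches.

#' Annotate tree branches with driver-gene mutations
#'
#' Pure decoration: for every mutation assigned to a branch whose gene is in
#' the driver list, one annotation row is emitted. The same gene may appear
#' on several branches; the `recurrence_flag` column records whether repeats
#' are the same variant or distinct variants of one gene. Unassigned
#' mutations are never annotated. Gene symbols are matched case-insensitively
#' after whitespace trimming.
#'
#' @param tree A `pti_tree` (typically the optimal tree of a fit).
#' @param gene_map Named character vector mapping mutation id to gene symbol,
#'   or a data frame with columns `mutation_id` and `gene`. May be partial;
#'   unmapped mutations are skipped.
#' @param drivers Character vector of driver gene symbols (non-empty).
#' @return Data frame with columns `branch_id`, `gene`, `mutation_id`,
#'   `recurrence_flag` (`"single"`, `"same_mutation"` or
#'   `"different_mutations"`); zero rows when no driver mutation lies on any
#'   branch.
#' @export
annotate_drivers <- function(tree, gene_map, drivers) {
  if (is.data.frame(gene_map)) {
    stopifnot(all(c("mutation_id", "gene") %in% names(gene_map)))
    gm <- as.character(gene_map$gene)
    names(gm) <- as.character(gene_map$mutation_id)
    gene_map <- gm
  }
  if (length(drivers) == 0L) stop("driver list must be non-empty")
  norm <- function(x) toupper(trimws(x))
  drivers <- unique(norm(drivers))
  tb <- branch_table(tree)
  rows <- list()
  for (i in seq_len(nrow(tb))) {
    muts <- strsplit(tb$mutation_ids[i], ",", fixed = TRUE)[[1]]
    muts <- muts[nzchar(muts)]
    for (mu in muts) {
      g <- unname(gene_map[mu])
      if (length(g) != 1L || is.na(g) || !nzchar(trimws(g))) next
      if (norm(g) %in% drivers)
        rows[[length(rows) + 1L]] <- data.frame(
          branch_id = tb$node_id[i], gene = trimws(g), mutation_id = mu,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(branch_id = character(0), gene = character(0),
                      mutation_id = character(0),
                      recurrence_flag = character(0),
                      stringsAsFactors = FALSE))
  ann <- do.call(rbind, rows)
  flag <- character(nrow(ann))
  for (g in unique(norm(ann$gene))) {
    idx <- norm(ann$gene) == g
    if (sum(idx) == 1L) flag[idx] <- "single"
    else if (length(unique(ann$mutation_id[idx])) < sum(idx))
      flag[idx] <- "same_mutation"
    else flag[idx] <- "different_mutations"
  }
  ann$recurrence_flag <- flag
  ann
}

#' Read a driver gene list
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of gene symbols.
#' @export
read_driver_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  unique(x[nzchar(x)])
}
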