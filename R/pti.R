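#' Fit a tumor phylogeny from presence/absence of somatic mutations
#'
#' `pti()` is the top-level fitting function. It takes per-mutation
#' per-sample variant allele frequencies (or an already binarized 0/1
#' matrix), binarizes at `vaf_threshold`, optionally pre-filters mutations by
#' maximum allele frequency, and reconstructs the rooted phylogenetic tree of
#' the samples by iterative top-down optimal branch splitting. Branch lengths
#' are mutation counts; the root trunk carries the mutations shared by all
#' samples. When known driver genes are supplied, branches are annotated
#' with the driver mutations they carry.
#'
#' At each node holding sample set G the algorithm enumerates every two-way
#' split shape (t, |G| - t) and every sample combination within a shape,
#' counts the mutations shared by the larger group (theta), and selects the
#' split size whose best combination most dominates its second best (the
#' split ratio). Tied optima are all pursued and the resulting candidate
#' trees ranked by the aggregated mutation-count weight [tree_weight()].
#' Internal branches supported by no mutation are collapsed, so true
#' multifurcations are recovered.
#'
#' @param x A VAF table (data frame with `mutation_id`, optional `gene`, and
#'   one numeric column per sample), a numeric VAF matrix, or a binary
#'   [mutation_matrix()].
#' @param vaf_threshold Presence threshold for binarization (default 0.01).
#'   This is the method's single scientific parameter.
#' @param af_filter Optional maximum-VAF pre-filter cutoff (e.g. 0.1);
#'   `NULL` (default) disables it. Ignored for binary input.
#' @param binary Set `TRUE` to force 0/1 interpretation of a numeric input.
#' @param drivers Optional character vector of driver gene symbols (see
#'   [annotate_drivers()]).
#' @param gene_map Optional named character vector mapping mutation ids to
#'   gene symbols; defaults to the `gene` column of a VAF table input.
#' @param max_trees Cap on candidate trees from cascading ties.
#' @return An object of class `pti_fit` with components `trees` (candidate
#'   trees, best first), `weights` (their tree weights), `optimal`,
#'   `multiple_solutions`, `trunk_mutations`, `trunk_length`, `unassigned`
#'   (mutations placed on no branch of the optimal tree), `dropped_rows`
#'   (all-zero rows removed), `n_samples`, `n_mutations`, and `annotations`
#'   (if drivers were supplied).
#' @examples
#' vaf <- data.frame(
#'   mutation_id = paste0("M", 1:6),
#'   A = c(0.4, 0.3, 0.3, 0.2, 0.0, 0.0),
#'   B = c(0.5, 0.4, 0.2, 0.0, 0.3, 0.0),
#'   C = c(0.4, 0.0, 0.0, 0.0, 0.0, 0.4))
#' fit <- pti(vaf, vaf_threshold = 0.05)
#' fit$trunk_length   # mutations shared by A, B and C
#' print(fit$optimal)
#' @seealso [infer_trees()], [similarity_score()], [sim_scenario()]
#' @export
pti <- function(x, vaf_threshold = 0.01, af_filter = NULL, binary = FALSE,
                drivers = NULL, gene_map = NULL, max_trees = 100L) {
  cl <- match.call()
  if (inherits(x, "mutation_matrix") || isTRUE(binary)) {
    M <- mutation_matrix(x)
  } else {
    if (!is.null(af_filter)) x <- apply_af_filter(x, af_filter)
    M <- build_binary_matrix(x, vaf_threshold = vaf_threshold)
  }
  if (is.null(gene_map)) gene_map <- attr(M, "gene_map")
  fit <- infer_trees(M, max_trees = max_trees)
  fit$call <- cl
  if (!is.null(drivers) && !is.null(gene_map))
    fit$annotations <- annotate_drivers(fit$optimal, gene_map, drivers)
  fit
}

#' @export
print.pti_fit <- function(x, ...) {
  cat("PTI phylogeny:", x$n_samples, "samples,", x$n_mutations, "mutations",
      sprintf("(trunk %d, unassigned %d, dropped %d)\n",
              x$trunk_length, length(x$unassigned), x$dropped_rows))
  cat(length(x$trees), "candidate tree(s); optimal weight W =", x$weights[1L],
      if (x$multiple_solutions) "[multiple equally weighted solutions]" else "",
      "\n")
  print(x$optimal)
  invisible(x)
}

#' @export
summary.pti_fit <- function(object, ...) {
  structure(list(fit = object, branches = branch_table(object$optimal)),
            class = "summary.pti_fit")
}

#' @export
print.summary.pti_fit <- function(x, ...) {
  print(x$fit)
  cat("\nBranches of the optimal tree:\n")
  print(x$branches, row.names = FALSE)
  if (!is.null(x$fit$annotations) && nrow(x$fit$annotations)) {
    cat("\nDriver annotations:\n")
    print(x$fit$annotations, row.names = FALSE)
  }
  invisible(x)
}

#' Plot the optimal inferred tree
#'
#' Renders the optimal tree via [ape::plot.phylo()] with branch lengths
#' (mutation counts) written on the edges and the root trunk drawn.
#'
#' @param x A `pti_fit`.
#' @param show_lengths Annotate edges with mutation counts.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.pti_fit <- function(x, show_lengths = TRUE, ...) {
  ph <- as.phylo.pti_tree(x$optimal)
  ape::plot.phylo(ph, root.edge = TRUE, ...)
  if (show_lengths && !is.null(ph$edge.length))
    ape::edgelabels(ph$edge.length, frame = "none", adj = c(0.5, -0.3))
  invisible(x)
}
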