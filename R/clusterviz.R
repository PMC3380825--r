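#' All-versus-all comparison matrix for one measure
#'
#' Builds the symmetric dataset-by-dataset matrix of one comparison
#' measure; every off-diagonal cell comes from [compare_networks()] on
#' that pair restricted to its common tested pairs, and the diagonal
#' holds the measure's self-comparison value (correlation 1, overlap 1,
#' unique 0, disagree 0). Cells that are undefined for a pair (e.g. no
#' common interactions) stay `NA`; they are never zero-filled.
#'
#' @param networks named list (or list with dataset ids) of >= 2
#'   `gi_network`s.
#' @param measure one of `"correlation"`, `"overlap"`, `"unique"`,
#'   `"disagree"`.
#' @param sign sign filter for overlap/unique (`"any"`, `"negative"`,
#'   `"positive"`).
#' @return a `measure_matrix`: list with `values` (n x n matrix with
#'   dataset-id dimnames) and `measure`.
#' @export
all_vs_all <- function(networks, measure = c("correlation", "overlap",
                                             "unique", "disagree"),
                       sign = "any") {
  measure <- match.arg(measure)
  stopifnot(length(networks) >= 2)
  ids <- vapply(networks, function(x) x$dataset_id, "")
  n <- length(networks)
  diag_value <- c(correlation = 1, overlap = 1, unique = 0, disagree = 0)
  values <- matrix(diag_value[[measure]], n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cmp <- compare_networks(networks[[i]], networks[[j]])
      row <- cmp[cmp$sign_filter ==
                   (if (measure %in% c("overlap", "unique")) sign
                    else "any"), ]
      values[i, j] <- values[j, i] <- row[[measure]]
    }
  }
  structure(list(values = values, measure = measure, sign = sign),
            class = "measure_matrix")
}

#' Dataset similarity from mean gene-profile correlation
#'
#' The similarity of two datasets is the mean, over all shared genes with
#' a defined value, of each gene's profile correlation between the two
#' datasets ([gene_profile_correlation()]).
#'
#' @param netA,netB `gi_network`s.
#' @param min_partners passed to [gene_profile_correlation()].
#' @return mean Spearman rho, or `NA` when no gene has a defined value.
#' @export
profile_similarity <- function(netA, netB, min_partners = 3) {
  shared <- intersect(netA$genes, netB$genes)
  if (length(shared) == 0) return(NA_real_)
  vals <- vapply(shared, function(g)
    gene_profile_correlation(netA, netB, g, min_partners), 0)
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' All-versus-all mean gene-profile-correlation matrix
#'
#' @inheritParams all_vs_all
#' @param min_partners passed to [profile_similarity()].
#' @return a `measure_matrix` with measure `"profile_similarity"`.
#' @export
profile_similarity_matrix <- function(networks, min_partners = 3) {
  stopifnot(length(networks) >= 2)
  ids <- vapply(networks, function(x) x$dataset_id, "")
  n <- length(networks)
  values <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      values[i, j] <- values[j, i] <-
        profile_similarity(networks[[i]], networks[[j]], min_partners)
    }
  }
  structure(list(values = values, measure = "profile_similarity",
                 sign = "any"),
            class = "measure_matrix")
}

# Measures where larger = more similar; they are converted to distances
# as d = max(value) - value. Unique/disagree are dissimilarities already.
similarity_measures <- c("correlation", "overlap", "profile_similarity")

#' Hierarchically cluster datasets from a comparison matrix
#'
#' Similarity measures (correlation, overlap, profile similarity) are
#' transformed to distances as `d = max(values) - values`; dissimilarity
#' measures (unique, disagree) are used as-is. Rows are ordered by
#' dataset id before clustering so ties break deterministically. Linkages
#' are Ward ("ward.D2"), complete, average (UPGMA) and median (WPGMC);
#' merge-height inversions, possible for median linkage only, are flagged
#' with a warning.
#'
#' @param matrix a `measure_matrix` with no undefined cells (impute or
#'   drop first; `NA` cells are an error).
#' @param linkage one of `"ward"`, `"complete"`, `"average"`, `"median"`.
#' @return a `gi_dendrogram`: list wrapping the `hclust` object
#'   (`$hclust`), `labels`, `linkage`, `measure`.
#' @export
hcluster <- function(matrix, linkage = c("average", "ward", "complete",
                                         "median")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(matrix, "measure_matrix"))
  v <- matrix$values
  if (anyNA(v))
    stop("measure matrix contains undefined cells; impute or drop ",
         "datasets before clustering")
  if (max(abs(v - t(v))) > 1e-12) stop("measure matrix must be symmetric")
  ord <- order(rownames(v), method = "radix")
  v <- v[ord, ord]
  d <- if (matrix$measure %in% similarity_measures) max(v) - v else v
  diag(d) <- 0
  method <- c(ward = "ward.D2", complete = "complete",
              average = "average", median = "median")[[linkage]]
  hc <- stats::hclust(stats::as.dist(d), method = method)
  if (is.unsorted(hc$height)) {
    if (linkage == "median") {
      warning("median (WPGMC) linkage produced merge-height inversions")
    } else {
      stop("unexpected merge-height inversion for ", linkage, " linkage")
    }
  }
  structure(list(hclust = hc, labels = hc$labels, linkage = linkage,
                 measure = matrix$measure),
            class = "gi_dendrogram")
}

#' @export
print.gi_dendrogram <- function(x, ...) {
  cat(sprintf("gi_dendrogram (%s linkage, %s measure): %d leaves\n",
              x$linkage, x$measure, length(x$labels)))
  invisible(x)
}

#' Newick serialization of a dendrogram
#'
#' Branch lengths are merge-height differences: a child's branch length
#' is its parent's merge height minus the child's own merge height
#' (leaves sit at height 0), so a two-leaf tree merged at height h is
#' `(A:h,B:h);`.
#'
#' @param dend a `gi_dendrogram`.
#' @return a single Newick string.
#' @export
dendrogram_newick <- function(dend) {
  stopifnot(inherits(dend, "gi_dendrogram"))
  hc <- dend$hclust
  node <- function(id, parent_height) {
    if (id < 0) {  # leaf
      sprintf("%s:%.10g", hc$labels[-id], parent_height)
    } else {
      h <- hc$height[id]
      sprintf("(%s,%s):%.10g",
              node(hc$merge[id, 1], h), node(hc$merge[id, 2], h),
              parent_height - h)
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  sprintf("(%s,%s);", node(hc$merge[root, 1], h), node(hc$merge[root, 2], h))
}

#' Leaf order of a dendrogram
#'
#' @param dend a `gi_dendrogram`.
#' @return dataset ids in dendrogram leaf order.
#' @export
dendrogram_leaves <- function(dend) {
  dend$hclust$labels[dend$hclust$order]
}

#' Export a measure matrix and its dendrogram
#'
#' Writes the matrix as a tab-separated table with rows and columns
#' ordered by the dendrogram's leaf order, and the dendrogram in Newick
#' format with merge-height branch lengths.
#'
#' @param matrix a `measure_matrix`.
#' @param dendrogram a `gi_dendrogram` over the same dataset ids.
#' @param matrix_path,tree_path output paths (either may be `NULL` to
#'   skip).
#' @return invisibly, the leaf order used.
#' @export
export_comparison <- function(matrix, dendrogram, matrix_path = NULL,
                              tree_path = NULL) {
  stopifnot(inherits(matrix, "measure_matrix"),
            inherits(dendrogram, "gi_dendrogram"))
  leaves <- dendrogram_leaves(dendrogram)
  stopifnot(setequal(leaves, rownames(matrix$values)))
  if (!is.null(matrix_path)) {
    v <- matrix$values[leaves, leaves]
    lines <- c(paste(c("dataset", leaves), collapse = "\t"),
               vapply(seq_along(leaves), function(i)
                 paste(c(leaves[i], sprintf("%.17g", v[i, ])),
                       collapse = "\t"), ""))
    writeLines(lines, matrix_path)
  }
  if (!is.null(tree_path))
    writeLines(dendrogram_newick(dendrogram), tree_path)
  invisible(leaves)
}

#' Read back an exported measure matrix
#'
#' @param path TSV path written by [export_comparison()].
#' @param measure measure name to attach.
#' @return a `measure_matrix`.
#' @export
read_measure_matrix <- function(path, measure = "correlation") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, row.names = 1)
  v <- as.matrix(tab)
  structure(list(values = v, measure = measure, sign = "any"),
            class = "measure_matrix")
}
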