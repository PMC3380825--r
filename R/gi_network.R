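#' Construct a quantitative genetic interaction network
#'
#' A `gi_network` holds one dataset's tested gene pairs with quantitative
#' interaction scores and ternary sign calls, plus dataset metadata
#' (phenotypic readout, environmental condition, laboratory, group).
#' Networks are undirected: pairs are stored canonically with
#' `gene_a < gene_b` and a pair is identified by its unordered members.
#' A tested pair with call 0 means "tested, no interaction detected" —
#' distinct from an untested pair, which is absent entirely.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`, `score` and
#'   optionally `call` (integer in -1/0/+1; defaults to 0 = no call).
#' @param dataset_id character scalar identifying the dataset.
#' @param readout,condition,laboratory free-text metadata strings.
#' @param group one of `"REFERENCE"`, `"CONTROL"`, `"PHENO"`, `"MMS"`,
#'   `"SYNTHETIC"`.
#' @param genes optional character vector of all assayed genes; defaults to
#'   the genes appearing in `pairs`. Extra genes are allowed (genes tested
#'   but without any retained pair).
#'
#' @return An object of class `gi_network`: a list with elements
#'   `dataset_id`, `metadata`, `genes` (sorted) and `pairs` (canonical,
#'   sorted by pair).
#' @export
gi_network <- function(pairs, dataset_id,
                       readout = NA_character_, condition = NA_character_,
                       laboratory = NA_character_, group = "SYNTHETIC",
                       genes = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("gene_a", "gene_b", "score") %in% names(pairs)))
  group <- match.arg(group, c("REFERENCE", "CONTROL", "PHENO", "MMS",
                              "SYNTHETIC"))
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)
  pairs$score <- as.numeric(pairs$score)
  if (is.null(pairs$call)) pairs$call <- 0L
  pairs$call <- as.integer(pairs$call)
  if (!all(pairs$call %in% c(-1L, 0L, 1L)))
    stop("calls must be -1, 0 or +1")
  if (any(pairs$gene_a == pairs$gene_b))
    stop("self-pairs are not allowed in a gi_network")
  pairs <- canonicalize_pairs(pairs)
  key <- pair_key(pairs$gene_a, pairs$gene_b)
  if (anyDuplicated(key))
    stop("duplicate gene pairs after canonicalization: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = ", "))
  bad <- (pairs$call == -1L & pairs$score >= 0) |
         (pairs$call == 1L & pairs$score <= 0)
  if (any(bad))
    stop("call sign inconsistent with score sign for ",
         sum(bad), " pair(s)")
  ord <- order(pairs$gene_a, pairs$gene_b, method = "radix")
  pairs <- pairs[ord, c("gene_a", "gene_b", "score", "call")]
  rownames(pairs) <- NULL
  pair_genes <- unique(c(pairs$gene_a, pairs$gene_b))
  genes <- if (is.null(genes)) pair_genes else
    unique(c(as.character(genes), pair_genes))
  structure(list(
    dataset_id = as.character(dataset_id),
    metadata = list(phenotype_readout = readout, condition = condition,
                    laboratory = laboratory, group = group),
    genes = sort(genes, method = "radix"),
    pairs = pairs
  ), class = "gi_network")
}

#' @export
print.gi_network <- function(x, ...) {
  cat(sprintf(
    "gi_network '%s' [%s]: %d genes, %d tested pairs (%d neg / %d pos calls)\n",
    x$dataset_id, x$metadata$group, length(x$genes), nrow(x$pairs),
    sum(x$pairs$call == -1L), sum(x$pairs$call == 1L)))
  invisible(x)
}

# Canonical pair keys of the tested pairs.
tested_keys <- function(net) pair_key(net$pairs$gene_a, net$pairs$gene_b)

# Keys of pairs carrying an interaction call matching the sign filter.
interaction_keys <- function(net, sign = c("any", "positive", "negative")) {
  sign <- match.arg(sign)
  keep <- switch(sign,
                 any = net$pairs$call != 0L,
                 positive = net$pairs$call == 1L,
                 negative = net$pairs$call == -1L)
  tested_keys(net)[keep]
}

#' Test two networks for equality of content
#'
#' Compares genes, tested pairs, scores and calls. Metadata and dataset id
#' are compared only when `check_metadata = TRUE`.
#'
#' @param a,b `gi_network` objects.
#' @param tolerance numeric tolerance on scores (0 for exact).
#' @param check_metadata compare `dataset_id` and metadata too?
#' @return logical scalar.
#' @export
gi_network_equal <- function(a, b, tolerance = 0, check_metadata = FALSE) {
  if (!identical(a$genes, b$genes)) return(FALSE)
  if (nrow(a$pairs) != nrow(b$pairs)) return(FALSE)
  if (!identical(a$pairs$gene_a, b$pairs$gene_a) ||
      !identical(a$pairs$gene_b, b$pairs$gene_b)) return(FALSE)
  if (!identical(a$pairs$call, b$pairs$call)) return(FALSE)
  if (tolerance == 0) {
    if (!identical(a$pairs$score, b$pairs$score)) return(FALSE)
  } else if (any(abs(a$pairs$score - b$pairs$score) > tolerance)) {
    return(FALSE)
  }
  if (check_metadata &&
      (!identical(a$dataset_id, b$dataset_id) ||
       !identical(a$metadata, b$metadata))) return(FALSE)
  TRUE
}

#' Binarize interaction calls from quantitative scores
#'
#' Re-derives the ternary call from the score: call is -1 where
#' `score <= neg_threshold`, +1 where `score >= pos_threshold`, 0
#' otherwise. Scores and tested pairs are unchanged. The defaults are the
#' conventional S-score cut-offs for this data family; calls already
#' present in an input file normally take precedence, so apply this only
#' to call-less networks or to re-threshold deliberately.
#'
#' @param net a `gi_network`.
#' @param neg_threshold negative score threshold (must be < 0).
#' @param pos_threshold positive score threshold (must be > 0).
#' @return the network with recomputed calls.
#' @export
binarize <- function(net, neg_threshold = -2.5, pos_threshold = 2.0) {
  stopifnot(inherits(net, "gi_network"))
  if (!(neg_threshold < 0)) stop("neg_threshold must be negative")
  if (!(pos_threshold > 0)) stop("pos_threshold must be positive")
  net$pairs$call <- ifelse(net$pairs$score <= neg_threshold, -1L,
                    ifelse(net$pairs$score >= pos_threshold, 1L, 0L))
  net
}

#' Restrict networks to their commonly tested gene pairs
#'
#' Pairwise and triplet comparisons are only meaningful on the pairs every
#' dataset actually tested; this returns each network cut down to the
#' intersection of all tested-pair sets, keeping its own scores and calls.
#' An empty intersection yields empty networks with a warning, not an
#' error.
#'
#' @param networks list of >= 2 `gi_network` objects.
#' @return list of restricted networks, same order and metadata.
#' @export
restrict_to_common <- function(networks) {
  stopifnot(length(networks) >= 2,
            all(vapply(networks, inherits, TRUE, "gi_network")))
  common <- Reduce(intersect, lapply(networks, tested_keys))
  if (length(common) == 0)
    warning("no gene pairs tested in all networks; returning empty networks")
  lapply(networks, function(net) {
    keep <- tested_keys(net) %in% common
    net$pairs <- net$pairs[keep, , drop = FALSE]
    rownames(net$pairs) <- NULL
    net$genes <- sort(unique(c(net$pairs$gene_a, net$pairs$gene_b)),
                      method = "radix")
    net
  })
}
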