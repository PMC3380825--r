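#' Genetic interaction profile similarity network
#'
#' For every gene pair (g, h), correlates (Spearman) their interaction
#' score profiles over the partners k tested with both g and h (the pair
#' members themselves are excluded from each other's profiles). Edges are
#' kept when rho is strictly greater than `tau` and the shared-partner
#' count is at least `min_shared`. High-similarity pairs are the
#' guilt-by-association substrate: genes with similar interaction
#' profiles tend to share function.
#'
#' @param net a `gi_network`.
#' @param tau correlation threshold; strictly exceeded to keep an edge.
#' @param min_shared minimum shared tested partners (Spearman is undefined
#'   below 3).
#' @param exclude_members drop g and h from each other's profiles before
#'   correlating (standard practice; switchable).
#' @return a `profile_network`: list with `genes` (all genes of `net`),
#'   `edges` (data.frame `gene_a`, `gene_b`, `rho`, `n_shared`), `tau`,
#'   `source_ids`.
#' @export
profile_similarity_network <- function(net, tau = 0.1, min_shared = 3,
                                       exclude_members = TRUE) {
  stopifnot(inherits(net, "gi_network"), nrow(net$pairs) > 0)
  genes <- net$genes
  n <- length(genes)
  # score matrix: genes x genes, NA = untested
  S <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  ia <- match(net$pairs$gene_a, genes)
  ib <- match(net$pairs$gene_b, genes)
  S[cbind(ia, ib)] <- net$pairs$score
  S[cbind(ib, ia)] <- net$pairs$score
  tested <- !is.na(S)

  res_a <- character(0); res_b <- character(0)
  res_r <- numeric(0); res_n <- integer(0)
  for (i in seq_len(n - 1L)) {
    si <- S[, i]
    ti <- tested[, i]
    for (j in (i + 1L):n) {
      shared <- ti & tested[, j]
      shared[c(i, j)] <- FALSE
      x <- si[shared]
      y <- S[shared, j]
      # without member exclusion, the pair's mutual score joins both
      # profiles as one aligned point (g's value at h = h's value at g)
      if (!exclude_members && tested[i, j]) {
        x <- c(x, S[i, j])
        y <- c(y, S[i, j])
      }
      m <- length(x)
      if (m < min_shared) next
      rho <- spearman_rho(x, y)
      if (!is.na(rho) && rho > tau) {
        res_a <- c(res_a, genes[i]); res_b <- c(res_b, genes[j])
        res_r <- c(res_r, rho); res_n <- c(res_n, m)
      }
    }
  }
  structure(list(genes = genes,
                 edges = data.frame(gene_a = res_a, gene_b = res_b,
                                    rho = res_r, n_shared = res_n,
                                    stringsAsFactors = FALSE),
                 tau = tau, source_ids = net$dataset_id),
            class = "profile_network")
}

#' @export
print.profile_network <- function(x, ...) {
  cat(sprintf(
    "profile_network [%s]: %d genes, %d edges (rho > %.3g)\n",
    paste(x$source_ids, collapse = "+"), length(x$genes), nrow(x$edges),
    x$tau))
  invisible(x)
}

#' Combine profile networks by maximum correlation
#'
#' The combined network's gene set is the union of the inputs'; each gene
#' pair present in at least one input keeps its maximum correlation across
#' inputs. Commutative and idempotent; requires equal thresholds.
#'
#' @param networks nonempty list of `profile_network`s with equal `tau`.
#' @return a combined `profile_network` (edge `source` column names the
#'   input attaining the maximum).
#' @export
combine_max <- function(networks) {
  if (!is.list(networks) || length(networks) == 0 ||
      !all(vapply(networks, inherits, TRUE, "profile_network")))
    stop("networks must be a nonempty list of profile_network objects")
  taus <- vapply(networks, function(x) x$tau, 0)
  if (length(unique(taus)) != 1)
    stop("all networks must share the same correlation threshold tau")
  all_edges <- do.call(rbind, lapply(networks, function(x) {
    if (nrow(x$edges) == 0) return(NULL)
    cbind(x$edges[, c("gene_a", "gene_b", "rho", "n_shared")],
          source = paste(x$source_ids, collapse = "+"))
  }))
  genes <- sort(unique(unlist(lapply(networks, function(x) x$genes))),
                method = "radix")
  src <- unlist(lapply(networks, function(x) x$source_ids))
  if (is.null(all_edges)) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        rho = numeric(), n_shared = integer(),
                        source = character(), stringsAsFactors = FALSE)
  } else {
    key <- pair_key(all_edges$gene_a, all_edges$gene_b)
    best <- vapply(split(seq_len(nrow(all_edges)), key),
                   function(ii) ii[which.max(all_edges$rho[ii])], 1L)
    edges <- all_edges[best, , drop = FALSE]
    edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"), ]
    rownames(edges) <- NULL
  }
  structure(list(genes = genes, edges = edges, tau = taus[1],
                 source_ids = src),
            class = "profile_network")
}

#' Write a profile network as an edge list (TSV or SIF)
#'
#' @param pcn a `profile_network`.
#' @param path output path.
#' @param format `"tsv"` (gene_a, gene_b, rho, n_shared, source) or
#'   `"sif"` (gene_a, relation `pc`, gene_b) for network viewers.
#' @return `path`, invisibly.
#' @export
write_profile_network <- function(pcn, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  stopifnot(inherits(pcn, "profile_network"))
  e <- pcn$edges
  if (format == "tsv") {
    src <- if ("source" %in% names(e)) e$source else
      rep(paste(pcn$source_ids, collapse = "+"), nrow(e))
    lines <- c("gene_a\tgene_b\trho\tn_shared\tsource",
               if (nrow(e) > 0)
                 sprintf("%s\t%s\t%.17g\t%d\t%s", e$gene_a, e$gene_b,
                         e$rho, e$n_shared, src))
  } else {
    lines <- if (nrow(e) > 0) sprintf("%s\tpc\t%s", e$gene_a, e$gene_b)
             else character(0)
  }
  writeLines(lines, path)
  invisible(path)
}
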