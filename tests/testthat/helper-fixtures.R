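# Builders and independent oracles shared across test files.

# A gi_network from a compact pair spec: list of c(gene_a, gene_b, score)
# (call derived from sign unless `calls` given).
toy_net <- function(..., id = "toy", calls = NULL, group = "SYNTHETIC") {
  rows <- list(...)
  df <- data.frame(
    gene_a = vapply(rows, function(r) as.character(r[[1]]), ""),
    gene_b = vapply(rows, function(r) as.character(r[[2]]), ""),
    score = vapply(rows, function(r) as.numeric(r[[3]]), 0),
    stringsAsFactors = FALSE)
  df$call <- if (is.null(calls)) as.integer(sign(df$score)) else
    as.integer(calls)
  gi_network(df, dataset_id = id, group = group)
}

# Two random synthetic observations of one small truth, sharing tested
# pairs (coverage 1).
random_net_pair <- function(seed, n_genes = 30, n_modules = 3) {
  tm <- truth_model(n_genes = n_genes, n_modules = n_modules)
  tr <- generate_truth(tm, seed)
  om <- observation_model()
  list(a = observe(tr, om, "a", seed = seed * 2 + 1),
       b = observe(tr, om, "b", seed = seed * 2 + 2),
       truth = tr)
}

# --- Independent oracles ---------------------------------------------------

# Spearman via the generic library route (rank handling inside cor()).
spearman_oracle <- function(x, y) stats::cor(x, y, method = "spearman")

# Naive set-operation versions of the binary comparison measures.
interactions_oracle <- function(net, sign = "any") {
  p <- net$pairs
  keep <- switch(sign, any = p$call != 0, positive = p$call == 1,
                 negative = p$call == -1)
  paste(p$gene_a, p$gene_b, sep = "\t")[keep]
}
overlap_oracle <- function(a, b, sign = "any") {
  ia <- interactions_oracle(a, sign); ib <- interactions_oracle(b, sign)
  u <- union(ia, ib)
  if (length(u) == 0) NA_real_ else length(intersect(ia, ib)) / length(u)
}
unique_oracle <- function(a, b, sign = "any") {
  ia <- interactions_oracle(a, sign); ib <- interactions_oracle(b, sign)
  u <- union(ia, ib)
  if (length(u) == 0) NA_real_ else
    (length(setdiff(ia, ib)) + length(setdiff(ib, ia))) / length(u)
}
disagree_oracle <- function(a, b) {
  ia <- interactions_oracle(a, "any"); ib <- interactions_oracle(b, "any")
  both <- intersect(ia, ib)
  if (length(both) == 0) return(NA_real_)
  ca <- setNames(a$pairs$call, paste(a$pairs$gene_a, a$pairs$gene_b,
                                     sep = "\t"))
  cb <- setNames(b$pairs$call, paste(b$pairs$gene_a, b$pairs$gene_b,
                                     sep = "\t"))
  mean(ca[both] != cb[both])
}

# AUROC by brute-force concordant-pair counting.
auroc_oracle <- function(scores, positives, negatives) {
  sp <- scores[positives]; sn <- scores[negatives]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

# AUPR by explicit step-function integration of the PR curve built from
# the stable descending ranking (ties broken by gene id).
aupr_oracle <- function(scores, positives, negatives) {
  ids <- c(positives, negatives)
  is_pos <- c(rep(TRUE, length(positives)), rep(FALSE, length(negatives)))
  ord <- order(-scores[ids], ids, method = "radix")
  lab <- is_pos[ord]
  tp <- cumsum(lab)
  recall <- tp / length(positives)
  precision <- tp / seq_along(lab)
  area <- 0
  prev_r <- 0
  for (i in seq_along(lab)) {
    if (recall[i] > prev_r) {
      area <- area + (recall[i] - prev_r) * precision[i]
      prev_r <- recall[i]
    }
  }
  area
}

# Naive O(n^3) agglomerative clustering via Lance-Williams updates on a
# full distance matrix. Returns sorted merge heights and the leaf
# partition after each merge (as sorted set signatures).
naive_agglomerate <- function(d, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  clusters <- as.list(rownames(d))
  dm <- d
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    n <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (dm[i, j] < best[1]) best <- c(dm[i, j], i, j)
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    newd <- vapply(seq_len(n), function(k) {
      if (k == i || k == j) return(NA_real_)
      if (linkage == "average")
        (ni * dm[i, k] + nj * dm[j, k]) / (ni + nj)
      else max(dm[i, k], dm[j, k])
    }, 0)
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    clusters[[i]] <- merged
    dm[i, ] <- newd; dm[, i] <- newd
    clusters <- clusters[-j]
    dm <- dm[-j, -j, drop = FALSE]
    partitions[[length(partitions) + 1]] <-
      sort(vapply(clusters, paste, "", collapse = "+"))
  }
  list(heights = heights, partitions = partitions)
}

# Dense direct solve of the Gaussian-field system (I + L) f = y.
propagate_oracle <- function(pcn, positives, negatives) {
  genes <- pcn$genes
  n <- length(genes)
  W <- matrix(0, n, n, dimnames = list(genes, genes))
  e <- pcn$edges
  if (nrow(e) > 0) {
    for (r in seq_len(nrow(e))) {
      w <- max(e$rho[r], 0)
      W[e$gene_a[r], e$gene_b[r]] <- w
      W[e$gene_b[r], e$gene_a[r]] <- w
    }
  }
  d <- rowSums(W)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Wn <- diag(dinv) %*% W %*% diag(dinv)
  L <- diag(as.numeric(d > 0)) - Wn
  k <- (length(positives) - length(negatives)) /
    max(1, length(positives) + length(negatives))
  y <- rep(k, n); names(y) <- genes
  y[positives] <- 1; y[negatives] <- -1
  f <- solve(diag(n) + L, y)
  setNames(as.numeric(f), genes)
}

# Random profile network over n genes with edge density `dens`.
random_pcn <- function(seed, n = 20, dens = 0.2, id = "rnd") {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n))
  pairs <- t(combn(genes, 2))
  keep <- which(runif(nrow(pairs)) < dens)
  structure(list(
    genes = genes,
    edges = data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                       rho = runif(length(keep), 0.1, 1),
                       n_shared = rep(5L, length(keep)),
                       stringsAsFactors = FALSE),
    tau = 0.1, source_ids = id), class = "profile_network")
}
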