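#' Gene annotation sets
#'
#' A minimal container for GO-style annotations: a named list mapping term
#' ids to character vectors of annotated genes, with each term's ontology
#' aspect (P/F/C).
#'
#' @param term_genes named list of nonempty character vectors.
#' @param aspect named character vector of aspects per term (defaults to
#'   "P").
#' @return an `annotation_set`.
#' @export
annotation_set <- function(term_genes, aspect = NULL) {
  stopifnot(is.list(term_genes))
  if (length(term_genes) > 0) {
    stopifnot(!is.null(names(term_genes)),
              all(lengths(term_genes) > 0))
    term_genes <- lapply(term_genes, function(g) sort(unique(g)))
  }
  if (is.null(aspect))
    aspect <- stats::setNames(rep("P", length(term_genes)),
                              names(term_genes))
  structure(list(terms = term_genes, aspect = aspect),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d terms, %d genes\n", length(x$terms),
              length(unique(unlist(x$terms)))))
  invisible(x)
}

#' Default experimentally supported GO evidence codes
#'
#' Direct-assay/experimental codes; electronically inferred annotations
#' (IEA etc.) are excluded to avoid circularity with network-derived
#' annotations.
#' @return character vector.
#' @export
experimental_evidence_codes <- function() {
  c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")
}

#' Read a GAF 2.x annotation file, filtered by evidence code
#'
#' Retains only rows with an allowed evidence code, drops NOT-qualified
#' annotations, and collapses duplicate gene-term rows. Genes are taken
#' from the DB Object ID column (column 2).
#'
#' @param path GAF file path.
#' @param allowed_codes evidence codes to keep.
#' @return an [annotation_set()].
#' @export
read_gaf <- function(path,
                     allowed_codes = experimental_evidence_codes()) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "!") & nzchar(lines)
  terms <- list()
  aspect <- character(0)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 15)
      stop("malformed GAF line ", i, ": expected >= 15 columns, got ",
           length(f))
    if (grepl("NOT", f[4], fixed = TRUE)) next
    if (!(f[7] %in% allowed_codes)) next
    gene <- f[2]; term <- f[5]
    terms[[term]] <- c(terms[[term]], gene)
    if (!(term %in% names(aspect))) aspect[term] <- f[9]
  }
  annotation_set(terms, aspect = aspect[names(terms)])
}

#' Write an annotation set as GAF 2.1
#'
#' @param ann an [annotation_set()].
#' @param path output path.
#' @param evidence evidence code to stamp on every row.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(ann, path, evidence = "IDA") {
  stopifnot(inherits(ann, "annotation_set"))
  rows <- unlist(lapply(names(ann$terms), function(term) {
    asp <- ann$aspect[[term]] %||% "P"
    sprintf("SYNT\t%s\t%s\t\t%s\tSYNT:REF\t%s\t\t%s\t\t\tgene\ttaxon:0\t20120101\tSYNT\t\t",
            ann$terms[[term]], ann$terms[[term]], term, evidence, asp)
  }))
  writeLines(c("!gaf-version: 2.1", rows), path)
  invisible(path)
}

#' Terms evaluable on a given network
#'
#' Five-fold cross-validation needs at least `min_genes` annotated genes
#' present in the network.
#'
#' @param ann an [annotation_set()].
#' @param network_genes character vector of network genes.
#' @param min_genes minimum annotated genes in the network (default 5).
#' @return character vector of eligible term ids.
#' @export
eligible_terms <- function(ann, network_genes, min_genes = 5) {
  stopifnot(inherits(ann, "annotation_set"))
  n_in <- vapply(ann$terms,
                 function(g) length(intersect(g, network_genes)), 0L)
  names(n_in)[n_in >= min_genes]
}

#' Gaussian-field label propagation over a profile network
#'
#' Scores every gene by solving `(I + L) f = y`, where `L` is the
#' symmetric-normalized graph Laplacian of the nonnegative edge weights,
#' `y` is +1 on positive genes, -1 on negative genes, and the label bias
#' `k = (n+ - n-) / (n+ + n-)` on unlabeled genes. Genes with no edges
#' get exactly their `y` value. This is the standard single-network
#' guilt-by-association scorer.
#'
#' @param pcn a `profile_network`.
#' @param positives,negatives disjoint subsets of `pcn$genes`.
#' @param clamp_negatives label the negatives `-1` (default). When
#'   `FALSE`, negatives still define the bias `k` but receive `y = k`
#'   like other unlabeled genes — the mode cross-validation uses so that
#'   evaluated negatives and held-out positives share the same prior (a
#'   clamped `-1` would rank every labeled negative below every unlabeled
#'   gene regardless of the graph).
#' @return named numeric vector of scores over all `pcn` genes.
#' @export
propagate_labels <- function(pcn, positives, negatives,
                             clamp_negatives = TRUE) {
  stopifnot(inherits(pcn, "profile_network"))
  genes <- pcn$genes
  if (!all(positives %in% genes) || !all(negatives %in% genes))
    stop("positives and negatives must be subsets of the network's genes")
  if (length(intersect(positives, negatives)) > 0)
    stop("positives and negatives must be disjoint")
  n <- length(genes)
  y <- rep((length(positives) - length(negatives)) /
             max(1L, length(positives) + length(negatives)), n)
  names(y) <- genes
  y[positives] <- 1
  if (clamp_negatives) y[negatives] <- -1
  e <- pcn$edges
  if (nrow(e) == 0) return(y)
  i <- match(e$gene_a, genes); j <- match(e$gene_b, genes)
  w <- pmax(e$rho, 0)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n))
  d <- Matrix::rowSums(W)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Wn <- Matrix::Diagonal(x = dinv) %*% W %*% Matrix::Diagonal(x = dinv)
  L <- Matrix::Diagonal(n, x = as.numeric(d > 0)) - Wn
  A <- Matrix::Diagonal(n) + L
  f <- as.numeric(Matrix::solve(A, y))
  names(f) <- genes
  f
}

#' Rank-based AUROC (Mann-Whitney, ties count one half)
#'
#' @param scores named numeric vector.
#' @param positives,negatives gene id vectors (must index into `scores`).
#' @return AUROC in \[0, 1\], or `NA` if either class is empty.
#' @export
auroc <- function(scores, positives, negatives) {
  np <- length(positives); nn <- length(negatives)
  if (np == 0 || nn == 0) return(NA_real_)
  v <- c(scores[positives], scores[negatives])
  r <- rank(v)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision: the mean over positives of the precision at each
#' positive's rank, with scores sorted descending and ties broken by
#' stable gene-id order.
#'
#' @inheritParams auroc
#' @return AUPR in (0, 1\], or `NA` if the positive class is empty.
#' @export
aupr <- function(scores, positives, negatives) {
  np <- length(positives)
  if (np == 0 || length(negatives) == 0) return(NA_real_)
  ids <- c(positives, negatives)
  is_pos <- c(rep(TRUE, np), rep(FALSE, length(negatives)))
  ord <- order(-scores[ids], ids, method = "radix")
  pos_at_rank <- is_pos[ord]
  cum_tp <- cumsum(pos_at_rank)
  prec <- cum_tp / seq_along(pos_at_rank)
  sum(prec[pos_at_rank]) / np
}

#' Cross-validated function prediction for one term
#'
#' Positives are the term's genes present in the network; negatives are
#' all other network genes not annotated to the term. Positives are
#' shuffled (seeded) and dealt round-robin into `k` folds; per fold the
#' held-out positives are unlabeled, labels are propagated with the
#' training positives clamped to +1 and the negatives left at the bias
#' (see [propagate_labels()], `clamp_negatives = FALSE` — this keeps the
#' evaluation at chance level on structureless graphs), and AUROC / AUPR
#' are computed on the held-out positives against all negatives.
#'
#' @param pcn a `profile_network`.
#' @param term term id.
#' @param ann an [annotation_set()].
#' @param k number of folds (reduced with a warning if positives are
#'   fewer).
#' @param seed fold-assignment seed.
#' @return a `term_evaluation`: list with `term`, `n_positives`, `auroc`,
#'   `aupr` (fold means) and `folds` (per-fold data.frame).
#' @export
cross_validate <- function(pcn, term, ann, k = 5, seed = 1L) {
  stopifnot(inherits(pcn, "profile_network"),
            inherits(ann, "annotation_set"), term %in% names(ann$terms))
  genes <- pcn$genes
  positives <- intersect(ann$terms[[term]], genes)
  negatives <- setdiff(genes, ann$terms[[term]])
  if (length(positives) < k) {
    warning("term ", term, " has ", length(positives),
            " positives; reducing folds from ", k)
    k <- max(2L, length(positives))
  }
  shuffled <- with_seed(seed, sample(positives))
  fold_of <- rep_len(seq_len(k), length(shuffled))
  rows <- lapply(seq_len(k), function(fold) {
    held <- shuffled[fold_of == fold]
    train <- setdiff(positives, held)
    f <- propagate_labels(pcn, train, negatives,
                          clamp_negatives = FALSE)
    data.frame(fold = fold, n_held = length(held),
               auroc = auroc(f, held, negatives),
               aupr = aupr(f, held, negatives))
  })
  folds <- do.call(rbind, rows)
  structure(list(term = term, n_positives = length(positives),
                 auroc = mean(folds$auroc), aupr = mean(folds$aupr),
                 folds = folds),
            class = "term_evaluation")
}

#' Relative improvement of a combined network over its parents
#'
#' `(score_C - mean(score_A, score_B)) / mean(score_A, score_B)`: the
#' fractional gain of the combined network C over the mean of the two
#' individual networks A and B it was built from.
#'
#' @param score_C,score_A,score_B per-term performance scores (AUROC or
#'   AUPR).
#' @return relative improvement, or `NA` when the parent mean is not
#'   positive.
#' @export
relative_improvement <- function(score_C, score_A, score_B) {
  m <- (score_A + score_B) / 2
  ifelse(is.na(m) | m <= 0, NA_real_, (score_C - m) / m)
}

#' Term-level comparison of two evaluation sets
#'
#' Global paired Wilcoxon signed-rank across terms on the mean scores,
#' plus per-term p-values (paired t-test across cross-validation folds
#' when per-fold scores are supplied) adjusted by Benjamini-Hochberg.
#'
#' @param evals_combined,evals_reference either named numeric vectors of
#'   per-term scores, or named lists of per-fold numeric vectors; the two
#'   inputs must cover the same terms.
#' @param alpha BH significance level.
#' @return list with `global_p`, `table` (term, delta, p, p_adj,
#'   direction) and `significant_terms`.
#' @export
term_difference_tests <- function(evals_combined, evals_reference,
                                  alpha = 0.05) {
  terms <- names(evals_combined)
  if (is.null(terms) || !setequal(terms, names(evals_reference)))
    stop("the two evaluation sets must cover the same terms")
  as_folds <- function(x) if (is.list(x)) x else as.list(x)
  fc <- as_folds(evals_combined)[terms]
  fr <- as_folds(evals_reference)[terms]
  mc <- vapply(fc, function(v) mean(unlist(v)), 0)
  mr <- vapply(fr, function(v) mean(unlist(v)), 0)
  delta <- mc - mr
  p <- mapply(function(a, b) {
    a <- unlist(a); b <- unlist(b)
    if (length(a) != length(b) || length(a) < 2 ||
        stats::sd(a - b) == 0) {
      if (length(a) == length(b) && all(a - b == 0)) 1 else NA_real_
    } else {
      stats::t.test(a, b, paired = TRUE)$p.value
    }
  }, fc, fr)
  p_adj <- stats::p.adjust(p, method = "BH")
  global_p <- if (all(delta == 0)) 1 else
    suppressWarnings(stats::wilcox.test(mc, mr, paired = TRUE)$p.value)
  tab <- data.frame(term = terms, delta = delta, p = p, p_adj = p_adj,
                    direction = ifelse(delta > 0, "combined",
                                ifelse(delta < 0, "reference", "tie")),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(global_p = global_p, table = tab,
       significant_terms = tab$term[!is.na(tab$p_adj) &
                                      tab$p_adj < alpha])
}
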