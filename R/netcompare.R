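#' Spearman rank correlation with explicit undefined handling
#'
#' Pearson correlation of average-ranked values (ties get average ranks).
#' Undefined cases — fewer than 3 observations, or zero variance after
#' ranking — return `NA` rather than a silent 0.
#'
#' @param x,y numeric vectors of equal length.
#' @return Spearman's rho, or `NA_real_` when undefined.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

check_same_tested <- function(netA, netB) {
  ka <- tested_keys(netA); kb <- tested_keys(netB)
  if (length(ka) != length(kb) || !setequal(ka, kb))
    stop("networks do not share the same tested pairs; ",
         "apply restrict_to_common() first")
  invisible(TRUE)
}

#' Jaccard overlap of binarized interaction sets
#'
#' `|I_A intersect I_B| / |I_A union I_B|`, where `I_X` is the set of
#' commonly tested pairs with a nonzero call (of the filtered sign) in
#' network X. Undefined (`NA`) when the union is empty.
#'
#' @param netA,netB `gi_network`s sharing the same tested pairs.
#' @param sign `"any"`, `"positive"` or `"negative"` — interactions of
#'   each sign class are analyzed separately because they have different
#'   properties and error rates.
#' @return fraction in \[0, 1\], or `NA`.
#' @export
overlap_jaccard <- function(netA, netB, sign = "any") {
  check_same_tested(netA, netB)
  ia <- interaction_keys(netA, sign); ib <- interaction_keys(netB, sign)
  u <- length(union(ia, ib))
  if (u == 0) return(NA_real_)
  length(intersect(ia, ib)) / u
}

#' Fraction of interactions unique to one network
#'
#' The complement of the Jaccard overlap: the fraction of all observed
#' interactions seen in only one of the two networks.
#'
#' @inheritParams overlap_jaccard
#' @return fraction in \[0, 1\], or `NA`.
#' @export
unique_fraction <- function(netA, netB, sign = "any") {
  ov <- overlap_jaccard(netA, netB, sign)
  if (is.na(ov)) NA_real_ else 1 - ov
}

#' Fraction of co-observed interactions that disagree on sign
#'
#' Among pairs called as interactions (either sign) in both networks, the
#' fraction whose calls differ in sign. Undefined (`NA`) when no
#' interactions are co-observed.
#'
#' @inheritParams overlap_jaccard
#' @return fraction in \[0, 1\], or `NA`.
#' @export
disagree_fraction <- function(netA, netB) {
  check_same_tested(netA, netB)
  both <- intersect(interaction_keys(netA, "any"),
                    interaction_keys(netB, "any"))
  if (length(both) == 0) return(NA_real_)
  ca <- net_calls(netA)[both]
  cb <- net_calls(netB)[both]
  mean(ca != cb)
}

net_calls <- function(net) {
  stats::setNames(net$pairs$call, tested_keys(net))
}
net_scores <- function(net) {
  stats::setNames(net$pairs$score, tested_keys(net))
}

#' Correlation of one gene's interaction profiles across two datasets
#'
#' Spearman correlation of the gene's interaction score vectors in the two
#' datasets, limited to interaction partners tested with that gene in both.
#' Undefined (`NA`) below `min_partners` shared partners.
#'
#' @param netA,netB `gi_network`s.
#' @param gene gene identifier, present in both networks.
#' @param min_partners minimum shared partners for a defined value.
#' @return Spearman's rho or `NA`.
#' @export
gene_profile_correlation <- function(netA, netB, gene, min_partners = 3) {
  if (!(gene %in% netA$genes) || !(gene %in% netB$genes))
    stop("gene '", gene, "' absent from one of the networks")
  pa <- gene_profile(netA, gene)
  pb <- gene_profile(netB, gene)
  shared <- intersect(names(pa), names(pb))
  if (length(shared) < min_partners) return(NA_real_)
  spearman_rho(pa[shared], pb[shared])
}

# Named score vector of a gene's tested partners.
gene_profile <- function(net, gene) {
  ia <- net$pairs$gene_a == gene
  ib <- net$pairs$gene_b == gene
  partners <- c(net$pairs$gene_b[ia], net$pairs$gene_a[ib])
  stats::setNames(c(net$pairs$score[ia], net$pairs$score[ib]), partners)
}

#' Compare two networks with the four standard measures
#'
#' Restricts both networks to their commonly tested pairs, then computes:
#' Spearman correlation of the quantitative scores, Jaccard overlap and
#' unique fraction of the binarized interactions (overall and per sign
#' class), and the sign-disagreement fraction among co-observed
#' interactions. Undefined measures are reported as `NA`, never as 0.
#'
#' @param netA,netB `gi_network`s (restricted internally).
#' @param correlation_on `"all"` (default: all commonly tested pairs,
#'   including pairs without a call) or `"interactions"` (pairs called in
#'   at least one network) — a sensitivity switch.
#' @return data.frame with one row per sign filter (`any`, `negative`,
#'   `positive`) and columns `dataset_a`, `dataset_b`, `sign_filter`,
#'   `correlation`, `overlap`, `unique`, `disagree`, `n_common_tested`,
#'   `n_obs_a`, `n_obs_b`, `n_both`, `n_only_a`, `n_only_b`. Correlation
#'   and disagree are computed sign-blind and reported on the `any` row.
#' @export
compare_networks <- function(netA, netB, correlation_on = c("all",
                                                            "interactions")) {
  correlation_on <- match.arg(correlation_on)
  rs <- restrict_to_common(list(netA, netB))
  a <- rs[[1]]; b <- rs[[2]]
  n_common <- nrow(a$pairs)

  if (n_common > 0) {
    sa <- net_scores(a); sb <- net_scores(b)[names(net_scores(a))]
    if (correlation_on == "interactions") {
      keep <- names(sa) %in% union(interaction_keys(a, "any"),
                                   interaction_keys(b, "any"))
      sa <- sa[keep]; sb <- sb[keep]
    }
    corr <- if (length(sa) >= 3) spearman_rho(sa, sb) else NA_real_
    dis <- disagree_fraction(a, b)
  } else {
    corr <- NA_real_
    dis <- NA_real_
  }

  one_sign <- function(sign) {
    if (n_common == 0) {
      return(data.frame(sign_filter = sign, correlation = NA_real_,
                        overlap = NA_real_, unique = NA_real_,
                        disagree = NA_real_, n_common_tested = 0L,
                        n_obs_a = 0L, n_obs_b = 0L, n_both = 0L,
                        n_only_a = 0L, n_only_b = 0L))
    }
    ia <- interaction_keys(a, sign); ib <- interaction_keys(b, sign)
    n_both <- length(intersect(ia, ib))
    data.frame(sign_filter = sign,
               correlation = if (sign == "any") corr else NA_real_,
               overlap = overlap_jaccard(a, b, sign),
               unique = unique_fraction(a, b, sign),
               disagree = if (sign == "any") dis else NA_real_,
               n_common_tested = n_common,
               n_obs_a = length(ia), n_obs_b = length(ib),
               n_both = n_both,
               n_only_a = length(ia) - n_both,
               n_only_b = length(ib) - n_both)
  }
  out <- do.call(rbind, lapply(c("any", "negative", "positive"), one_sign))
  out <- cbind(data.frame(dataset_a = netA$dataset_id,
                          dataset_b = netB$dataset_id), out)
  rownames(out) <- NULL
  out
}

#' Compare a measure between two groups of networks
#'
#' Two-sided Student's t-test (equal variance; paired on differences when
#' `paired = TRUE`) or Wilcoxon (rank-sum / signed-rank) between two
#' vectors of per-network comparison measures, e.g. PHENO/MMS-group values
#' versus CONTROL-group values.
#'
#' @param values_group1,values_group2 numeric vectors (NA dropped; for the
#'   paired test, pairs with an NA member are dropped).
#' @param paired paired test?
#' @param method `"t"` or `"wilcoxon"`.
#' @return list with `statistic`, `p_value`, `method`, `paired`.
#' @export
group_difference_test <- function(values_group1, values_group2,
                                  paired = FALSE,
                                  method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  x <- as.numeric(values_group1); y <- as.numeric(values_group2)
  if (paired) {
    stopifnot(length(x) == length(y))
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
  } else {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
  }
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be nonempty")
  degenerate <- if (paired) all(x - y == 0) else
    (stats::sd(x) == 0 && stats::sd(y) == 0)
  if (degenerate) {
    equal <- if (paired) TRUE else isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (equal) 0 else NA_real_,
                p_value = if (equal) 1 else NA_real_,
                method = method, paired = paired))
  }
  res <- if (method == "t") {
    stats::t.test(x, y, paired = paired, var.equal = TRUE)
  } else {
    suppressWarnings(stats::wilcox.test(x, y, paired = paired))
  }
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = method, paired = paired)
}
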