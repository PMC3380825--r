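gaf_line <- function(gene, term, code, qualifier = "", aspect = "P") {
  paste("DB", gene, gene, qualifier, term, "REF:1", code, "", aspect,
        "", "", "gene", "taxon:0", "20120101", "DB", "", "", sep = "\t")
}

test_that("read_gaf keeps experimental codes and drops the rest", {
  path <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               gaf_line("g1", "GO:1", "IDA"),
               gaf_line("g2", "GO:1", "IEA"),
               gaf_line("g3", "GO:1", "IMP"),
               gaf_line("g4", "GO:2", "ISS"),
               gaf_line("g5", "GO:2", "EXP"),
               gaf_line("g6", "GO:2", "IDA", qualifier = "NOT"),
               gaf_line("g1", "GO:1", "IDA")), path)  # duplicate row
  ann <- read_gaf(path)
  expect_equal(sort(names(ann$terms)), c("GO:1", "GO:2"))
  expect_equal(ann$terms[["GO:1"]], c("g1", "g3"))
  expect_equal(ann$terms[["GO:2"]], "g5")

  # empty file
  writeLines("!gaf-version: 2.1", path)
  expect_length(read_gaf(path)$terms, 0)

  # malformed line reported with its number
  writeLines(c("!gaf-version: 2.1", "too\tfew\tcolumns"), path)
  expect_error(read_gaf(path), "line 2")
})

test_that("eligible_terms enforces the minimum-genes-in-network rule", {
  ann <- annotation_set(list(t5 = paste0("g", 1:5),
                             t6 = paste0("g", 1:6),
                             t2 = c("g1", "g2")))
  net_genes <- paste0("g", 1:5)  # g6 missing
  expect_equal(eligible_terms(ann, net_genes), c("t5", "t6"))
  expect_equal(eligible_terms(ann, paste0("g", 1:4)), character(0))
  expect_setequal(eligible_terms(ann, net_genes, min_genes = 1),
                  c("t5", "t6", "t2"))
})

test_that("label propagation orders a path and handles isolated genes", {
  pcn <- structure(list(
    genes = c("a", "b", "c", "iso"),
    edges = data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                       rho = c(1, 1), n_shared = 5L),
    tau = 0.1, source_ids = "p"), class = "profile_network")
  f <- propagate_labels(pcn, positives = "a", negatives = "c")
  expect_true(f[["a"]] > f[["b"]])
  expect_true(f[["b"]] > f[["c"]])
  expect_equal(f[["iso"]], 0)  # bias k = (1 - 1)/2 = 0

  f2 <- propagate_labels(pcn, positives = c("a", "b"), negatives = "c")
  expect_equal(f2[["iso"]], 1 / 3)  # k = (2 - 1)/3

  expect_error(propagate_labels(pcn, "a", "a"), "disjoint")
  expect_error(propagate_labels(pcn, "zz", "a"), "subsets")
})

test_that("propagation matches the dense direct-solve oracle", {
  for (seed in 1:3) {
    pcn <- random_pcn(seed, n = 30, dens = 0.15)
    set.seed(seed + 100)
    pos <- sample(pcn$genes, 4)
    neg <- sample(setdiff(pcn$genes, pos), 10)
    f <- propagate_labels(pcn, pos, neg)
    expect_equal(f, propagate_oracle(pcn, pos, neg), tolerance = 1e-6)
  }
})

test_that("auroc and aupr match their definitions", {
  s <- setNames(c(4, 3, 2, 1), c("p1", "p2", "n1", "n2"))
  expect_equal(auroc(s, c("p1", "p2"), c("n1", "n2")), 1.0)
  expect_equal(aupr(s, c("p1", "p2"), c("n1", "n2")), 1.0)

  tied <- setNames(rep(1, 6), paste0("g", 1:6))
  expect_equal(auroc(tied, paste0("g", 1:3), paste0("g", 4:6)), 0.5)

  # 1 positive ranked 2nd of 3: AP = precision at its rank = 1/2
  s3 <- setNames(c(3, 2, 1), c("n1", "p1", "n2"))
  expect_equal(aupr(s3, "p1", c("n1", "n2")), 0.5)

  # random instances vs oracles
  for (seed in 1:20) {
    set.seed(seed)
    genes <- paste0("g", 1:30)
    sc <- setNames(sample(1:10, 30, replace = TRUE), genes)  # many ties
    pos <- sample(genes, 6)
    neg <- setdiff(genes, pos)
    expect_equal(auroc(sc, pos, neg), auroc_oracle(sc, pos, neg))
    expect_equal(aupr(sc, pos, neg), aupr_oracle(sc, pos, neg))
  }
  expect_true(is.na(auroc(s, character(0), "n1")))
  expect_true(is.na(aupr(s, character(0), "n1")))
})

test_that("auroc is invariant under monotone score transforms", {
  set.seed(5)
  genes <- paste0("g", 1:40)
  sc <- setNames(rnorm(40), genes)
  pos <- sample(genes, 8); neg <- setdiff(genes, pos)
  expect_equal(auroc(exp(sc), pos, neg), auroc(sc, pos, neg))
})

test_that("cross_validate is deterministic and separates a clique term", {
  # a term whose genes form a high-weight clique, disconnected from the rest
  genes <- c(paste0("m", 1:6), paste0("x", 1:14))
  clique <- t(combn(paste0("m", 1:6), 2))
  pcn <- structure(list(
    genes = genes,
    edges = data.frame(gene_a = clique[, 1], gene_b = clique[, 2],
                       rho = 0.9, n_shared = 5L),
    tau = 0.1, source_ids = "p"), class = "profile_network")
  ann <- annotation_set(list(`MOD:1` = paste0("m", 1:6)))
  ev <- cross_validate(pcn, "MOD:1", ann, k = 5, seed = 3)
  expect_gt(ev$auroc, 0.95)
  ev2 <- cross_validate(pcn, "MOD:1", ann, k = 5, seed = 3)
  expect_equal(ev, ev2)
  expect_equal(nrow(ev$folds), 5)

  # fewer positives than folds -> folds reduced with a warning
  ann2 <- annotation_set(list(`MOD:2` = paste0("m", 1:3)))
  expect_warning(ev3 <- cross_validate(pcn, "MOD:2", ann2, k = 5, seed = 1),
                 "reducing folds")
  expect_equal(nrow(ev3$folds), 3)
})

test_that("random networks predict random terms at chance level", {
  aurocs <- vapply(1:20, function(seed) {
    pcn <- random_pcn(seed, n = 40, dens = 0.15)
    set.seed(seed + 500)
    ann <- annotation_set(list(rnd = sample(pcn$genes, 8)))
    cross_validate(pcn, "rnd", ann, k = 5, seed = seed)$auroc
  }, 0)
  expect_gt(mean(aurocs), 0.35)
  expect_lt(mean(aurocs), 0.65)
})

test_that("relative improvement follows its formula", {
  expect_equal(relative_improvement(0.5, 0.5, 0.5), 0)
  expect_equal(relative_improvement(0.6, 0.5, 0.3), 0.5)
  expect_equal(relative_improvement(0.8, 0.5, 0.3), 1.0)
  expect_true(is.na(relative_improvement(0.5, 0, 0)))
})

test_that("term_difference_tests adjusts and selects correctly", {
  # identical evaluations: global p = 1, nothing significant
  x <- setNames(as.list(rep(list(c(0.5, 0.6, 0.7)), 3)), c("t1", "t2", "t3"))
  res <- term_difference_tests(x, x)
  expect_equal(res$global_p, 1)
  expect_length(res$significant_terms, 0)

  # BH adjustment equals p.adjust on the computed raw p-values
  set.seed(9)
  mk <- function(shift) lapply(setNames(1:4, paste0("t", 1:4)),
                               function(i) rnorm(5, 0.5 + shift * i / 10,
                                                 0.01))
  a <- mk(1); b <- mk(0)
  res2 <- term_difference_tests(a, b)
  expect_equal(res2$table$p_adj, p.adjust(res2$table$p, "BH"))
  expect_true(all(res2$table$direction == "combined"))

  # single term: BH reduces to the raw p-value
  res3 <- term_difference_tests(a["t4"], b["t4"])
  expect_equal(res3$table$p_adj, res3$table$p)

  expect_error(term_difference_tests(a, b[c("t1", "t2")]), "same terms")
})

test_that("propagation is invariant under gene relabeling", {
  pcn <- random_pcn(7, n = 15, dens = 0.3)
  set.seed(7)
  pos <- sample(pcn$genes, 3); neg <- sample(setdiff(pcn$genes, pos), 5)
  f <- propagate_labels(pcn, pos, neg)
  # permute the gene universe and the edge table rows
  perm <- sample(length(pcn$genes))
  relab <- setNames(sprintf("z%03d", seq_along(pcn$genes)), pcn$genes)
  pcn2 <- pcn
  pcn2$genes <- sort(unname(relab))
  pcn2$edges$gene_a <- unname(relab[pcn$edges$gene_a])
  pcn2$edges$gene_b <- unname(relab[pcn$edges$gene_b])
  pcn2$edges <- pcn2$edges[sample(nrow(pcn2$edges)), ]
  f2 <- propagate_labels(pcn2, unname(relab[pos]), unname(relab[neg]))
  expect_equal(unname(f2[relab[names(f)]]), unname(f), tolerance = 1e-10)
})
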