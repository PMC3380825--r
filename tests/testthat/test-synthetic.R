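test_that("generate_truth honors degenerate probabilities", {
  m <- truth_model(n_genes = 5, n_modules = 1, p_within_neg = 1,
                   p_within_pos = 0, p_between_neg = 0, p_between_pos = 0)
  tr <- generate_truth(m, 1)
  expect_equal(nrow(tr$pairs), 10)
  expect_true(all(tr$pairs$call == -1L))
  expect_true(all(tr$pairs$score < 0))

  m0 <- truth_model(n_genes = 10, n_modules = 2, p_within_neg = 0,
                    p_within_pos = 0, p_between_neg = 0, p_between_pos = 0,
                    p_block_neg = 0, p_block_pos = 0)
  expect_equal(nrow(generate_truth(m0, 1)$pairs), 0)

  expect_error(truth_model(p_within_neg = 0.7, p_within_pos = 0.5),
               "exceed 1")
})

test_that("within-module negative rate matches its binomial target", {
  m <- truth_model(n_genes = 200, n_modules = 10, p_within_neg = 0.2)
  tr <- generate_truth(m, 42)
  within <- tr$modules[tr$pairs$gene_a] == tr$modules[tr$pairs$gene_b]
  n_within_pairs <- sum(choose(table(tr$modules), 2))
  frac <- sum(tr$pairs$call == -1L & within) / n_within_pairs
  se <- sqrt(0.2 * 0.8 / n_within_pairs)
  expect_lt(abs(frac - 0.2), 3 * se)
})

test_that("observe is the identity on calls in the error-free limit", {
  tr <- generate_truth(truth_model(n_genes = 30, n_modules = 3), 5)
  om <- observation_model(sensitivity_pos = 1, precision_pos = 1,
                          sensitivity_neg = 1, precision_neg = 1,
                          coverage = 1, noise_sd = 0)
  net <- observe(tr, om, "perfect", seed = 9)
  obs <- setNames(net$pairs$call, paste(net$pairs$gene_a,
                                        net$pairs$gene_b))
  tru <- setNames(tr$pairs$call, paste(tr$pairs$gene_a, tr$pairs$gene_b))
  expect_equal(sum(obs != 0), length(tru))
  expect_equal(obs[names(tru)], tru)
  # and scores are reproduced exactly
  sc <- setNames(net$pairs$score, paste(net$pairs$gene_a,
                                        net$pairs$gene_b))
  expect_equal(unname(sc[names(tru)]),
               unname(setNames(tr$pairs$score,
                               paste(tr$pairs$gene_a, tr$pairs$gene_b))))
})

test_that("detection frequency matches the stated sensitivity", {
  tr <- generate_truth(truth_model(n_genes = 60, n_modules = 6), 2)
  om <- observation_model(noise_sd = 0.5)
  tru_neg <- paste(tr$pairs$gene_a, tr$pairs$gene_b)[tr$pairs$call == -1L]
  detected <- 0; total <- 0
  for (s in 1:50) {
    net <- observe(tr, om, "d", seed = s)
    obs <- setNames(net$pairs$call, paste(net$pairs$gene_a,
                                          net$pairs$gene_b))
    detected <- detected + sum(obs[tru_neg] == -1L)
    total <- total + length(tru_neg)
  }
  se <- sqrt(0.35 * 0.65 / total)
  expect_lt(abs(detected / total - 0.35), 3 * se)
})

test_that("realized precision matches the stated per-sign precision", {
  tr <- generate_truth(truth_model(n_genes = 300, n_modules = 10), 7)
  tru_neg <- paste(tr$pairs$gene_a, tr$pairs$gene_b)[tr$pairs$call == -1L]
  tp <- 0; called <- 0
  for (s in 1:3) {
    net <- observe(tr, observation_model(), "d", seed = 100 + s)
    neg_called <- paste(net$pairs$gene_a,
                        net$pairs$gene_b)[net$pairs$call == -1L]
    tp <- tp + length(intersect(neg_called, tru_neg))
    called <- called + length(neg_called)
  }
  se <- sqrt(0.63 * 0.37 / called)
  expect_lt(abs(tp / called - 0.63), 3 * se)
})

test_that("rewiring conserves per-sign interaction counts", {
  tr <- generate_truth(truth_model(n_genes = 60, n_modules = 6), 3)
  om0 <- observation_model(sensitivity_pos = 1, precision_pos = 1,
                           sensitivity_neg = 1, precision_neg = 1,
                           noise_sd = 0)
  om5 <- observation_model(sensitivity_pos = 1, precision_pos = 1,
                           sensitivity_neg = 1, precision_neg = 1,
                           noise_sd = 0, rewire_fraction = 0.5)
  n0 <- observe(tr, om0, "d0", seed = 4)
  n5 <- observe(tr, om5, "d5", seed = 4)
  expect_equal(sum(n5$pairs$call == -1L), sum(n0$pairs$call == -1L))
  expect_equal(sum(n5$pairs$call == 1L), sum(n0$pairs$call == 1L))
  # but roughly half the negative interactions moved elsewhere
  k0 <- paste(n0$pairs$gene_a, n0$pairs$gene_b)[n0$pairs$call == -1L]
  k5 <- paste(n5$pairs$gene_a, n5$pairs$gene_b)[n5$pairs$call == -1L]
  expect_lt(length(intersect(k0, k5)) / length(k0), 0.65)
  expect_gt(length(intersect(k0, k5)) / length(k0), 0.35)
})

test_that("study suites are deterministic and structurally correct", {
  cfg <- list(
    truth = truth_model(n_genes = 30, n_modules = 3),
    datasets = list(
      list(dataset_id = "d1", observation = observation_model()),
      list(dataset_id = "d2", observation = observation_model())))
  s1 <- generate_study_suite(cfg, seed = 11)
  s2 <- generate_study_suite(cfg, seed = 11)
  expect_true(gi_network_equal(s1$networks$d1, s2$networks$d1))
  expect_true(gi_network_equal(s1$networks$d2, s2$networks$d2))
  # byte-for-byte determinism of written files
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_edge_list(s1$networks$d1, f1)
  write_edge_list(s2$networks$d1, f2)
  expect_identical(readLines(f1), readLines(f2))

  # same model, different dataset ids -> different draws
  expect_false(gi_network_equal(s1$networks$d1, s1$networks$d2))

  cfg$datasets[[2]]$dataset_id <- "d1"
  expect_error(generate_study_suite(cfg, seed = 1), "duplicate")
})

test_that("suite annotations mirror the module structure as GAF", {
  cfg <- list(
    truth = truth_model(n_genes = 30, n_modules = 3),
    datasets = list(list(dataset_id = "d1",
                         observation = observation_model())))
  path <- withr::local_tempfile(fileext = ".gaf")
  suite <- generate_study_suite(cfg, seed = 2, gaf_path = path)
  expect_equal(length(suite$annotations$terms), 3)
  expect_true(all(lengths(suite$annotations$terms) == 10))
  back <- read_gaf(path)
  expect_equal(back$terms, suite$annotations$terms)
})

test_that("complementary_split partitions the truth gene-anchored", {
  tr <- generate_truth(truth_model(n_genes = 60, n_modules = 6), 8)
  halves <- complementary_split(tr, seed = 3)
  keys <- function(t) paste(t$pairs$gene_a, t$pairs$gene_b)
  k1 <- keys(halves[[1]]); k2 <- keys(halves[[2]])
  expect_length(intersect(k1, k2), 0)
  expect_setequal(c(k1, k2), keys(tr))
  # each half holds roughly half of each module's pairs
  within_count <- function(t) {
    w <- t$modules[t$pairs$gene_a] == t$modules[t$pairs$gene_b]
    sum(w)
  }
  total <- within_count(tr)
  expect_gt(within_count(halves[[1]]), 0.35 * total)
  expect_lt(within_count(halves[[1]]), 0.65 * total)
  # gene-anchored: every gene keeps a coherent same-half clique, so each
  # half's within-module pairs cover only ~half of the module's genes
  # densely; verified via degree concentration
  deg1 <- table(c(halves[[1]]$pairs$gene_a, halves[[1]]$pairs$gene_b))
  expect_gt(sd(as.numeric(deg1)), 0)
})
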