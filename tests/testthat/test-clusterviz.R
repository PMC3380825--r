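test_that("all_vs_all matrices are symmetric with identity diagonals", {
  pr <- random_net_pair(12)
  n3 <- observe(pr$truth, observation_model(), "c", seed = 77)
  nets <- list(pr$a, pr$b, n3)
  for (measure in c("correlation", "overlap", "unique", "disagree")) {
    mat <- all_vs_all(nets, measure)
    expect_equal(mat$values, t(mat$values))
    diag_val <- c(correlation = 1, overlap = 1, unique = 0, disagree = 0)
    expect_equal(unname(diag(mat$values)), rep(diag_val[[measure]], 3))
    # off-diagonals equal direct pairwise recomputation
    cmp <- compare_networks(pr$a, n3)
    expect_equal(mat$values["a", "c"],
                 cmp[[measure]][cmp$sign_filter == "any"][1])
  }
  # identical networks correlate perfectly
  mat_id <- all_vs_all(list(pr$a, pr$a), "correlation")
  expect_equal(mat_id$values[1, 2], 1.0)
})

test_that("profile similarity is the mean of per-gene profile correlations", {
  pr <- random_net_pair(13, n_genes = 15)
  sim <- profile_similarity(pr$a, pr$b)
  per_gene <- vapply(intersect(pr$a$genes, pr$b$genes), function(g)
    gene_profile_correlation(pr$a, pr$b, g), 0)
  expect_equal(sim, mean(per_gene, na.rm = TRUE))
  expect_equal(profile_similarity(pr$a, pr$a), 1.0)

  # negated scores reverse every profile
  neg <- pr$a
  neg$pairs$score <- -neg$pairs$score
  neg$pairs$call <- -neg$pairs$call
  expect_equal(profile_similarity(pr$a, neg), -1.0)
})

test_that("hcluster merges identical datasets first and matches the naive
           agglomeration oracle", {
  v <- matrix(c(1, 1, 0.2,
                1, 1, 0.2,
                0.2, 0.2, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  mat <- structure(list(values = v, measure = "correlation", sign = "any"),
                   class = "measure_matrix")
  dend <- hcluster(mat, "average")
  # A and B (distance 0) merge first, at height 0
  expect_equal(dend$hclust$height[1], 0)
  expect_setequal(dend$hclust$labels[-dend$hclust$merge[1, ]], c("A", "B"))

  # random matrices vs the naive O(n^3) oracle
  for (seed in 1:5) {
    set.seed(seed)
    n <- 6
    d <- matrix(runif(n * n), n, n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    dimnames(d) <- list(LETTERS[1:n], LETTERS[1:n])
    mat <- structure(list(values = d, measure = "unique", sign = "any"),
                     class = "measure_matrix")
    for (linkage in c("average", "complete")) {
      dend <- hcluster(mat, linkage)
      oracle <- naive_agglomerate(d, linkage)
      expect_equal(dend$hclust$height, oracle$heights, tolerance = 1e-9)
      # cluster compositions agree after every merge
      got <- lapply(seq_len(n - 1), function(k) {
        memb <- cutree(dend$hclust, n - k)
        sort(unname(vapply(split(names(memb), memb), function(g)
          paste(sort(g), collapse = "+"), "")))
      })
      expect_equal(got, oracle$partitions)
    }
  }
})

test_that("hcluster validates input and flags undefined cells", {
  v <- matrix(c(0, NA, NA, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  mat <- structure(list(values = v, measure = "unique", sign = "any"),
                   class = "measure_matrix")
  expect_error(hcluster(mat), "undefined cells")
})

test_that("ultrametric input yields the same topology for all linkages", {
  # distances: A-B = 0.2, {A,B}-C = 0.6, all-D = 1.0 (ultrametric)
  d <- matrix(c(0, .2, .6, 1,
                .2, 0, .6, 1,
                .6, .6, 0, 1,
                1, 1, 1, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  mat <- structure(list(values = d, measure = "unique", sign = "any"),
                   class = "measure_matrix")
  tops <- lapply(c("ward", "complete", "average", "median"), function(l) {
    hc <- hcluster(mat, l)$hclust
    lapply(1:3, function(k) sort(vapply(split(LETTERS[1:4],
                                              cutree(hc, k)),
                                        function(g) paste(sort(g),
                                                          collapse = "+"),
                                        "")))
  })
  for (i in 2:4) expect_equal(tops[[i]], tops[[1]])
})

test_that("newick export and matrix round trip are faithful", {
  # two leaves merged at height h -> (A:h,B:h);
  d <- matrix(c(0, 0.7, 0.7, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  mat <- structure(list(values = d, measure = "disagree", sign = "any"),
                   class = "measure_matrix")
  dend <- hcluster(mat, "average")
  expect_equal(dendrogram_newick(dend), "(A:0.7,B:0.7);")

  # matrix round trip + leaf order consistency
  pr <- random_net_pair(14)
  n3 <- observe(pr$truth, observation_model(), "c", seed = 5)
  mat <- all_vs_all(list(pr$a, pr$b, n3), "correlation")
  dend <- hcluster(mat, "average")
  mpath <- withr::local_tempfile(fileext = ".tsv")
  tpath <- withr::local_tempfile(fileext = ".nwk")
  export_comparison(mat, dend, mpath, tpath)
  back <- read_measure_matrix(mpath)
  leaves <- dendrogram_leaves(dend)
  expect_equal(back$values[leaves, leaves],
               mat$values[leaves, leaves])
  # header order matches the Newick leaf set
  nwk <- readLines(tpath)
  for (leaf in leaves) expect_match(nwk, leaf, fixed = TRUE)
  expect_equal(rownames(back$values), leaves)
})
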