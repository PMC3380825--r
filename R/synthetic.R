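#' Ground-truth model for synthetic GI screens
#'
#' The latent biology the simulator assumes: genes partition into
#' functional modules; gene pairs within a module interact densely, and
#' whole modules are connected by coherent "blocks" — each module
#' genetically interacts with a few partner modules, and within such an
#' active block every gene pair interacts with probability `p_block_*`.
#' Block coherence is essential, not decoration: it is what gives two
#' genes of the same module overlapping interaction partner sets, and
#' therefore correlated interaction profiles — the property that makes
#' guilt-by-association prediction possible. With independently drawn
#' pairs, two same-module genes would share at most a couple of partners
#' and Spearman profile correlation over a few hundred genes could never
#' clear a 0.1 threshold (rho scales as shared-partners / profile
#' length). Remaining pairs interact at the sparse `p_between_*`
#' background rates. True interaction magnitudes are Gaussian, floored at
#' 0.1 (S-score-like units).
#'
#' Defaults emulate a few-hundred-gene screen that preserves per-gene
#' interaction counts of genome-scale growth screens (tens of partners
#' per gene) rather than per-pair density, since profile-based function
#' prediction operates on partner counts: 300 genes in 10 equal modules,
#' dense negative structure within modules and blocks, sparse positive
#' structure, and a sparse background.
#'
#' @param n_genes number of genes.
#' @param n_modules number of equal-sized modules (used when
#'   `module_sizes` is NULL; `n_genes` must be divisible by it).
#' @param module_sizes optional integer vector of module sizes summing to
#'   `n_genes`.
#' @param p_within_neg,p_within_pos per-pair probabilities of a true
#'   negative/positive interaction within a module.
#' @param p_between_neg,p_between_pos background probabilities between
#'   modules outside active blocks.
#' @param n_partner_modules number of partner modules each module is
#'   coherently connected to (capped at `n_modules - 1`; 0 disables
#'   blocks). Default `NULL`: about 30% of the other modules
#'   (`ceiling(0.3 * (n_modules - 1))`), which keeps the interacting
#'   fraction of the genome comparable across world sizes.
#' @param p_block_neg,p_block_pos per-pair probabilities inside an active
#'   between-module block.
#' @param score_magnitude_mean,score_magnitude_sd Normal parameters of the
#'   true |score| distribution.
#' @return a `truth_model` list.
#' @export
truth_model <- function(n_genes = 300, n_modules = 10, module_sizes = NULL,
                        p_within_neg = 0.8, p_within_pos = 0.05,
                        p_between_neg = 0.02, p_between_pos = 0.01,
                        n_partner_modules = NULL,
                        p_block_neg = 0.8, p_block_pos = 0.05,
                        score_magnitude_mean = 4, score_magnitude_sd = 1.5) {
  if (is.null(module_sizes)) {
    stopifnot(n_genes %% n_modules == 0)
    module_sizes <- rep.int(n_genes %/% n_modules, n_modules)
  }
  stopifnot(sum(module_sizes) == n_genes)
  if (is.null(n_partner_modules))
    n_partner_modules <- ceiling(0.3 * (length(module_sizes) - 1))
  probs <- c(p_within_neg, p_within_pos, p_between_neg, p_between_pos,
             p_block_neg, p_block_pos)
  stopifnot(all(probs >= 0), all(probs <= 1),
            p_within_neg >= p_between_neg, p_within_pos >= p_between_pos,
            n_partner_modules >= 0)
  if (p_within_neg + p_within_pos > 1)
    stop("p_within_neg + p_within_pos must not exceed 1")
  if (p_between_neg + p_between_pos > 1)
    stop("p_between_neg + p_between_pos must not exceed 1")
  if (p_block_neg + p_block_pos > 1)
    stop("p_block_neg + p_block_pos must not exceed 1")
  n_partner_modules <- min(as.integer(n_partner_modules),
                           length(module_sizes) - 1L)
  structure(list(n_genes = n_genes, module_sizes = as.integer(module_sizes),
                 p_within_neg = p_within_neg, p_within_pos = p_within_pos,
                 p_between_neg = p_between_neg, p_between_pos = p_between_pos,
                 n_partner_modules = n_partner_modules,
                 p_block_neg = p_block_neg, p_block_pos = p_block_pos,
                 score_magnitude_mean = score_magnitude_mean,
                 score_magnitude_sd = score_magnitude_sd),
            class = "truth_model")
}

# Seeded, approximately regular assignment of coherent partner-module
# blocks: module pairs are shuffled and accepted greedily while both
# members still have fewer than n_partner_modules partners.
assign_blocks <- function(n_modules, n_partner, seed) {
  if (n_partner == 0 || n_modules < 2)
    return(matrix(integer(0), ncol = 2))
  pairs <- which(upper.tri(diag(n_modules)), arr.ind = TRUE)
  with_seed(seed, {
    ord <- sample.int(nrow(pairs))
    degree <- integer(n_modules)
    keep <- logical(nrow(pairs))
    for (r in ord) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (degree[i] < n_partner && degree[j] < n_partner) {
        keep[r] <- TRUE
        degree[i] <- degree[i] + 1L
        degree[j] <- degree[j] + 1L
      }
    }
    pairs[keep, , drop = FALSE]
  })
}

#' Observation model of one synthetic screen
#'
#' The error process layered on the shared truth to produce one observed
#' dataset: partial pair coverage, per-sign detection with the stated
#' sensitivity, false-positive calls targeting the stated per-sign
#' precision in expectation, additive Gaussian score noise,
#' condition-specific rewiring of a fraction of true interactions, and a
#' laboratory batch effect in which datasets sharing a `batch_id` draw a
#' fraction of their false-positive positions from a common pool.
#'
#' Rate defaults are the published per-sign estimates for the reference
#' growth screen (see [costanzo_rates()]).
#'
#' @param sensitivity_pos,precision_pos,sensitivity_neg,precision_neg
#'   per-sign detection rates in (0, 1].
#' @param coverage fraction of all gene pairs tested, in (0, 1].
#' @param noise_sd SD of additive Gaussian score noise.
#' @param rewire_fraction fraction of this dataset's true interactions
#'   replaced by condition-specific ones (same sign, conserved count), in
#'   \[0, 1).
#' @param batch_id laboratory/batch label (`NA` = no batch effect).
#' @param batch_fp_share fraction of false-positive positions drawn from
#'   the batch-shared pool, in \[0, 1\].
#' @return an `observation_model` list.
#' @export
observation_model <- function(sensitivity_pos = 0.18, precision_pos = 0.59,
                              sensitivity_neg = 0.35, precision_neg = 0.63,
                              coverage = 1, noise_sd = 1,
                              rewire_fraction = 0,
                              batch_id = NA_character_,
                              batch_fp_share = 0) {
  rates <- c(sensitivity_pos, precision_pos, sensitivity_neg, precision_neg)
  stopifnot(all(rates > 0), all(rates <= 1),
            coverage > 0, coverage <= 1,
            rewire_fraction >= 0, rewire_fraction < 1,
            batch_fp_share >= 0, batch_fp_share <= 1)
  batch_id <- if (is.null(batch_id) || length(batch_id) != 1 ||
                  is.na(batch_id)) NA_character_ else as.character(batch_id)
  structure(list(sensitivity_pos = sensitivity_pos,
                 precision_pos = precision_pos,
                 sensitivity_neg = sensitivity_neg,
                 precision_neg = precision_neg,
                 coverage = coverage, noise_sd = noise_sd,
                 rewire_fraction = rewire_fraction,
                 batch_id = batch_id, batch_fp_share = batch_fp_share),
            class = "observation_model")
}

#' Draw a latent true interaction network
#'
#' Each gene pair's true call is drawn independently with the
#' module-dependent probabilities of the [truth_model()]; true scores get
#' a Gaussian magnitude (floored at 0.1) and the sign of the call.
#' Deterministic given `seed`.
#'
#' @param model a [truth_model()].
#' @param seed RNG seed.
#' @return a `true_network`: list with `genes`, `modules` (named integer
#'   vector of module indices), `pairs` (data.frame of the nonzero pairs:
#'   `gene_a`, `gene_b`, `call`, `score`) and the magnitude parameters.
#' @export
generate_truth <- function(model, seed = 1L) {
  stopifnot(inherits(model, "truth_model"))
  genes <- sprintf("g%04d", seq_len(model$n_genes))
  modules <- stats::setNames(
    rep.int(seq_along(model$module_sizes), model$module_sizes), genes)
  pairs <- all_gene_pairs(genes)
  mod_a <- modules[pairs$gene_a]
  mod_b <- modules[pairs$gene_b]
  within <- mod_a == mod_b
  blocks <- assign_blocks(length(model$module_sizes),
                          model$n_partner_modules,
                          seed = string_seed("blocks", seed))
  in_block <- rep(FALSE, nrow(pairs))
  if (nrow(blocks) > 0) {
    block_key <- paste(blocks[, 1], blocks[, 2])
    in_block <- paste(pmin(mod_a, mod_b), pmax(mod_a, mod_b)) %in% block_key
  }
  p_neg <- ifelse(within, model$p_within_neg,
           ifelse(in_block, model$p_block_neg, model$p_between_neg))
  p_pos <- ifelse(within, model$p_within_pos,
           ifelse(in_block, model$p_block_pos, model$p_between_pos))
  with_seed(seed, {
    u <- stats::runif(nrow(pairs))
    call <- ifelse(u < p_neg, -1L, ifelse(u < p_neg + p_pos, 1L, 0L))
    nz <- call != 0L
    mag <- pmax(0.1, stats::rnorm(sum(nz), model$score_magnitude_mean,
                                  model$score_magnitude_sd))
    out <- pairs[nz, , drop = FALSE]
    out$call <- call[nz]
    out$score <- out$call * mag
    rownames(out) <- NULL
    structure(list(genes = genes, modules = modules, pairs = out,
                   blocks = blocks,
                   score_magnitude_mean = model$score_magnitude_mean,
                   score_magnitude_sd = model$score_magnitude_sd),
              class = "true_network")
  })
}

#' @export
print.true_network <- function(x, ...) {
  cat(sprintf(
    "true_network: %d genes, %d modules, %d true interactions (%d neg / %d pos)\n",
    length(x$genes), length(unique(x$modules)), nrow(x$pairs),
    sum(x$pairs$call == -1L), sum(x$pairs$call == 1L)))
  invisible(x)
}

#' Observe a truth through a screen's error process
#'
#' Produces one observed [gi_network()] from a [generate_truth()] result:
#'
#' 1. a random `coverage` fraction of all gene pairs is tested;
#' 2. a `rewire_fraction` of the tested true interactions is moved (same
#'    sign) onto randomly chosen tested null pairs — the dataset-specific
#'    condition rewiring;
#' 3. each tested true interaction is detected with the per-sign
#'    sensitivity;
#' 4. false-positive calls are added on tested null pairs so that each
#'    sign class's expected precision equals the model's precision
#'    (expected FP count = expected TP count × (1 − p)/p); a
#'    `batch_fp_share` fraction of the FP positions comes from a
#'    pseudo-random pool keyed by `batch_id`, shared by all datasets with
#'    the same `batch_id` and `batch_seed`;
#' 5. detected pairs score `true_score + N(0, noise_sd)` (sign forced to
#'    match the call), false positives draw a fresh magnitude with the
#'    called sign, and undetected tested pairs get call 0 and pure noise.
#'
#' @param truth a `true_network`.
#' @param model an [observation_model()].
#' @param dataset_id identifier of the produced dataset.
#' @param seed RNG seed for this dataset's private randomness.
#' @param batch_seed seed shared by all datasets of one study; combined
#'   with `batch_id` to key the shared false-positive pool.
#' @param ... metadata passed to [gi_network()] (`readout`, `condition`,
#'   `laboratory`, `group`).
#' @return a `gi_network`.
#' @export
observe <- function(truth, model, dataset_id, seed = 1L, batch_seed = 0L,
                    ...) {
  stopifnot(inherits(truth, "true_network"),
            inherits(model, "observation_model"))
  genes <- truth$genes
  pairs <- all_gene_pairs(genes)
  M <- nrow(pairs)
  key <- pair_key(pairs$gene_a, pairs$gene_b)
  tcall <- integer(M)
  tscore <- numeric(M)
  hit <- match(pair_key(truth$pairs$gene_a, truth$pairs$gene_b), key)
  tcall[hit] <- truth$pairs$call
  tscore[hit] <- truth$pairs$score

  sens <- c(`-1` = model$sensitivity_neg, `1` = model$sensitivity_pos)
  prec <- c(`-1` = model$precision_neg, `1` = model$precision_pos)

  with_seed(seed, {
    n_tested <- max(1L, as.integer(round(model$coverage * M)))
    tested <- logical(M)
    tested[if (n_tested == M) seq_len(M) else sample.int(M, n_tested)] <- TRUE

    # dataset-specific truth after condition rewiring
    dcall <- tcall
    dscore <- tscore
    for (sgn in c(-1L, 1L)) {
      idx_true <- which(tested & dcall == sgn)
      n_rw <- round(model$rewire_fraction * length(idx_true))
      if (n_rw > 0) {
        drop_idx <- sample(idx_true, n_rw)
        nulls <- which(tested & dcall == 0L)
        add_idx <- sample(nulls, min(n_rw, length(nulls)))
        dcall[drop_idx] <- 0L
        dscore[drop_idx] <- 0
        dcall[add_idx] <- sgn
        dscore[add_idx] <- sgn * pmax(0.1, stats::rnorm(
          length(add_idx), truth$score_magnitude_mean,
          truth$score_magnitude_sd))
      }
    }

    # detection of true interactions
    ocall <- integer(M)
    for (sgn in c(-1L, 1L)) {
      idx_true <- which(tested & dcall == sgn)
      det <- stats::runif(length(idx_true)) < sens[as.character(sgn)]
      ocall[idx_true[det]] <- sgn
    }

    # false positives targeting expected per-sign precision
    for (sgn in c(-1L, 1L)) {
      s <- sens[as.character(sgn)]
      p <- prec[as.character(sgn)]
      n_true_s <- sum(tested & dcall == sgn)
      exp_fp <- s * n_true_s * (1 - p) / p
      eligible <- which(tested & dcall == 0L & ocall == 0L)
      if (exp_fp <= 0 || length(eligible) == 0) next
      f <- min(1, exp_fp / length(eligible))
      n_fp <- stats::rbinom(1L, length(eligible), f)
      if (n_fp == 0) next
      fp_idx <- integer(0)
      n_batch <- if (!is.na(model$batch_id))
        round(model$batch_fp_share * n_fp) else 0L
      if (n_batch > 0) {
        pool_seed <- string_seed(paste0(model$batch_id, "/", sgn),
                                 batch_seed)
        pool <- with_seed(pool_seed, sample.int(M))
        fp_idx <- pool[pool %in% eligible][seq_len(n_batch)]
        fp_idx <- fp_idx[!is.na(fp_idx)]
      }
      remaining <- setdiff(eligible, fp_idx)
      n_indep <- n_fp - length(fp_idx)
      if (n_indep > 0 && length(remaining) > 0)
        fp_idx <- c(fp_idx, sample(remaining, min(n_indep,
                                                  length(remaining))))
      ocall[fp_idx] <- sgn
      dscore[fp_idx] <- sgn * pmax(0.1, stats::rnorm(
        length(fp_idx), truth$score_magnitude_mean,
        truth$score_magnitude_sd))
    }

    # observed scores
    oscore <- numeric(M)
    noise <- stats::rnorm(M, 0, model$noise_sd)
    called <- tested & ocall != 0L
    oscore[called] <- ocall[called] *
      pmax(0.05, abs(dscore[called] + noise[called]))
    silent <- tested & ocall == 0L
    oscore[silent] <- noise[silent]

    out <- pairs[tested, , drop = FALSE]
    out$score <- oscore[tested]
    out$call <- ocall[tested]
    gi_network(out, dataset_id = dataset_id, genes = genes, ...)
  })
}

#' Generate a full multi-dataset synthetic study
#'
#' One shared truth observed through several per-dataset error processes,
#' plus GO-like annotations (one term per functional module, evidence code
#' IDA). Deterministic given `seed`; each dataset's private seed is
#' derived from its id, and the batch pools from the suite seed, so
#' datasets sharing a `batch_id` share false-positive positions.
#'
#' @param config list with elements `truth` (a [truth_model()]) and
#'   `datasets`, a list of entries each holding `dataset_id`, an
#'   `observation` ([observation_model()]) and optional metadata
#'   (`readout`, `condition`, `laboratory`, `group`).
#' @param seed suite seed.
#' @param gaf_path optional path; when given, annotations are written
#'   there in GAF 2.1.
#' @return list with `networks` (named list of `gi_network`),
#'   `annotations` (an [annotation_set()]) and `truth`.
#' @export
generate_study_suite <- function(config, seed = 1L, gaf_path = NULL) {
  stopifnot(is.list(config), inherits(config$truth, "truth_model"),
            length(config$datasets) >= 1)
  ids <- vapply(config$datasets, function(d) d$dataset_id, "")
  if (anyDuplicated(ids))
    stop("duplicate dataset_id: ", ids[duplicated(ids)][1])
  truth <- generate_truth(config$truth, seed)
  networks <- lapply(config$datasets, function(d) {
    observe(truth, d$observation, d$dataset_id,
            seed = string_seed(d$dataset_id, seed), batch_seed = seed,
            readout = d$readout %||% NA_character_,
            condition = d$condition %||% NA_character_,
            laboratory = d$laboratory %||% d$observation$batch_id %||%
              NA_character_,
            group = d$group %||% "SYNTHETIC")
  })
  names(networks) <- ids
  ann <- module_annotations(truth)
  if (!is.null(gaf_path)) write_gaf(ann, gaf_path)
  list(networks = networks, annotations = ann, truth = truth)
}

#' GO-like annotations from a truth's module structure
#'
#' One term per functional module (ids `MOD:0001`, ...), annotating the
#' module's genes, aspect "P", evidence code IDA.
#'
#' @param truth a `true_network`.
#' @return an [annotation_set()].
#' @export
module_annotations <- function(truth) {
  stopifnot(inherits(truth, "true_network"))
  mods <- sort(unique(truth$modules))
  term_genes <- lapply(mods, function(m)
    sort(names(truth$modules)[truth$modules == m]))
  ids <- sprintf("MOD:%04d", mods)
  names(term_genes) <- ids
  annotation_set(term_genes,
                 aspect = stats::setNames(rep("P", length(ids)), ids))
}

#' Split a truth into two complementary half-signal truths
#'
#' Splits the interaction signal gene-wise: each module's genes are
#' partitioned at random into two halves, and a true interaction goes to
#' dataset 1 when both its genes fall in their modules' first halves, to
#' dataset 2 when both fall in the second halves, and to a fair coin flip
#' otherwise. Each dataset therefore carries complete interaction
#' profiles for one half of every module's genes (and roughly half of
#' each module's pairs overall), so the two observed networks hold
#' complementary functional signal: either alone can connect only its own
#' half of a module, while their combination connects both — the regime
#' in which combining networks must outperform either alone.
#'
#' The split is anchored on genes rather than sampled pair-by-pair
#' because an independent pair split would thin every gene's partner set
#' in both datasets at once, leaving Spearman profile correlations below
#' any useful threshold in either (shared-partner counts drop
#' quadratically).
#'
#' @param truth a `true_network`.
#' @param seed RNG seed for the split.
#' @return list of two `true_network`s whose `pairs` partition the
#'   truth's pairs.
#' @export
complementary_split <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "true_network"))
  genes <- truth$genes
  with_seed(seed, {
    pref <- integer(length(genes))
    names(pref) <- genes
    for (m in unique(truth$modules)) {
      members <- sample(names(truth$modules)[truth$modules == m])
      pref[members] <- rep_len(1:2, length(members))
    }
    pa <- pref[truth$pairs$gene_a]
    pb <- pref[truth$pairs$gene_b]
    ds <- ifelse(pa == pb, pa, sample(1:2, nrow(truth$pairs),
                                      replace = TRUE))
  })
  keep <- function(which_ds) {
    t2 <- truth
    t2$pairs <- truth$pairs[ds == which_ds, , drop = FALSE]
    rownames(t2$pairs) <- NULL
    t2
  }
  list(keep(1L), keep(2L))
}
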