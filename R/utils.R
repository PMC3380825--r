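# Internal helpers shared across modules.

# Canonical (unordered) pair key. "\t" cannot occur inside a gene identifier
# coming from a tab-separated file, so the key is collision-free.
pair_key <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "\t")
}

# Canonicalize pair orientation: gene_a < gene_b lexicographically.
canonicalize_pairs <- function(df) {
  swap <- df$gene_a > df$gene_b
  if (any(swap)) {
    tmp <- df$gene_a[swap]
    df$gene_a[swap] <- df$gene_b[swap]
    df$gene_b[swap] <- tmp
  }
  df
}

# Deterministic 32-bit seed derived from a string and a base seed.
# Polynomial rolling hash modulo the Mersenne prime 2^31 - 1, so the
# result is always a valid R integer seed.
string_seed <- function(s, base_seed = 0L) {
  h <- as.double(base_seed) %% 2147483647
  for (k in utf8ToInt(as.character(s))) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# All unordered pairs over a sorted gene vector, in a fixed enumeration
# order (i < j by position). Returns a data.frame(gene_a, gene_b); because
# `genes` is sorted the pairs are already canonical.
all_gene_pairs <- function(genes) {
  n <- length(genes)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  data.frame(gene_a = genes[i], gene_b = genes[j], stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
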