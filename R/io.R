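#' Describe the column layout of a GI edge-list file
#'
#' @param query,array,score,call column names for the query gene, array
#'   gene, quantitative score and (optional) sign call; set `call = NULL`
#'   when the file carries no call column.
#' @param na missing-value token; rows whose score equals it are dropped
#'   (the pair is treated as untested).
#' @param has_header does the file start with a header line?
#' @return a `table_dialect` list.
#' @export
table_dialect <- function(query = "gene_a", array = "gene_b",
                          score = "score", call = "call",
                          na = "NA", has_header = TRUE) {
  structure(list(query = query, array = array, score = score, call = call,
                 na = na, has_header = has_header),
            class = "table_dialect")
}

#' Collapse reciprocal query/array measurements onto canonical pairs
#'
#' Screens often measure a pair twice, once in each query/array
#' orientation. Networks are treated as undirected, so reciprocal
#' measurements collapse to one canonical pair. Scores are combined by the
#' chosen policy; duplicate calls collapse to the majority sign (sign of
#' their sum).
#'
#' @param records data.frame with columns `gene_a`, `gene_b`, `score` and
#'   optionally `call`.
#' @param policy `"mean"` (arithmetic mean of duplicate scores),
#'   `"min-magnitude"` (duplicate with the smallest absolute score), or
#'   `"error-on-conflict"` (mean, but error if duplicate calls — or score
#'   signs, when no calls are present — disagree in sign).
#' @return data.frame of canonical pairs (`gene_a < gene_b`), one row per
#'   unordered pair, with collapsed `score` and `call`.
#' @export
symmetrize <- function(records,
                       policy = c("mean", "min-magnitude",
                                  "error-on-conflict")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(records),
            all(c("gene_a", "gene_b", "score") %in% names(records)))
  if (nrow(records) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), call = integer()))
  records$gene_a <- as.character(records$gene_a)
  records$gene_b <- as.character(records$gene_b)
  if (is.null(records$call)) records$call <- 0L
  records <- canonicalize_pairs(records)
  key <- pair_key(records$gene_a, records$gene_b)
  idx <- split(seq_len(nrow(records)), key)
  if (policy == "error-on-conflict") {
    for (ii in idx) {
      sgn <- records$call[ii]
      if (all(sgn == 0L)) sgn <- sign(records$score[ii])
      sgn <- unique(sgn[sgn != 0])
      if (length(sgn) > 1)
        stop("conflicting interaction signs for pair (",
             records$gene_a[ii[1]], ", ", records$gene_b[ii[1]], ")")
    }
  }
  rows <- lapply(idx, function(ii) {
    sc <- records$score[ii]
    score <- if (policy == "min-magnitude") sc[which.min(abs(sc))]
             else mean(sc)
    call <- as.integer(sign(sum(records$call[ii])))
    # a collapsed call must stay sign-consistent with the collapsed score
    if ((call == -1L && score >= 0) || (call == 1L && score <= 0)) call <- 0L
    data.frame(gene_a = records$gene_a[ii[1]], gene_b = records$gene_b[ii[1]],
               score = score, call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_a, out$gene_b, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Read a quantitative GI dataset from a tab-separated edge list
#'
#' Reads a tab-separated file of (query gene, array gene, score, optional
#' call) rows, drops self-pairs (with a warning) and rows with a missing
#' score, collapses reciprocal measurements with [symmetrize()], and
#' returns a [gi_network()]. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param dialect a [table_dialect()] describing the columns.
#' @param dataset_id dataset identifier.
#' @param policy duplicate-collapse policy passed to [symmetrize()].
#' @inheritParams gi_network
#' @return a `gi_network`.
#' @export
read_gi_table <- function(path, dialect = table_dialect(),
                          dataset_id = basename(path),
                          readout = NA_character_, condition = NA_character_,
                          laboratory = NA_character_, group = "SYNTHETIC",
                          policy = "mean") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, sep = "\t", header = dialect$has_header,
                           comment.char = "#", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!dialect$has_header) {
    wanted <- c(dialect$query, dialect$array, dialect$score, dialect$call)
    names(raw) <- wanted[seq_len(ncol(raw))]
  }
  for (col in c(dialect$query, dialect$array, dialect$score)) {
    if (!col %in% names(raw))
      stop("required column '", col, "' not found in ", path)
  }
  df <- data.frame(gene_a = raw[[dialect$query]],
                   gene_b = raw[[dialect$array]],
                   score_chr = raw[[dialect$score]],
                   stringsAsFactors = FALSE)
  has_call <- !is.null(dialect$call) && dialect$call %in% names(raw)
  df$call_chr <- if (has_call) raw[[dialect$call]] else "0"

  missing_score <- df$score_chr == dialect$na | is.na(df$score_chr)
  df <- df[!missing_score, , drop = FALSE]
  score <- suppressWarnings(as.numeric(df$score_chr))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1]
    stop("non-numeric score '", df$score_chr[bad], "' at data row ",
         bad, " of ", path)
  }
  df$score <- score
  call <- suppressWarnings(as.integer(as.numeric(df$call_chr)))
  call[is.na(call)] <- 0L
  df$call <- call

  self <- df$gene_a == df$gene_b
  if (any(self)) {
    warning("dropping ", sum(self), " self-pair row(s) in ", path)
    df <- df[!self, , drop = FALSE]
  }
  pairs <- symmetrize(df[, c("gene_a", "gene_b", "score", "call")],
                      policy = policy)
  gi_network(pairs, dataset_id = dataset_id, readout = readout,
             condition = condition, laboratory = laboratory, group = group)
}

#' Write a network as a canonical tab-separated edge list
#'
#' One canonical pair per row, columns `gene_a`, `gene_b`, `score`, `call`.
#' Scores are printed with full double precision so that re-reading the
#' file reproduces the network exactly.
#'
#' @param net a `gi_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "gi_network"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("gene_a\tgene_b\tscore\tcall", con)
  if (nrow(net$pairs) > 0) {
    writeLines(sprintf("%s\t%s\t%.17g\t%d", net$pairs$gene_a,
                       net$pairs$gene_b, net$pairs$score, net$pairs$call),
               con)
  }
  invisible(path)
}
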