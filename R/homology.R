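#' Scoring model for protein local alignment
#'
#' Bundles the substitution matrix, affine gap penalties and
#' Karlin-Altschul parameters used to turn raw Smith-Waterman scores into
#' bit scores and E-values.  Defaults are the standard published values
#' for gapped BLOSUM62 with gap open 11 / extend 1.
#'
#' @param matrix substitution matrix name; only "BLOSUM62" is supported.
#' @param gap_open,gap_extend affine gap penalties (a gap of length k costs
#'   `gap_open + k * gap_extend`).
#' @param lambda,K Karlin-Altschul constants (lambda > 0, K > 0).
#' @param search_space optional numeric `c(m, n)` effective query/subject
#'   residue counts; when `NULL`, search functions use the query length and
#'   the total subject residue count.
#' @return object of class `scoring_model`.
#' @export
scoring_model <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          lambda = 0.267, K = 0.041, search_space = NULL) {
  if (!identical(matrix, "BLOSUM62"))
    stop("only BLOSUM62 is supported")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 search_space = search_space),
            class = "scoring_model")
}

#' Optimal local alignment of two proteins
#'
#' Affine-gap Smith-Waterman under the model's substitution matrix.  An
#' empty alignment (score 0) is returned when no positive-scoring residue
#' pair exists.  Reported coordinates are 1-based inclusive.
#'
#' @param a,b amino-acid strings over the 20-letter alphabet plus X.
#' @param model a [scoring_model()].
#' @return list with `raw_score`, `qstart`, `qend`, `sstart`, `send`,
#'   `identity` (matched columns), `alignment_length`, `gapopen`,
#'   `mismatch`.  Span fields are 0 for an empty alignment.
#' @export
align_local <- function(a, b, model = scoring_model()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  r <- sw_align_cpp(a, b, model$gap_open, model$gap_extend)
  empty <- r$score <= 0
  list(raw_score = r$score,
       qstart = if (empty) 0L else r$qstart + 1L, qend = r$qend,
       sstart = if (empty) 0L else r$sstart + 1L, send = r$send,
       identity = r$ident, alignment_length = r$length,
       gapopen = r$gapopen, mismatch = r$mismatch)
}

#' Bit score and E-value from a raw alignment score
#'
#' `bitscore = (lambda * raw - ln K) / ln 2`;
#' `evalue = m * n * 2^-bitscore`, with the effective search space taken as
#' the plain product of query and subject residue counts.
#'
#' @param raw_score raw score(s), >= 0.
#' @param model a [scoring_model()].
#' @param m,n effective query and subject residue counts; default to
#'   `model$search_space`.
#' @return list with numeric vectors `bitscore` and `evalue`.
#' @export
bits_and_evalue <- function(raw_score, model = scoring_model(), m = NULL,
                            n = NULL) {
  if (any(raw_score < 0)) stop("raw_score must be >= 0")
  ss <- model$search_space %||% c(NA_real_, NA_real_)
  m <- m %||% ss[1]; n <- n %||% ss[2]
  bits <- (model$lambda * raw_score - log(model$K)) / log(2)
  list(bitscore = bits, evalue = m * n * 2^(-bits))
}

# Bulk in-frame translation of a character vector (trailing partial codon
# trimmed); stops appear as '*'.
translate_bulk <- function(x) {
  n3 <- nchar(x) - nchar(x) %% 3L
  s <- Biostrings::DNAStringSet(substr(x, 1L, n3))
  as.character(Biostrings::translate(s, if.fuzzy.codon = "solve"))
}

# Six-frame translation of nucleotide reads into peptide fragments split at
# stop codons.  Returns a data.frame mapping each fragment back to its read
# and frame; fragments shorter than min_fragment_aa are dropped.
six_frame_fragments <- function(reads, min_fragment_aa = 10) {
  ids <- names(reads) %||% sprintf("q%d", seq_along(reads))
  lens <- nchar(reads)
  fwd <- unname(reads); rev <- revcomp(fwd)
  out <- list()
  for (fr in 1:3) {
    for (dir in c(1L, -1L)) {
      src <- if (dir == 1L) fwd else rev
      aa <- translate_bulk(substring(src, fr))
      pieces <- strsplit(aa, "*", fixed = TRUE)
      np <- lengths(pieces)
      if (!sum(np)) next
      flat <- unlist(pieces, use.names = FALSE)
      ridx <- rep.int(seq_along(pieces), np)
      offs <- unlist(lapply(pieces, function(p) {
        if (!length(p)) integer() else
          cumsum(c(0L, nchar(p[-length(p)]) + 1L))
      }), use.names = FALSE)
      keep <- nchar(flat) >= min_fragment_aa
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        seq = flat[keep], read = ridx[keep], frame = dir * fr,
        aa_off = offs[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seq = character(), read = integer(),
                      read_id = character(), frame = integer(),
                      aa_off = integer(), read_len = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$read_id <- ids[res$read]
  res$read_len <- lens[res$read]
  res
}

# map fragment-local aa coordinates to read nucleotide coordinates
# (1-based inclusive; qstart > qend on reverse frames, BLASTx-style)
frag_to_read_coords <- function(frame, aa_off, read_len, qs0, qe0) {
  fr <- abs(frame)
  nt_s <- (fr - 1L) + 3L * (aa_off + qs0)       # 0-based on translated strand
  nt_e <- (fr - 1L) + 3L * (aa_off + qe0)       # exclusive
  qstart <- ifelse(frame > 0, nt_s + 1L, read_len - nt_s)
  qend <- ifelse(frame > 0, nt_e, read_len - nt_e + 1L)
  list(qstart = as.integer(qstart), qend = as.integer(qend))
}

#' Search protein or nucleotide queries against a protein database
#'
#' The package's replacement for an external BLASTp/BLASTx-style search.
#' In `protein` mode the queries are amino-acid sequences; in `translated`
#' mode they are nucleotide reads, translated in all six frames, split at
#' stop codons, with fragments shorter than `min_fragment_aa` discarded.
#' At most the best hit per (query, subject, frame) is reported and hits
#' are sorted by descending bit score.
#'
#' A k-mer (k = 4) two-hit prefilter precedes full dynamic programming;
#' disable with `prefilter = FALSE` for exhaustive (oracle-comparable)
#' search.
#'
#' @param queries named character vector (proteins, or nucleotide reads in
#'   translated mode), or a `virome` data.frame.
#' @param subjects named character vector of proteins.
#' @param model a [scoring_model()].
#' @param mode "protein" or "translated".
#' @param max_evalue,min_bitscore reporting thresholds (inclusive).
#' @param prefilter logical; use the k-mer prefilter.
#' @param min_fragment_aa minimum translated fragment length.
#' @return data.frame of hits in BLAST tabular ("outfmt 6") column order
#'   (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore`) plus `raw_score`, `frame` (0 for protein queries)
#'   and `qcovs` (aligned query span / query length x 100, measured on the
#'   translated fragment in translated mode).
#' @export
homology_search <- function(queries, subjects, model = scoring_model(),
                            mode = c("protein", "translated"),
                            max_evalue = 10, min_bitscore = 0,
                            prefilter = TRUE, min_fragment_aa = 10) {
  mode <- match.arg(mode)
  if (inherits(queries, "virome") ||
      (is.data.frame(queries) && all(c("read_id", "sequence") %in% names(queries))))
    queries <- stats::setNames(queries$sequence, queries$read_id)
  if (is.null(names(queries)))
    names(queries) <- sprintf("q%d", seq_along(queries))
  if (is.null(names(subjects)))
    names(subjects) <- sprintf("s%d", seq_along(subjects))
  if (!length(subjects) || !length(queries)) return(empty_hits())

  if (mode == "translated") {
    frags <- six_frame_fragments(queries, min_fragment_aa)
    if (!nrow(frags)) return(empty_hits())
    qseq <- frags$seq
  } else {
    qseq <- unname(queries)
  }
  raw <- search_cpp(qseq, unname(subjects), model$gap_open,
                    model$gap_extend, prefilter)
  if (!nrow(raw)) return(empty_hits())

  n_db <- sum(nchar(subjects))
  qlen <- nchar(qseq)[raw$q_idx]
  be <- bits_and_evalue(raw$raw_score, model, m = qlen, n = n_db)
  hits <- data.frame(
    qseqid = if (mode == "translated") frags$read_id[raw$q_idx]
             else names(queries)[raw$q_idx],
    sseqid = names(subjects)[raw$s_idx],
    pident = 100 * raw$ident / raw$aln_len,
    length = raw$aln_len,
    mismatch = raw$mismatch,
    gapopen = raw$gapopen,
    qstart = raw$qstart0 + 1L,
    qend = raw$qend0,
    sstart = raw$sstart0 + 1L,
    send = raw$send0,
    evalue = be$evalue,
    bitscore = be$bitscore,
    raw_score = raw$raw_score,
    frame = if (mode == "translated") frags$frame[raw$q_idx] else 0L,
    qcovs = 100 * (raw$qend0 - raw$qstart0) / qlen,
    stringsAsFactors = FALSE)

  if (mode == "translated") {
    cc <- frag_to_read_coords(hits$frame, frags$aa_off[raw$q_idx],
                              frags$read_len[raw$q_idx],
                              raw$qstart0, raw$qend0)
    hits$qstart <- cc$qstart
    hits$qend <- cc$qend
  }
  hits <- hits[hits$evalue <= max_evalue & hits$bitscore >= min_bitscore, ,
               drop = FALSE]
  if (nrow(hits)) {
    # best hit per (query, subject, frame)
    key <- paste(hits$qseqid, hits$sseqid, hits$frame, sep = "\r")
    hits <- hits[order(key, -hits$bitscore, hits$evalue), , drop = FALSE]
    hits <- hits[!duplicated(key[order(key, -hits$bitscore, hits$evalue)]), ,
                 drop = FALSE]
    hits <- hits[order(-hits$bitscore, hits$evalue, hits$qseqid,
                       hits$sseqid), , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             raw_score = integer(), frame = integer(), qcovs = numeric(),
             stringsAsFactors = FALSE)
}

OUTFMT6 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
             "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Write hits in BLAST tabular (outfmt 6) format
#' @param hits a hits data.frame (from [homology_search()] or
#'   [read_hits()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(hits[, c("qseqid", "sseqid")],
                    pident = sprintf("%.3f", hits$pident),
                    hits[, c("length", "mismatch", "gapopen", "qstart",
                             "qend", "sstart", "send")],
                    evalue = sprintf("%.3e", hits$evalue),
                    bitscore = sprintf("%.1f", hits$bitscore),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read hits from BLAST tabular (outfmt 6) format
#'
#' Accepts the standard 12-column dialect; extra trailing columns are
#' tolerated and ignored.  A malformed row raises an error naming its line
#' number.
#'
#' @param path tab-separated hits file.
#' @return hits data.frame with the 12 standard columns.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hits()[, OUTFMT6])
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 12)
      stop("malformed hit row at line ", i, ": expected 12 columns")
    nums <- suppressWarnings(as.numeric(p[3:12]))
    if (anyNA(nums))
      stop("malformed hit row at line ", i, ": non-numeric field")
  }
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                    pident = as.numeric(m[, 3]),
                    length = as.integer(m[, 4]),
                    mismatch = as.integer(m[, 5]),
                    gapopen = as.integer(m[, 6]),
                    qstart = as.integer(m[, 7]),
                    qend = as.integer(m[, 8]),
                    sstart = as.integer(m[, 9]),
                    send = as.integer(m[, 10]),
                    evalue = as.numeric(m[, 11]),
                    bitscore = as.numeric(m[, 12]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
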