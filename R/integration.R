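#' Map nucleotide reads to a reference by seeded local alignment
#'
#' Exact 12-mer seeding on both strands followed by banded local
#' alignment around each candidate diagonal; the best local alignment per
#' read at or above `min_score` is reported with soft-clipped ends.
#' Reads sharing no 12-mer with the reference are reported unmapped.
#'
#' @param reads a `virome` data.frame or named character vector.
#' @param reference an [annotated_genome()] or a nucleotide string.
#' @param match,mismatch,gap alignment scores (linear gap penalty).
#' @param min_score minimum reported alignment score.
#' @param k seed length.
#' @param band half-width of the alignment band around a seed diagonal.
#' @return data.frame with one row per read: `read_id`, `mapped`,
#'   `score`, `strand`, and 1-based inclusive `read_start`, `read_end`
#'   (in the original read orientation), `ref_start`, `ref_end`.
#' @export
map_reads_nt <- function(reads, reference, match = 1, mismatch = -2,
                         gap = -3, min_score = 25, k = 12, band = 8) {
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads) %||%
                          sprintf("read_%d", seq_along(reads)),
                        sequence = unname(reads), stringsAsFactors = FALSE)
  refseq <- if (inherits(reference, "annotated_genome")) reference$sequence
            else reference
  r <- map_reads_cpp(reads$sequence, refseq, match, mismatch, gap,
                     min_score, k, band)
  data.frame(read_id = reads$read_id, mapped = r$mapped, score = r$score,
             strand = r$strand,
             read_start = r$qstart0 + 1L, read_end = r$qend0,
             ref_start = r$rstart0 + 1L, ref_end = r$rend0,
             stringsAsFactors = FALSE)
}

#' Detect phage-host hybrid reads
#'
#' A read is called hybrid when it splits into a phage-aligned segment
#' and a host-aligned segment, each at least `min_flank` bp, together
#' covering at least `min_cov` of the read.  The read is oriented so that
#' the host alignment is on the forward strand; the bases aligning to
#' both references (the inter-segment overlap) are recorded as an att
#' core candidate, and the junction is labeled `left` (host then phage
#' along the read, the attL side) or `right` (phage then host, attR).
#'
#' @param reads a `virome` data.frame or named character vector.
#' @param phage,host references ([annotated_genome()] or string).
#' @param min_flank minimum segment length on each side (default 20).
#' @param min_cov minimum fraction of the read covered by the two
#'   segments together (default 0.9).
#' @param min_score,... passed to [map_reads_nt()].
#' @return data.frame of class `junction_evidence`: `read_id`, `side`,
#'   `host_start`, `host_end`, `host_junction` (1-based host coordinate
#'   of the junction-side alignment boundary), `phage_start`, `phage_end`,
#'   `overlap` (possibly empty core-candidate string).
#' @export
find_hybrid_reads <- function(reads, phage, host, min_flank = 20,
                              min_cov = 0.9, min_score = 25, ...) {
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads) %||%
                          sprintf("read_%d", seq_along(reads)),
                        sequence = unname(reads), stringsAsFactors = FALSE)
  mp <- map_reads_nt(reads, phage, min_score = min_score, ...)
  mh <- map_reads_nt(reads, host, min_score = min_score, ...)
  both <- which(mp$mapped & mh$mapped)
  rows <- list()
  for (i in both) {
    L <- nchar(reads$sequence[i])
    # orient the read so the host alignment is forward
    flipped <- mh$strand[i] == "-"
    flip <- function(s, e) c(L - e + 1L, L - s + 1L)
    hse <- c(mh$read_start[i], mh$read_end[i])
    pse <- c(mp$read_start[i], mp$read_end[i])
    if (flipped) { hse <- flip(hse[1], hse[2]); pse <- flip(pse[1], pse[2]) }
    hlen <- hse[2] - hse[1] + 1L
    plen <- pse[2] - pse[1] + 1L
    if (hlen < min_flank || plen < min_flank) next
    ov_s <- max(hse[1], pse[1]); ov_e <- min(hse[2], pse[2])
    ov_len <- max(0L, ov_e - ov_s + 1L)
    union_len <- hlen + plen - ov_len
    if (ov_len >= min(hlen, plen)) next       # nested, not a split read
    if (union_len < min_cov * L) next
    side <- if (hse[1] <= pse[1]) "left" else "right"
    oriented <- if (flipped) revcomp(reads$sequence[i]) else reads$sequence[i]
    overlap <- if (ov_len > 0) substr(oriented, ov_s, ov_e) else ""
    # host coordinate of the junction-side boundary of the host alignment
    # (reference coordinates are strand-independent: attL ends the host
    # segment at its highest host coordinate, attR starts it)
    host_junction <- if (side == "left") mh$ref_end[i] else mh$ref_start[i]
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = reads$read_id[i], side = side,
      host_start = mh$ref_start[i], host_end = mh$ref_end[i],
      host_junction = host_junction,
      phage_start = mp$ref_start[i], phage_end = mp$ref_end[i],
      overlap = overlap, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), side = character(),
               host_start = integer(), host_end = integer(),
               host_junction = integer(), phage_start = integer(),
               phage_end = integer(), overlap = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("junction_evidence", "data.frame")
  out
}

# longest substring of s that occurs in both genomes (exact), preferring
# longer, then leftmost.  Used to strip read errors and chance alignment
# extensions from core candidates.
trim_to_common <- function(s, host_seq, phage_seq) {
  n <- nchar(s)
  for (len in seq(n, 1L)) {
    for (start in seq_len(n - len + 1L)) {
      sub <- substr(s, start, start + len - 1L)
      if (grepl(sub, host_seq, fixed = TRUE) &&
          grepl(sub, phage_seq, fixed = TRUE))
        return(sub)
    }
  }
  ""
}

cluster_positions <- function(pos, window) {
  ord <- order(pos)
  cl <- integer(length(pos))
  cid <- 0L; last <- -Inf
  for (i in ord) {
    if (pos[i] - last > window) cid <- cid + 1L
    cl[i] <- cid
    last <- pos[i]
  }
  cl
}

#' Call attachment sites from hybrid-read evidence
#'
#' Junctions are clustered by host position (within `window` bp) on each
#' side; a call requires at least `min_support` reads on the left (attL)
#' and right (attR) sides.  The core is the sequence common to the
#' left-junction and right-junction overlaps (each overlap first trimmed
#' to its longest substring present in both genomes, which removes read
#' errors and chance alignment extensions), chosen by support and
#' verified to occur in both genomes; attL and attR are then assembled
#' from the genome sequences around the verified positions.
#'
#' @param evidence `junction_evidence` from [find_hybrid_reads()] for one
#'   (phage, host) pair.
#' @param phage,host the references ([annotated_genome()] or string).
#' @param min_support minimum supporting reads per side (default 2).
#' @param window junction clustering window in bp (default 5).
#' @param flank flanking bases included in the reported attL/attR
#'   sequences (default 20).
#' @param max_core maximum core length considered when pairing left and
#'   right junction clusters (default 500).
#' @return data.frame of class `att_calls`: `core`, `core_len`,
#'   `host_core_start`, `phage_core_start` (1-based), `attL`, `attR`,
#'   `support_left`, `support_right`.  Zero rows when no junction pair
#'   reaches `min_support` or the sides share no common sequence.
#' @export
call_att <- function(evidence, phage, host, min_support = 2, window = 5,
                     flank = 20, max_core = 500) {
  host_seq <- if (inherits(host, "annotated_genome")) host$sequence else host
  phage_seq <- if (inherits(phage, "annotated_genome")) phage$sequence
               else phage
  empty <- data.frame(core = character(), core_len = integer(),
                      host_core_start = integer(),
                      phage_core_start = integer(), attL = character(),
                      attR = character(), support_left = integer(),
                      support_right = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("att_calls", "data.frame")
  lefts <- evidence[evidence$side == "left", , drop = FALSE]
  rights <- evidence[evidence$side == "right", , drop = FALSE]
  if (!nrow(lefts) || !nrow(rights)) return(empty)
  lefts$cl <- cluster_positions(lefts$host_junction, window)
  rights$cl <- cluster_positions(rights$host_junction, window)
  calls <- list()
  for (lc in unique(lefts$cl)) {
    lev <- lefts[lefts$cl == lc, , drop = FALSE]
    if (nrow(lev) < min_support) next
    lpos <- stats::median(lev$host_junction)
    for (rc in unique(rights$cl)) {
      rev_ <- rights[rights$cl == rc, , drop = FALSE]
      if (nrow(rev_) < min_support) next
      rpos <- stats::median(rev_$host_junction)
      sep <- lpos - rpos + 1L   # approximate core length
      if (sep < 1 || sep > max_core) next
      lcand <- vapply(lev$overlap[nzchar(lev$overlap)], trim_to_common,
                      character(1), host_seq, phage_seq)
      rcand <- vapply(rev_$overlap[nzchar(rev_$overlap)], trim_to_common,
                      character(1), host_seq, phage_seq)
      lcand <- lcand[nzchar(lcand)]; rcand <- rcand[nzchar(rcand)]
      common <- intersect(unique(lcand), unique(rcand))
      if (!length(common)) next   # sides disagree on the core
      support <- vapply(common, function(s)
        sum(lcand == s) + sum(rcand == s), numeric(1))
      ord <- order(-support, -nchar(common), common)
      core <- common[ord[1]]
      # host position: occurrence closest to the right-junction cluster
      occ <- gregexpr(core, host_seq, fixed = TRUE)[[1]]
      hpos <- occ[which.min(abs(occ - rpos))]
      pocc <- gregexpr(core, phage_seq, fixed = TRUE)[[1]]
      ppos <- pocc[1]
      cl_ <- nchar(core)
      attL <- paste0(
        substr(host_seq, max(1L, hpos - flank), hpos - 1L), core,
        substr(phage_seq, ppos + cl_,
               min(nchar(phage_seq), ppos + cl_ + flank - 1L)))
      attR <- paste0(
        substr(phage_seq, max(1L, ppos - flank), ppos - 1L), core,
        substr(host_seq, hpos + cl_,
               min(nchar(host_seq), hpos + cl_ + flank - 1L)))
      calls[[length(calls) + 1L]] <- data.frame(
        core = core, core_len = cl_, host_core_start = hpos,
        phage_core_start = ppos, attL = attL, attR = attR,
        support_left = nrow(lev), support_right = nrow(rev_),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty
  rownames(out) <- NULL
  class(out) <- c("att_calls", "data.frame")
  out
}

#' Write att calls as TSV plus attL/attR FASTA
#' @param calls an `att_calls` data.frame.
#' @param path output TSV; att sequences are written to `<path>.fasta`.
#' @return `path`, invisibly.
#' @export
write_att_calls <- function(calls, path) {
  utils::write.table(
    calls[, c("core", "core_len", "host_core_start", "phage_core_start",
              "support_left", "support_right")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(calls)) {
    seqs <- Biostrings::DNAStringSet(c(
      stats::setNames(calls$attL, sprintf("attL_%d", seq_len(nrow(calls)))),
      stats::setNames(calls$attR, sprintf("attR_%d", seq_len(nrow(calls))))))
    Biostrings::writeXStringSet(seqs, paste0(path, ".fasta"))
  }
  invisible(path)
}
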