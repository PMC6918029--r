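#' Writers and readers for standard sequence and table formats
#'
#' Thin wrappers around Biostrings for FASTA/FASTQ, plus TSV writers for
#' gene tables, truth labels, shared-gene matrices and recruitment
#' reports.  All human-readable coordinates are 1-based inclusive.
#'
#' @name io
NULL

#' @rdname io
#' @param genomes an [annotated_genome()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(
    stats::setNames(vapply(genomes, function(g) g$sequence, character(1)),
                    vapply(genomes, function(g) g$genome_id, character(1))))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname io
#' @export
write_protein_fasta <- function(genomes, path) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  prots <- genome_proteins(genomes)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prots), path)
  invisible(path)
}

#' @rdname io
#' @export
write_gene_table <- function(genomes, path) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  rows <- do.call(rbind, lapply(genomes, function(g) {
    if (!nrow(g$genes)) return(NULL)
    data.frame(genome_id = g$genome_id, gene_id = g$genes$gene_id,
               start = g$genes$start + 1L, end = g$genes$end,
               strand = g$genes$strand, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(genome_id = character(), gene_id = character(),
                       start = integer(), end = integer(),
                       strand = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param reads a `virome` data.frame (see [simulate_virome()]).
#' @param format "fasta" or "fastq" (uniform quality "I").
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  seqs <- Biostrings::DNAStringSet(
    stats::setNames(reads$sequence, reads$read_id))
  if (format == "fasta") {
    Biostrings::writeXStringSet(seqs, path)
  } else {
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
    Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  }
  invisible(path)
}

#' @rdname io
#' @export
write_truth_table <- function(reads, path) {
  utils::write.table(
    reads[, c("read_id", "truth_genome", "truth_group")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' Accepts wrapped and unwrapped FASTA records; the format is chosen by
#' file extension (`.fq`/`.fastq` read as FASTQ).
#'
#' @param path input file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq"
         else "fasta"
  s <- Biostrings::readBStringSet(path, format = fmt)
  stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
}

#' @rdname read_fasta
#' @return for `read_reads`, a data.frame with `read_id` and `sequence`.
#' @export
read_reads <- function(path) {
  s <- read_fasta(path)
  out <- data.frame(read_id = names(s), sequence = unname(s),
                    stringsAsFactors = FALSE)
  class(out) <- c("virome", "data.frame")
  out
}
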