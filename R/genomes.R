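#' Construct an annotated genome
#'
#' The basic unit of every analysis in this package: a single replicon with
#' an ordered table of protein-coding genes.  Coordinates are 0-based,
#' half-open internally; writers emit 1-based inclusive coordinates.
#'
#' @param genome_id character scalar identifier.
#' @param sequence nucleotide string over A/C/G/T.
#' @param genes data.frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open), `strand` ("+"/"-"), `protein` (amino-acid string).
#'   May have zero rows.
#' @param group optional group label (e.g. a phage group); required for
#'   recruitment focal genomes.
#' @param kind one of "phage", "host", "background_viral",
#'   "bacterial_decoy", "env_contig".
#' @param meta free-form list of generator metadata.
#' @return an object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, sequence, genes = empty_gene_table(),
                             group = NULL, kind = "phage", meta = list()) {
  kind <- match.arg(kind, c("phage", "host", "background_viral",
                            "bacterial_decoy", "env_contig"))
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            is.character(sequence), length(sequence) == 1L,
            is.data.frame(genes))
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  if (nrow(genes)) {
    if (any(genes$start < 0L) || any(genes$end > nchar(sequence)) ||
        any(genes$start >= genes$end))
      stop("gene coordinates out of range for genome '", genome_id, "'")
    if (anyDuplicated(genes$gene_id))
      stop("duplicate gene_id in genome '", genome_id, "'")
  }
  structure(list(genome_id = genome_id, sequence = sequence, genes = genes,
                 group = group, kind = kind, meta = meta),
            class = "annotated_genome")
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             strand = character(), protein = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s (%s%s): %s bp, %d genes, G+C %.3f\n",
              x$genome_id, x$kind,
              if (!is.null(x$group)) paste0(", group ", x$group) else "",
              format(nchar(x$sequence), big.mark = ","), nrow(x$genes),
              gc_fraction(x$sequence)))
  invisible(x)
}

#' Genome length in bp
#' @param g an `annotated_genome`.
#' @return integer length.
#' @export
genome_length <- function(g) nchar(g$sequence)

#' Extract a genome's proteins as a named vector
#'
#' Names follow the `genomeID|geneID` convention used throughout the
#' package (and in protein FASTA headers), so that every protein id is
#' genome-qualified.
#'
#' @param g an `annotated_genome`, or a list of them.
#' @return named character vector of amino-acid sequences.
#' @export
genome_proteins <- function(g) {
  if (inherits(g, "annotated_genome")) g <- list(g)
  out <- lapply(g, function(gg) {
    if (!nrow(gg$genes)) return(stats::setNames(character(), character()))
    stats::setNames(gg$genes$protein,
                    paste(gg$genome_id, gg$genes$gene_id, sep = "|"))
  })
  out <- unlist(unname(out)) # outer names must not pollute protein ids
  out %||% stats::setNames(character(), character())
}

# split "genome|gene" qualified ids
genome_of <- function(ids) sub("\\|.*$", "", ids)
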