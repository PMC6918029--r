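#' Call homologous gene pairs from protein hits
#'
#' Applies the homolog rule used throughout the comparative analysis:
#' amino-acid identity >= `min_identity`, alignment coverage >=
#' `min_coverage`, and E-value <= `max_evalue` (all thresholds inclusive).
#' Self-hits are excluded, pairs are unordered, and each pair keeps its
#' highest-bitscore supporting hit.
#'
#' @param hits hits data.frame with genome-qualified ids
#'   (`genomeID|geneID`).
#' @param min_identity minimum percent identity (default 30).
#' @param min_coverage minimum percent query coverage (default 50).
#' @param max_evalue maximum E-value (default 1e-3).
#' @return data.frame of class `homolog_pairs` with columns `gene_a`,
#'   `gene_b`, `genome_a`, `genome_b` and the supporting hit's `pident`,
#'   `qcovs`, `evalue`, `bitscore`.
#' @export
call_homologs <- function(hits, min_identity = 30, min_coverage = 50,
                          max_evalue = 1e-3) {
  keep <- hits$pident >= min_identity & hits$qcovs >= min_coverage &
    hits$evalue <= max_evalue & hits$qseqid != hits$sseqid
  h <- hits[keep, , drop = FALSE]
  if (!nrow(h)) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      genome_a = character(), genome_b = character(),
                      pident = numeric(), qcovs = numeric(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("homolog_pairs", "data.frame")
    return(out)
  }
  swap <- h$qseqid > h$sseqid
  ga <- ifelse(swap, h$sseqid, h$qseqid)
  gb <- ifelse(swap, h$qseqid, h$sseqid)
  ord <- order(ga, gb, -h$bitscore, h$evalue)
  h <- h[ord, , drop = FALSE]; ga <- ga[ord]; gb <- gb[ord]
  first <- !duplicated(paste(ga, gb, sep = "\r"))
  out <- data.frame(gene_a = ga[first], gene_b = gb[first],
                    genome_a = genome_of(ga[first]),
                    genome_b = genome_of(gb[first]),
                    pident = h$pident[first], qcovs = h$qcovs[first],
                    evalue = h$evalue[first], bitscore = h$bitscore[first],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("homolog_pairs", "data.frame")
  out
}

# gene ids of genome A having >= 1 homolog in genome B, given homolog pairs
genes_with_homolog <- function(id_a, id_b, pairs) {
  hit_a <- pairs$gene_a[pairs$genome_a == id_a & pairs$genome_b == id_b]
  hit_a2 <- pairs$gene_b[pairs$genome_b == id_a & pairs$genome_a == id_b]
  unique(c(hit_a, hit_a2))
}

#' Number of genes of A with a homolog in B
#'
#' Directional count: how many of A's genes have at least one homolog in
#' B under the calls in `pairs`.
#'
#' @param A,B [annotated_genome()] objects.
#' @param pairs homolog pairs from [call_homologs()].
#' @return integer count.
#' @export
shared_gene_count <- function(A, B, pairs) {
  length(genes_with_homolog(A$genome_id, B$genome_id, pairs))
}

#' Genome-by-genome shared-gene percentage matrix
#'
#' For each unordered genome pair the percentage of shared genes is the
#' larger of the two directional shared counts divided by the chosen
#' denominator (`min` = the smaller genome's gene count, the default;
#' `mean` = mean gene count; `query` = the row genome's count, which makes
#' the matrix asymmetric).  The diagonal is 100 for genomes with at least
#' one gene; genomes with zero genes get 0 rows/columns with a warning.
#'
#' @param genomes list of [annotated_genome()] objects.
#' @param pairs homolog pairs from [call_homologs()] computed all-vs-all.
#' @param denominator "min", "mean" or "query".
#' @return list of class `shared_gene_matrix` with elements `percent`
#'   (numeric matrix), `counts` (directional integer matrix, `counts[A, B]`
#'   = genes of A with a homolog in B), and `denominator`.
#' @export
shared_gene_matrix <- function(genomes, pairs,
                               denominator = c("min", "mean", "query")) {
  denominator <- match.arg(denominator)
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  ngenes <- vapply(genomes, function(g) nrow(g$genes), numeric(1))
  if (any(ngenes == 0))
    warning("genomes with 0 genes: ",
            paste(ids[ngenes == 0], collapse = ", "))
  n <- length(ids)
  counts <- matrix(0L, n, n, dimnames = list(ids, ids))
  pct <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      counts[i, j] <- length(genes_with_homolog(ids[i], ids[j], pairs))
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { pct[i, j] <- if (ngenes[i] > 0) 100 else 0; next }
      if (ngenes[i] == 0 || ngenes[j] == 0) next
      num <- max(counts[i, j], counts[j, i])
      den <- switch(denominator,
                    min = min(ngenes[i], ngenes[j]),
                    mean = mean(c(ngenes[i], ngenes[j])),
                    query = ngenes[i])
      if (denominator == "query") num <- counts[i, j]
      pct[i, j] <- 100 * num / den
    }
  }
  structure(list(percent = pct, counts = counts, denominator = denominator),
            class = "shared_gene_matrix")
}

#' Write a shared-gene matrix and its directional counts
#' @param x a `shared_gene_matrix`.
#' @param path output TSV for the percentage matrix; directional counts
#'   are written alongside as `<path>.counts.tsv`.
#' @return `path`, invisibly.
#' @export
write_shared_gene_matrix <- function(x, path) {
  utils::write.table(data.frame(genome_id = rownames(x$percent),
                                x$percent, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  ids <- rownames(x$counts)
  long <- expand.grid(A = ids, B = ids, stringsAsFactors = FALSE)
  long <- long[long$A != long$B, ]
  long$count <- x$counts[cbind(long$A, long$B)]
  utils::write.table(long, paste0(path, ".counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
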