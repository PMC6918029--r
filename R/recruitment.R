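#' Reference database for fragment recruitment
#'
#' Bundles the focal phage genomes (each with a group label), background
#' viral genomes and bacterial decoy genomes used by the reciprocal
#' best-hit recruitment pipeline.  Background and decoy entries exist only
#' to veto assignments: reads are never assigned to them.
#'
#' @param focal list of focal [annotated_genome()] objects; every focal
#'   genome must carry a non-empty `group`.
#' @param background list of background viral genomes.
#' @param decoys list of bacterial decoy genomes.
#' @return list of class `reference_db` with protein sets, genome-to-group
#'   and genome-to-role maps, and per-group mean genome size in kb
#'   (arithmetic mean over the group's focal genomes).
#' @export
reference_db <- function(focal, background = list(), decoys = list()) {
  if (inherits(focal, "annotated_genome")) focal <- list(focal)
  groups <- vapply(focal, function(g) g$group %||% NA_character_,
                   character(1))
  if (anyNA(groups) || any(!nzchar(groups)))
    stop("every focal genome must have a group label")
  ids <- c(vapply(focal, function(g) g$genome_id, character(1)),
           vapply(background, function(g) g$genome_id, character(1)),
           vapply(decoys, function(g) g$genome_id, character(1)))
  if (anyDuplicated(ids)) stop("duplicate genome ids in reference db")
  focal_ids <- ids[seq_along(focal)]
  kb <- vapply(focal, genome_length, numeric(1)) / 1000
  mean_kb <- tapply(kb, groups, mean)
  structure(list(
    focal = focal, background = background, decoys = decoys,
    focal_proteins = genome_proteins(focal),
    all_proteins = genome_proteins(c(focal, background, decoys)),
    group_of = stats::setNames(groups, focal_ids),
    focal_ids = focal_ids,
    mean_genome_kb = stats::setNames(as.numeric(mean_kb), names(mean_kb))),
    class = "reference_db")
}

best_hit_per_read <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Screen virome reads against the focal proteins
#'
#' Recruitment step 1: translated search of every read against the focal
#' phage proteins; reads with at least one hit passing the E-value and
#' bitscore cutoffs (both inclusive) become candidates for the reciprocal
#' step.
#'
#' @param reads a `virome` data.frame or named character vector of reads.
#' @param db a [reference_db()].
#' @param max_evalue,min_bitscore screening cutoffs (defaults 1e-3 / 40).
#' @param model a [scoring_model()].
#' @param prefilter use the k-mer prefilter (default TRUE).
#' @return data.frame with one row per read: `read_id`, `stage`
#'   ("candidate" or "screened_out") and `screen_bitscore` (best focal
#'   bitscore, NA when screened out).
#' @export
screen_reads <- function(reads, db, max_evalue = 1e-3, min_bitscore = 40,
                         model = scoring_model(), prefilter = TRUE) {
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  hits <- homology_search(reads, db$focal_proteins, model = model,
                          mode = "translated", max_evalue = max_evalue,
                          min_bitscore = min_bitscore, prefilter = prefilter)
  best <- best_hit_per_read(hits)
  m <- match(reads$read_id, best$qseqid)
  data.frame(read_id = reads$read_id,
             stage = ifelse(is.na(m), "screened_out", "candidate"),
             screen_bitscore = best$bitscore[m],
             stringsAsFactors = FALSE)
}

#' Reciprocal best-hit assignment of screened reads
#'
#' Recruitment steps 2-3: every candidate read is searched against the
#' combined database (focal + background viral + bacterial decoy
#' proteins); its best hit is the highest-bitscore hit (ties broken by
#' lower E-value, then lexicographic subject id).  The read is assigned to
#' focal genome G iff its best combined hit lies on G; otherwise it is
#' `reciprocal_rejected`.
#'
#' @param reads the same reads passed to [screen_reads()].
#' @param screened result of [screen_reads()].
#' @param db a [reference_db()].
#' @param max_evalue,min_bitscore hit thresholds for the combined search
#'   (defaults 1e-3 / 40).
#' @param model a [scoring_model()].
#' @param prefilter use the k-mer prefilter.
#' @return data.frame of class `read_assignments`: `read_id`, `stage`
#'   ("screened_out", "reciprocal_rejected" or "assigned"),
#'   `assigned_genome`, `assigned_group`, `best_bitscore`.
#' @export
reciprocal_assign <- function(reads, screened, db, max_evalue = 1e-3,
                              min_bitscore = 40, model = scoring_model(),
                              prefilter = TRUE) {
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  cand <- reads[reads$read_id %in%
                  screened$read_id[screened$stage == "candidate"], ,
                drop = FALSE]
  out <- data.frame(read_id = reads$read_id, stage = "screened_out",
                    assigned_genome = NA_character_,
                    assigned_group = NA_character_,
                    best_bitscore = NA_real_, stringsAsFactors = FALSE)
  if (nrow(cand)) {
    hits <- homology_search(cand, db$all_proteins, model = model,
                            mode = "translated", max_evalue = max_evalue,
                            min_bitscore = min_bitscore,
                            prefilter = prefilter)
    best <- best_hit_per_read(hits)
    best$genome <- genome_of(best$sseqid)
    m <- match(out$read_id, best$qseqid)
    is_cand <- out$read_id %in% cand$read_id
    hit_genome <- best$genome[m]
    assigned <- !is.na(hit_genome) & hit_genome %in% db$focal_ids
    out$stage[is_cand] <- "reciprocal_rejected"
    out$stage[assigned] <- "assigned"
    out$assigned_genome[assigned] <- hit_genome[assigned]
    out$assigned_group[assigned] <-
      unname(db$group_of[hit_genome[assigned]])
    out$best_bitscore <- best$bitscore[m]
  }
  class(out) <- c("read_assignments", "data.frame")
  out
}

#' Single-pass best-hit assignment (large-virome mode)
#'
#' Alternative to the reciprocal pipeline for very large viromes: reads
#' are recruited directly onto the focal proteins with a strict E-value
#' cutoff, and a read hitting more than one genome is associated with the
#' genome providing the highest bitscore.
#'
#' @param reads a `virome` data.frame or named character vector.
#' @param db a [reference_db()].
#' @param max_evalue strict cutoff (default 1e-10, inclusive).
#' @param model a [scoring_model()].
#' @param prefilter use the k-mer prefilter.
#' @return `read_assignments` data.frame as in [reciprocal_assign()],
#'   with stage "assigned" or "screened_out".
#' @export
gov_assign <- function(reads, db, max_evalue = 1e-10,
                       model = scoring_model(), prefilter = TRUE) {
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  hits <- homology_search(reads, db$focal_proteins, model = model,
                          mode = "translated", max_evalue = max_evalue,
                          prefilter = prefilter)
  best <- best_hit_per_read(hits)
  m <- match(reads$read_id, best$qseqid)
  genome <- genome_of(best$sseqid[m])
  out <- data.frame(read_id = reads$read_id,
                    stage = ifelse(is.na(m), "screened_out", "assigned"),
                    assigned_genome = genome,
                    assigned_group = unname(db$group_of[genome]),
                    best_bitscore = best$bitscore[m],
                    stringsAsFactors = FALSE)
  class(out) <- c("read_assignments", "data.frame")
  out
}

#' Group-level RPKM abundances
#'
#' For each phage group: the number of recruited (assigned) reads divided
#' by the group's mean genome size in kilobases and by the virome size in
#' millions of reads.  A read assigned to any genome of a group counts
#' once for that group.  Groups with zero recruited reads are reported
#' with RPKM 0.
#'
#' @param assignments `read_assignments` from [reciprocal_assign()] or
#'   [gov_assign()].
#' @param db a [reference_db()].
#' @param virome_total_reads total reads in the virome (>= 1).
#' @param virome_id label for the output rows.
#' @return data.frame with `virome`, `group`, `recruited_read_count`,
#'   `mean_genome_kb`, `virome_total_reads`, `rpkm`.
#' @export
rpkm <- function(assignments, db, virome_total_reads,
                 virome_id = "virome") {
  if (virome_total_reads < 1) stop("virome_total_reads must be >= 1")
  if (any(db$mean_genome_kb == 0)) stop("group with mean genome size 0")
  groups <- sort(names(db$mean_genome_kb))
  counts <- table(factor(
    assignments$assigned_group[assignments$stage == "assigned"],
    levels = groups))
  out <- data.frame(virome = virome_id, group = groups,
                    recruited_read_count = as.integer(counts),
                    mean_genome_kb = unname(db$mean_genome_kb[groups]),
                    virome_total_reads = virome_total_reads,
                    stringsAsFactors = FALSE)
  out$rpkm <- out$recruited_read_count / out$mean_genome_kb /
    (out$virome_total_reads / 1e6)
  out
}

#' Run the full reciprocal recruitment pipeline on one virome
#'
#' Convenience wrapper: screen, reciprocally assign, and compute group
#' RPKM.
#'
#' @inheritParams screen_reads
#' @param virome_id label used in the abundance table.
#' @param ... passed to [screen_reads()] and [reciprocal_assign()].
#' @return list with `assignments` and `abundance`.
#' @export
recruit_reciprocal <- function(reads, db, virome_id = "virome", ...) {
  screened <- screen_reads(reads, db, ...)
  assignments <- reciprocal_assign(reads, screened, db, ...)
  abundance <- rpkm(assignments, db, virome_total_reads = nrow(assignments),
                    virome_id = virome_id)
  list(assignments = assignments, abundance = abundance)
}

#' Combine per-virome abundance tables into a long-format report
#'
#' @param abundances list of abundance data.frames from [rpkm()].
#' @return single data.frame ordered by virome then group.
#' @export
recruitment_report <- function(abundances) {
  if (is.data.frame(abundances)) abundances <- list(abundances)
  out <- do.call(rbind, abundances)
  if (is.null(out))
    out <- data.frame(virome = character(), group = character(),
                      recruited_read_count = integer(),
                      mean_genome_kb = numeric(),
                      virome_total_reads = numeric(), rpkm = numeric(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$virome, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
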