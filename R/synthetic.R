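#' Synthetic phage/host genome and virome generator
#'
#' These functions produce annotated genomes, diverged genome families,
#' truth-labeled viromes and planted lysogens so that every analysis stage
#' (homology search, comparative genomics, network clustering, fragment
#' recruitment, integration-site detection) can be exercised end to end on
#' data with known ground truth.  All operations are deterministic given
#' their `seed`.
#'
#' @name synthetic-data
NULL

# Synonymous codon choice weighted toward a target G+C: each codon is
# weighted as if its bases were drawn iid with P(G or C) = gc, restricted
# to the codons encoding the required residue.
codon_sampler <- function(gc) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  lapply(by_aa, function(codons) {
    ngc <- vapply(strsplit(codons, ""), function(b) sum(b %in% c("G", "C")),
                  numeric(1))
    w <- gc^ngc * (1 - gc)^(3 - ngc)
    list(codons = codons, w = w / sum(w))
  })
}

back_translate <- function(protein, sampler) {
  aa <- strsplit(protein, "")[[1]]
  out <- character(length(aa))
  for (a in unique(aa)) {
    cs <- sampler[[a]]
    if (is.null(cs)) stop("cannot back-translate residue '", a, "'")
    idx <- which(aa == a)
    out[idx] <- sample(cs$codons, length(idx), replace = TRUE, prob = cs$w)
  }
  paste(out, collapse = "")
}

assemble_genome <- function(genome_id, proteins, strands, gc, intergenic_len,
                            group, kind, sampler = codon_sampler(gc)) {
  n <- length(proteins)
  stops <- sampler[["*"]]
  pieces <- character(2L * n + 1L)
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    ig <- random_dna(intergenic_len, gc)
    pieces[2L * i - 1L] <- ig
    pos <- pos + nchar(ig)
    cds <- paste0(back_translate(proteins[i], sampler),
                  sample(stops$codons, 1L, prob = stops$w))
    if (strands[i] == "-") cds <- revcomp(cds)
    pieces[2L * i] <- cds
    starts[i] <- pos
    pos <- pos + nchar(cds)
    ends[i] <- pos
  }
  pieces[2L * n + 1L] <- random_dna(intergenic_len, gc)
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                      start = starts, end = ends, strand = strands,
                      protein = unname(proteins), stringsAsFactors = FALSE)
  annotated_genome(genome_id, paste(pieces, collapse = ""), genes,
                   group = group, kind = kind,
                   meta = list(gc_target = gc, intergenic_len = intergenic_len))
}

#' Generate a random annotated genome
#'
#' Genes are random proteins (uniform over the 20 residues, leading
#' methionine) back-translated with synonymous-codon weights tuned toward
#' the target G+C; intergenic spacers are sampled with the same base
#' composition.  Defaults emulate a gene-dense ~40-60 kb phage genome.
#'
#' @param n_genes number of genes (>= 1).
#' @param mean_gene_len mean protein length in amino acids.
#' @param gc target G+C fraction, 0 < gc < 1.
#' @param intergenic_len spacer length in bp between consecutive genes.
#' @param seed integer seed; the function is a pure function of its
#'   arguments and this seed.
#' @param genome_id,group,kind identity fields of the result.
#' @return an [annotated_genome()].
#' @export
generate_genome <- function(n_genes = 60, mean_gene_len = 200, gc = 0.45,
                            intergenic_len = 30, seed = 1,
                            genome_id = sprintf("synth%06d", seed),
                            group = NULL, kind = "phage") {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (mean_gene_len <= 0 || intergenic_len < 0)
    stop("lengths must be positive")
  withr::with_seed(seed, {
    lens <- pmax(50L, round(rnorm(n_genes, mean_gene_len, 0.25 * mean_gene_len)))
    proteins <- vapply(lens, random_protein, character(1))
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    assemble_genome(genome_id, proteins, strands, gc, intergenic_len,
                    group, kind)
  })
}

mutate_protein <- function(p, rate) {
  if (rate <= 0) return(p)
  aa <- strsplit(p, "")[[1]]
  hit <- runif(length(aa)) < rate
  if (any(hit)) {
    repl <- vapply(aa[hit], function(a) sample(setdiff(AA20, a), 1L),
                   character(1))
    aa[hit] <- repl
  }
  paste(aa, collapse = "")
}

#' Derive a diverged genome from a parent
#'
#' Emulates divergence of related phages from a common ancestor: each
#' retained protein is mutated at a per-site amino-acid rate (mutated sites
#' change to a uniformly chosen different residue, so expected identity to
#' the parent is `1 - aa_divergence`), genes are lost independently, and
#' novel genes are appended.  Retained CDSs are re-back-translated, so
#' synonymous sites also diverge.
#'
#' @param parent an [annotated_genome()].
#' @param aa_divergence per-site amino-acid substitution rate in `[0, 1)`.
#' @param gene_loss probability that each parent gene is dropped.
#' @param gene_gain number of novel genes appended.
#' @param seed integer seed.
#' @param genome_id,group,kind identity fields (group defaults to parent's).
#' @param gc target G+C; defaults to the parent's realized G+C.
#' @return an [annotated_genome()].
#' @export
evolve_genome <- function(parent, aa_divergence, gene_loss = 0, gene_gain = 0,
                          seed = 1,
                          genome_id = paste0(parent$genome_id, "_d", seed),
                          group = parent$group, kind = parent$kind,
                          gc = NULL) {
  if (aa_divergence < 0 || aa_divergence >= 1)
    stop("aa_divergence must be in [0, 1)")
  gc <- gc %||% gc_fraction(parent$sequence)
  ig <- parent$meta$intergenic_len %||% 30L
  withr::with_seed(seed, {
    keep <- runif(nrow(parent$genes)) >= gene_loss
    proteins <- vapply(parent$genes$protein[keep], mutate_protein,
                       character(1), rate = aa_divergence)
    strands <- parent$genes$strand[keep]
    if (gene_gain > 0) {
      mean_len <- if (nrow(parent$genes))
        mean(nchar(parent$genes$protein)) else 200
      novel <- vapply(pmax(50L, round(rnorm(gene_gain, mean_len,
                                            0.25 * mean_len))),
                      random_protein, character(1))
      proteins <- c(proteins, novel)
      strands <- c(strands, sample(c("+", "-"), gene_gain, replace = TRUE))
    }
    if (!length(proteins)) {
      return(annotated_genome(genome_id, random_dna(max(ig, 1L), gc),
                              group = group, kind = kind,
                              meta = list(gc_target = gc, intergenic_len = ig)))
    }
    assemble_genome(genome_id, proteins, strands, gc, ig, group, kind)
  })
}

#' Generate a family of related genomes
#'
#' Convenience wrapper producing an unobserved common ancestor and
#' `n_members` observed genomes diverged from it, mimicking a phage group
#' (approximately genus-level viral cluster).
#'
#' @param n_members number of observed family members.
#' @param divergence per-site amino-acid divergence of each member from the
#'   ancestor.
#' @param group group label applied to every member.
#' @param seed integer seed.
#' @param gene_loss,gene_gain per-member gene turnover (see
#'   [evolve_genome()]).
#' @param ... passed to [generate_genome()] for the ancestor.
#' @return list with elements `ancestor` and `members` (list of genomes).
#' @export
make_genome_family <- function(n_members = 3, divergence = 0.2, group = "grp",
                               seed = 1, gene_loss = 0, gene_gain = 0, ...) {
  anc <- generate_genome(seed = seed, group = group,
                         genome_id = paste0(group, "_anc"), ...)
  member_seeds <- withr::with_seed(seed, sample.int(2^30, n_members))
  members <- lapply(seq_len(n_members), function(i) {
    evolve_genome(anc, divergence, gene_loss = gene_loss,
                  gene_gain = gene_gain, seed = member_seeds[i],
                  genome_id = sprintf("%s_m%d", group, i))
  })
  list(ancestor = anc, members = members)
}

#' Simulate a truth-labeled virome
#'
#' Reads are drawn from a weighted mixture of source genomes (uniform start
#' position and strand, substitution-only errors), and each read carries
#' the identity and group of its source genome as truth labels.  Genomes
#' are treated as linear: no reads are produced across the origin, and all
#' reads have full length `read_len`.
#'
#' @param sources list of [annotated_genome()] objects.
#' @param weights non-negative sampling weights, one per source (at least
#'   one positive); normalized internally.
#' @param n_reads number of reads.
#' @param read_len read length in bp; must not exceed any source length.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return data.frame of class `virome` with columns `read_id`, `sequence`,
#'   `truth_genome`, `truth_group`.
#' @export
simulate_virome <- function(sources, weights, n_reads, read_len = 150,
                            error_rate = 0.005, seed = 1) {
  if (inherits(sources, "annotated_genome")) sources <- list(sources)
  if (length(weights) != length(sources))
    stop("weights must match sources")
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative with at least one positive")
  lens <- vapply(sources, genome_length, numeric(1))
  if (any(read_len > lens))
    stop("read_len exceeds a source genome length")
  nt <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    counts <- as.vector(rmultinom(1, n_reads, weights / sum(weights)))
    src_idx <- rep(seq_along(sources), counts)
    src_idx <- sample(src_idx) # interleave sources
    seqs <- character(n_reads)
    for (s in unique(src_idx)) {
      idx <- which(src_idx == s)
      g <- sources[[s]]
      starts <- sample.int(genome_length(g) - read_len + 1L, length(idx),
                           replace = TRUE)
      seqs[idx] <- substring(g$sequence, starts, starts + read_len - 1L)
    }
    minus <- runif(n_reads) < 0.5
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    if (error_rate > 0) {
      nerr <- rbinom(n_reads, read_len, error_rate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(read_len, nerr[i])
        ch <- strsplit(seqs[i], "")[[1]]
        ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(nt, b), 1L),
                          character(1))
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    ids <- vapply(sources, function(g) g$genome_id, character(1))
    grps <- vapply(sources, function(g) g$group %||% NA_character_,
                   character(1))
    out <- data.frame(read_id = sprintf("read_%06d", seq_len(n_reads)),
                      sequence = seqs,
                      truth_genome = ids[src_idx],
                      truth_group = grps[src_idx],
                      stringsAsFactors = FALSE)
    class(out) <- c("virome", "data.frame")
    out
  })
}

#' Plant a site-specific prophage integration
#'
#' Emulates integrase-mediated integration at an attB/attP pair sharing an
#' identical core sequence.  The core is read from the host at `host_site`
#' and inserted into the phage at a (seeded) attP position, producing the
#' att-bearing phage reference; the lysogen is assembled as host-left +
#' core + phage (circularly permuted at attP) + core + host-right, so the
#' core flanks the prophage at attL and attR and the lysogen length equals
#' host length + original phage length + core length.
#' The bases immediately flanking the planted core are forced to differ
#' between host and phage, making the planted core the maximal identical
#' stretch (and hence the unique correct answer for detection).
#'
#' @param host,phage [annotated_genome()] objects.
#' @param core_len core length in bp (>= 1).
#' @param host_site 0-based host coordinate of the core (attB); random if
#'   `NULL`.
#' @param attP 0-based phage coordinate at which the core is written;
#'   random if `NULL`.
#' @param seed integer seed.
#' @return list of class `integration_truth` with fields `host_id`,
#'   `phage_id`, `core`, `host_core_start`, `phage_core_start`, `phage`
#'   (the att-bearing phage genome used as reference), `lysogen`, and
#'   `ambiguous` (TRUE when the core is not unique in host or phage).
#' @export
plant_integration <- function(host, phage, core_len = 30, host_site = NULL,
                              attP = NULL, seed = 1) {
  if (core_len < 1) stop("core_len must be >= 1")
  hl <- genome_length(host); pl <- genome_length(phage)
  withr::with_seed(seed, {
    if (is.null(host_site))
      host_site <- sample.int(hl - core_len - 200L, 1L) + 100L
    if (host_site < 1 || host_site + core_len > hl)
      stop("host_site + core_len exceeds host length")
    if (is.null(attP)) attP <- sample.int(pl - core_len - 200L, 1L) + 100L
    core <- substr(host$sequence, host_site + 1L, host_site + core_len)
    # att-bearing phage: insert the core at attP so that, like a real
    # temperate phage, the phage reference itself carries the att core
    pseq <- paste0(substr(phage$sequence, 1L, attP), core,
                   substr(phage$sequence, attP + 1L, pl))
    # force a mismatch at each core boundary so the planted core is maximal
    fix_base <- function(seq, pos1, avoid) {
      b <- substr(seq, pos1, pos1)
      if (b == avoid) {
        substr(seq, pos1, pos1) <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }
      seq
    }
    if (attP >= 1 && host_site >= 1)
      pseq <- fix_base(pseq, attP, substr(host$sequence, host_site, host_site))
    if (attP + core_len < nchar(pseq) && host_site + core_len < hl)
      pseq <- fix_base(pseq, attP + core_len + 1L,
                       substr(host$sequence, host_site + core_len + 1L,
                              host_site + core_len + 1L))
    phage_att <- annotated_genome(phage$genome_id, pseq,
                                  group = phage$group, kind = phage$kind,
                                  meta = phage$meta)
    count_occ <- function(hay, needle) {
      m <- gregexpr(needle, hay, fixed = TRUE)[[1]]
      if (m[1] == -1L) 0L else length(m)
    }
    ambiguous <- count_occ(host$sequence, core) != 1L ||
      count_occ(pseq, core) != 1L
    lys_seq <- paste0(
      substr(host$sequence, 1L, host_site + core_len),           # host left + core (attL)
      substr(pseq, attP + core_len + 1L, nchar(pseq)),           # phage after attP
      substr(pseq, 1L, attP),                                    # phage up to attP
      core,                                                      # attR core copy
      substr(host$sequence, host_site + core_len + 1L, hl))      # host right
    lysogen <- annotated_genome(paste0(host$genome_id, "_lysogen"), lys_seq,
                                kind = "host",
                                meta = list(host_id = host$genome_id,
                                            phage_id = phage$genome_id))
    structure(list(host_id = host$genome_id, phage_id = phage$genome_id,
                   core = core, host_core_start = host_site,
                   phage_core_start = attP, phage = phage_att,
                   lysogen = lysogen, ambiguous = ambiguous),
              class = "integration_truth")
  })
}
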