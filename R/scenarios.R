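#' Synthetic recruitment scenario with known group abundances
#'
#' Builds a complete, truth-labeled fragment-recruitment experiment: three
#' unrelated phage groups (two genomes each, diverged from a common
#' ancestor per group), a bacterial host whose genome donates a few
#' diverged auxiliary-metabolic-like genes (AMGs) to every phage group,
#' unrelated background viral genomes, and a virome mixing the phage
#' groups at the given genome-copy abundances plus a fraction of
#' host-derived reads.
#'
#' Because the phage groups are generated independently, between-group
#' protein identity is at the random-protein baseline (<40%); the
#' host-derived AMG copies are the only protein-level bridge between host
#' and phages, which is exactly what makes the reciprocal best-hit step
#' necessary: host reads from AMG source genes pass the screening step
#' but are vetoed by their exact best hit on the bacterial decoy.
#'
#' Read sampling weights are proportional to abundance x genome length,
#' so group RPKM (reads / mean genome kb / million reads) is an unbiased
#' estimate of relative genome-copy abundance.
#'
#' @param n_reads virome size (default 50000).
#' @param abundances relative genome-copy abundances of the three groups.
#' @param host_read_fraction fraction of virome reads drawn from the host
#'   genome (cellular contamination of the viral fraction).
#' @param group_divergence per-site amino-acid divergence of each group
#'   member from its ancestor.
#' @param amg_divergence divergence of each group's AMG copies from the
#'   host source genes.
#' @param n_amg number of host genes copied into each group.
#' @param read_len,error_rate read simulation parameters.
#' @param seed integer seed controlling every random choice.
#' @return list with `db` (a [reference_db()]), `reads` (a `virome`),
#'   `abundances` (named true relative abundances), `host`, `groups`
#'   (list of genome lists).
#' @export
make_recruitment_scenario <- function(n_reads = 50000,
                                      abundances = c(grpA = 5, grpB = 3,
                                                     grpC = 2),
                                      host_read_fraction = 0.30,
                                      group_divergence = 0.15,
                                      amg_divergence = 0.25,
                                      n_amg = 3,
                                      read_len = 150, error_rate = 0.005,
                                      seed = 1) {
  group_names <- names(abundances)
  withr::with_seed(seed, {
    sub_seeds <- sample.int(1e6, 20 + 10 * length(abundances))
  })
  host <- generate_genome(n_genes = 100, mean_gene_len = 200, gc = 0.50,
                          intergenic_len = 40, seed = sub_seeds[1],
                          genome_id = "hostA", kind = "bacterial_decoy")
  background <- lapply(1:2, function(i)
    generate_genome(n_genes = 60, mean_gene_len = 200, gc = 0.45,
                    seed = sub_seeds[1 + i],
                    genome_id = paste0("bgvir", i), kind = "background_viral"))
  decoy2 <- generate_genome(n_genes = 80, mean_gene_len = 200, gc = 0.55,
                            seed = sub_seeds[4], genome_id = "decoyB",
                            kind = "bacterial_decoy")
  groups <- list()
  for (gi in seq_along(group_names)) {
    gname <- group_names[gi]
    base <- sub_seeds[4 + 3 * gi]
    anc <- generate_genome(n_genes = 60, mean_gene_len = 200, gc = 0.45,
                           seed = base, genome_id = paste0(gname, "_anc"),
                           group = gname)
    # graft diverged host genes (AMG-like) onto the ancestor
    anc2 <- withr::with_seed(base + 1L, {
      amg <- vapply(host$genes$protein[seq_len(n_amg)], mutate_protein,
                    character(1), rate = amg_divergence)
      assemble_genome(anc$genome_id,
                      c(anc$genes$protein, unname(amg)),
                      c(anc$genes$strand,
                        sample(c("+", "-"), n_amg, replace = TRUE)),
                      gc = 0.45, intergenic_len = 30,
                      group = gname, kind = "phage")
    })
    members <- lapply(1:2, function(mi)
      evolve_genome(anc2, group_divergence, seed = base + 1L + mi,
                    genome_id = sprintf("%s_m%d", gname, mi)))
    groups[[gname]] <- members
  }
  focal <- unlist(groups, recursive = FALSE)
  db <- reference_db(focal, background = background,
                     decoys = list(host, decoy2))
  # genome-level weights: abundance x length for phages; host weight set
  # so that host reads make up host_read_fraction of the virome
  w_focal <- unlist(lapply(seq_along(group_names), function(gi)
    rep(abundances[gi], 2) *
      vapply(groups[[gi]], genome_length, numeric(1))))
  w_host <- host_read_fraction / (1 - host_read_fraction) * sum(w_focal)
  sources <- c(focal, list(host))
  weights <- c(w_focal, w_host)
  reads <- simulate_virome(sources, weights, n_reads = n_reads,
                           read_len = read_len, error_rate = error_rate,
                           seed = sub_seeds[20])
  list(db = db, reads = reads,
       abundances = abundances / sum(abundances),
       host = host, groups = groups)
}

#' Planted-integration recovery experiment
#'
#' Repeatedly plants a site-specific integration with a random core length
#' (uniform over `core_range`), sequences the synthetic lysogen to the
#' requested depth, and runs the hybrid-read detection and att-calling
#' pipeline, scoring whether the planted core was recovered exactly.
#'
#' @param n_integrations number of independent plantings.
#' @param error_rate per-base read substitution rate.
#' @param core_range integer range of core lengths.
#' @param depth mean read coverage of the lysogen.
#' @param read_len read length in bp.
#' @param host_genes,phage_genes gene counts of the synthetic host region
#'   and phage.
#' @param seed integer seed.
#' @return data.frame with one row per planting: `core_len`, `n_hybrid`,
#'   `n_calls`, `recovered` (exact core match), `ambiguous`.
#' @export
att_recovery_experiment <- function(n_integrations = 20, error_rate = 0,
                                    core_range = c(10, 50), depth = 20,
                                    read_len = 150, host_genes = 15,
                                    phage_genes = 25, seed = 1) {
  seeds <- withr::with_seed(seed, {
    list(s = sample.int(1e8, 4 * n_integrations),
         cores = sample(seq(core_range[1], core_range[2]),
                        n_integrations, replace = TRUE))
  })
  out <- vector("list", n_integrations)
  for (i in seq_len(n_integrations)) {
    s <- seeds$s[(4 * i - 3):(4 * i)]
    host <- generate_genome(n_genes = host_genes, mean_gene_len = 150,
                            gc = 0.50, seed = s[1], genome_id = "host",
                            kind = "host")
    phage <- generate_genome(n_genes = phage_genes, mean_gene_len = 150,
                             gc = 0.45, seed = s[2], genome_id = "phage")
    tr <- plant_integration(host, phage, core_len = seeds$cores[i],
                            seed = s[3])
    reads <- simulate_virome(
      list(tr$lysogen), 1,
      n_reads = round(depth * genome_length(tr$lysogen) / read_len),
      read_len = read_len, error_rate = error_rate, seed = s[4])
    ev <- find_hybrid_reads(reads, tr$phage, host)
    calls <- call_att(ev, tr$phage, host)
    out[[i]] <- data.frame(
      core_len = seeds$cores[i], n_hybrid = nrow(ev),
      n_calls = nrow(calls),
      recovered = nrow(calls) > 0 && any(calls$core == tr$core),
      ambiguous = tr$ambiguous)
  }
  do.call(rbind, out)
}
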