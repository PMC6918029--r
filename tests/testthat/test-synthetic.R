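test_that("generate_genome honours its contract", {
  g <- generate_genome(n_genes = 30, mean_gene_len = 120, seed = 7)
  expect_s3_class(g, "annotated_genome")
  expect_equal(nrow(g$genes), 30)
  expect_true(all(diff(g$genes$start) > 0))
  expect_true(all(g$genes$start >= 0 & g$genes$end <= genome_length(g)))
  expect_true(all((g$genes$end - g$genes$start) %% 3 == 0))
  # proteins are the strand-adjusted translations of their CDS (stop removed)
  for (i in c(1, 15, 30)) {
    gn <- g$genes[i, ]
    cds <- substr(g$sequence, gn$start + 1, gn$end)
    expect_identical(phagenomics:::translate_cds(cds, gn$strand), gn$protein)
  }
  expect_identical(generate_genome(n_genes = 30, seed = 9),
                   generate_genome(n_genes = 30, seed = 9))
  expect_error(generate_genome(n_genes = 0), "n_genes")
  expect_error(generate_genome(gc = 1.2), "gc")
  expect_error(generate_genome(mean_gene_len = -5), "positive")
})

test_that("realized G+C tracks the target within 0.02 on ~50 kb genomes", {
  gcs <- vapply(1:8, function(s)
    gc_fraction(generate_genome(n_genes = 75, mean_gene_len = 200,
                                gc = 0.45, seed = 700 + s)$sequence),
    numeric(1))
  expect_true(all(abs(gcs - 0.45) <= 0.02))
})

test_that("evolve_genome: identity case, divergence calibration, loss", {
  g <- small_genome()
  same <- evolve_genome(g, 0, gene_loss = 0, gene_gain = 0, seed = 5)
  expect_identical(same$genes$protein, g$genes$protein)

  idents <- vapply(1:10, function(s) {
    ch <- evolve_genome(g, 0.3, seed = 900 + s)
    mean(mapply(function(p, q) {
      a <- strsplit(p, "")[[1]]; b <- strsplit(q, "")[[1]]
      mean(a == b)
    }, g$genes$protein, ch$genes$protein))
  }, numeric(1))
  expect_true(abs(mean(idents) * 100 - 70) <= 3)

  none <- evolve_genome(g, 0.1, gene_loss = 1, gene_gain = 0, seed = 6)
  expect_equal(nrow(none$genes), 0)
  gained <- evolve_genome(g, 0.1, gene_loss = 0, gene_gain = 4, seed = 6)
  expect_equal(nrow(gained$genes), nrow(g$genes) + 4)
  expect_error(evolve_genome(g, 1.0), "aa_divergence")
})

test_that("simulate_virome reads are faithful and truth-labeled", {
  g <- small_genome()
  reads <- simulate_virome(list(g), 1, n_reads = 150, read_len = 100,
                           error_rate = 0, seed = 21)
  expect_equal(nrow(reads), 150)
  expect_true(all(reads$truth_genome == g$genome_id))
  expect_true(all(reads$truth_group == "grpS"))
  # error-free reads are exact substrings of the genome or its rc
  rcg <- revcomp(g$sequence)
  ok <- vapply(reads$sequence, function(s)
    grepl(s, g$sequence, fixed = TRUE) || grepl(s, rcg, fixed = TRUE),
    logical(1))
  expect_true(all(ok))
  expect_identical(reads,
                   simulate_virome(list(g), 1, n_reads = 150,
                                   read_len = 100, error_rate = 0,
                                   seed = 21))
})

test_that("virome mixture weights are respected (binomial bound)", {
  g1 <- small_genome()
  g2 <- generate_genome(n_genes = 12, seed = 402, genome_id = "gsmall2",
                        group = "grpT")
  reads <- simulate_virome(list(g1, g2), c(1, 1), n_reads = 10000,
                           read_len = 120, error_rate = 0, seed = 31)
  n1 <- sum(reads$truth_genome == g1$genome_id)
  sigma <- sqrt(10000 * 0.25)
  expect_lt(abs(n1 - 5000), 3 * sigma)
  # truth_group always matches the group of truth_genome
  expect_true(all(reads$truth_group[reads$truth_genome == "gsmall"] == "grpS"))
  expect_true(all(reads$truth_group[reads$truth_genome == "gsmall2"] == "grpT"))
  expect_error(simulate_virome(list(g1), 0, n_reads = 10), "weights")
  expect_error(simulate_virome(list(g1), 1, n_reads = 10, read_len = 1e6),
               "read_len")
})

test_that("plant_integration builds a conservative, core-duplicated lysogen", {
  host <- generate_genome(n_genes = 15, seed = 601, genome_id = "h1",
                          kind = "host")
  phage <- generate_genome(n_genes = 20, seed = 602, genome_id = "p1")
  tr <- plant_integration(host, phage, core_len = 20, seed = 603)
  expect_s3_class(tr, "integration_truth")
  expect_equal(genome_length(tr$lysogen),
               genome_length(host) + genome_length(phage) + 20)
  expect_false(tr$ambiguous)
  occ <- gregexpr(tr$core, tr$lysogen$sequence, fixed = TRUE)[[1]]
  expect_length(occ, 2)
  # core is present in both references at the recorded positions
  expect_identical(substr(host$sequence, tr$host_core_start + 1,
                          tr$host_core_start + 20), tr$core)
  expect_identical(substr(tr$phage$sequence, tr$phage_core_start + 1,
                          tr$phage_core_start + 20), tr$core)
  # conservation: host is untouched and every phage base survives
  expect_true(startsWith(tr$lysogen$sequence,
                         substr(host$sequence, 1, tr$host_core_start + 20)))
  expect_true(endsWith(tr$lysogen$sequence,
                       substr(host$sequence, tr$host_core_start + 21,
                              genome_length(host))))
  pl <- genome_length(tr$phage)
  prophage <- paste0(substr(tr$phage$sequence, tr$phage_core_start + 21, pl),
                     substr(tr$phage$sequence, 1, tr$phage_core_start))
  expect_true(grepl(prophage, tr$lysogen$sequence, fixed = TRUE))
  expect_error(plant_integration(host, phage, core_len = 0), "core_len")
})

test_that("plant_integration flags a non-unique core as ambiguous", {
  base <- generate_genome(n_genes = 10, seed = 604, genome_id = "hrep",
                          kind = "host")
  dup <- paste0(base$sequence, substr(base$sequence, 501, 700))
  host <- annotated_genome("hrep", dup, kind = "host")
  phage <- generate_genome(n_genes = 10, seed = 605, genome_id = "p2")
  tr <- plant_integration(host, phage, core_len = 30, host_site = 550,
                          seed = 606)
  expect_true(tr$ambiguous)
})

test_that("sequence and table writers round-trip through standard formats", {
  g <- small_genome()
  td <- withr::local_tempdir()
  fa <- file.path(td, "g.fasta")
  write_genome_fasta(g, fa)
  back <- read_fasta(fa)
  expect_identical(unname(back), g$sequence)
  pf <- file.path(td, "p.faa")
  write_protein_fasta(g, pf)
  prots <- read_fasta(pf)
  expect_identical(names(prots), paste(g$genome_id, g$genes$gene_id,
                                       sep = "|"))
  expect_identical(unname(prots), g$genes$protein)
  gt <- file.path(td, "genes.tsv")
  write_gene_table(g, gt)
  tab <- read.table(gt, header = TRUE, sep = "\t")
  expect_equal(tab$start, g$genes$start + 1) # 1-based in human outputs
  expect_equal(tab$end, g$genes$end)
  reads <- simulate_virome(list(g), 1, n_reads = 20, read_len = 80,
                           error_rate = 0, seed = 41)
  fq <- file.path(td, "reads.fastq")
  write_reads(reads, fq, format = "fastq")
  back2 <- read_reads(fq)
  expect_identical(back2$sequence, reads$sequence)
  expect_identical(back2$read_id, reads$read_id)
})
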