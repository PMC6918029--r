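fake_db_50kb <- function() {
  g <- annotated_genome("ref50", strrep("ACGT", 12500),
                        group = "grp1", kind = "phage")
  reference_db(list(g))
}

fake_assignments <- function(n_assigned, group = "grp1") {
  out <- data.frame(
    read_id = sprintf("r%06d", seq_len(max(n_assigned, 1))),
    stage = c(rep("assigned", n_assigned),
              rep("screened_out", max(n_assigned, 1) - n_assigned)),
    assigned_genome = NA_character_, assigned_group = NA_character_,
    best_bitscore = NA_real_, stringsAsFactors = FALSE)
  out$assigned_group[out$stage == "assigned"] <- group
  class(out) <- c("read_assignments", "data.frame")
  out
}

test_that("RPKM arithmetic matches its printed definition exactly", {
  db <- fake_db_50kb()
  ab <- rpkm(fake_assignments(1000), db, virome_total_reads = 1e6)
  expect_identical(ab$rpkm, 20.0) # 1000 / 50 kb / 1M reads
  ab0 <- rpkm(fake_assignments(0), db, virome_total_reads = 1e6)
  expect_identical(ab0$rpkm, 0)
  expect_identical(ab0$recruited_read_count, 0L)
  # two genomes of 40 and 60 kb: mean 50 kb; 500 reads in 2M: 5.0
  g1 <- annotated_genome("a40", strrep("ACGT", 10000), group = "g")
  g2 <- annotated_genome("a60", strrep("ACGT", 15000), group = "g")
  db2 <- reference_db(list(g1, g2))
  ab2 <- rpkm(fake_assignments(500, "g"), db2, virome_total_reads = 2e6)
  expect_identical(ab2$rpkm, 5.0)
  expect_error(rpkm(fake_assignments(1), db, virome_total_reads = 0),
               "virome_total_reads")
})

test_that("reference_db validates groups and computes mean sizes", {
  g <- small_genome()
  expect_s3_class(reference_db(list(g)), "reference_db")
  nogrp <- annotated_genome("x", strrep("ACGT", 1000))
  expect_error(reference_db(list(nogrp)), "group")
  db <- small_scenario()$db
  expect_equal(unname(db$mean_genome_kb["grpA"]),
               mean(vapply(small_scenario()$groups$grpA, genome_length,
                           numeric(1))) / 1000)
})

test_that("screening keeps focal-derived reads and drops unrelated ones", {
  sc <- small_scenario()
  scr <- screen_reads(sc$reads, sc$db)
  truth <- sc$reads$truth_group
  phage_reads <- !is.na(truth)
  # nearly all phage-derived reads pass; the small remainder are reads
  # whose in-frame fragment is too short to clear 40 bits
  expect_gt(mean(scr$stage[phage_reads] == "candidate"), 0.6)
  # host reads only pass via AMG homology, a small minority
  expect_lt(mean(scr$stage[!phage_reads] == "candidate"), 0.15)
})

test_that("reciprocal step vetoes host reads and conserves read counts", {
  sc <- small_scenario()
  scr <- screen_reads(sc$reads, sc$db)
  a <- reciprocal_assign(sc$reads, scr, sc$db)
  expect_equal(nrow(a), nrow(sc$reads))
  expect_equal(sum(table(a$stage)), nrow(sc$reads))
  expect_equal(sum(a$stage == "screened_out"),
               sum(scr$stage == "screened_out"))
  # assigned implies a focal genome and its group
  asg <- a[a$stage == "assigned", ]
  expect_true(all(asg$assigned_genome %in% sc$db$focal_ids))
  expect_identical(unname(sc$db$group_of[asg$assigned_genome]),
                   asg$assigned_group)
  # no host read is assigned while the decoys are present
  host_ids <- sc$reads$read_id[is.na(sc$reads$truth_group)]
  expect_equal(sum(asg$read_id %in% host_ids), 0)
  # and assigned phage reads land in their true group
  truth <- sc$reads$truth_group[match(asg$read_id, sc$reads$read_id)]
  expect_true(all(truth == asg$assigned_group))
})

test_that("dropping the bacterial decoys lets host reads through", {
  sc <- small_scenario()
  scr <- screen_reads(sc$reads, sc$db)
  with_dec <- reciprocal_assign(sc$reads, scr, sc$db)
  db_nd <- reference_db(unlist(sc$groups, recursive = FALSE),
                        background = sc$db$background, decoys = list())
  no_dec <- reciprocal_assign(sc$reads, scr, db_nd)
  host_ids <- sc$reads$read_id[is.na(sc$reads$truth_group)]
  f_with <- sum(with_dec$stage == "assigned" &
                  with_dec$read_id %in% host_ids)
  f_without <- sum(no_dec$stage == "assigned" &
                     no_dec$read_id %in% host_ids)
  expect_gt(f_without, f_with)
})

test_that("single-pass mode assigns by highest bitscore at a strict cutoff", {
  # two one-gene genomes: an exact copy of the read's source protein and a
  # diverged copy; the exact copy must win the bitscore comparison
  base <- generate_genome(n_genes = 1, mean_gene_len = 150, seed = 71,
                          genome_id = "exact", group = "gE")
  divg <- evolve_genome(base, 0.25, seed = 72, genome_id = "diverged",
                        group = "gD")
  db <- reference_db(list(base, divg))
  gn <- base$genes[1, ]
  read <- substr(base$sequence, gn$start + 1, gn$start + 150)
  a <- gov_assign(c(read1 = read), db)
  expect_equal(a$stage, "assigned")
  expect_equal(a$assigned_genome, "exact")
  # a short read whose best hit has E-value between 1e-10 and 1e-3 is
  # recruited by the screening step but not in single-pass mode
  short <- substr(base$sequence, gn$start + 1, gn$start + 57)
  scr <- screen_reads(c(r = short), db)
  expect_equal(scr$stage, "candidate")
  a2 <- gov_assign(c(r = short), db)
  expect_equal(a2$stage, "screened_out")
})

test_that("reciprocal and single-pass modes agree on a decoy-free virome", {
  sc <- small_scenario()
  phage_only <- sc$reads[!is.na(sc$reads$truth_group), , drop = FALSE]
  scr <- screen_reads(phage_only, sc$db)
  rec <- reciprocal_assign(phage_only, scr, sc$db)
  gov <- gov_assign(phage_only, sc$db)
  both <- rec$stage == "assigned" & gov$stage == "assigned"
  expect_gt(sum(both), 0)
  concordance <- mean(rec$assigned_group[both] == gov$assigned_group[both])
  expect_gte(concordance, 0.95)
})

test_that("recruitment report is long-format, ordered, re-derivable", {
  db <- fake_db_50kb()
  ab <- lapply(c("v1", "v2"), function(v)
    rpkm(fake_assignments(100), db, virome_total_reads = 1e6,
         virome_id = v))
  rep_ <- recruitment_report(ab)
  expect_equal(nrow(rep_), 2) # 1 group x 2 viromes
  expect_equal(rep_$virome, c("v1", "v2"))
  expect_equal(rep_$rpkm,
               rep_$recruited_read_count / rep_$mean_genome_kb /
                 (rep_$virome_total_reads / 1e6))
  expect_equal(nrow(recruitment_report(list())), 0)
})
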