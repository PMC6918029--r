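test_that("align_local matches hand-computed and boundary cases", {
  r <- align_local("MKVLH", "MKVLH")
  expect_equal(r$raw_score, 26) # 5+5+4+4+8 on the BLOSUM62 diagonal
  expect_equal(r$identity, 5)
  expect_equal(r$alignment_length, 5)
  r0 <- align_local("A", "T") # BLOSUM62 A<->T scores 0
  expect_equal(r0$raw_score, 0)
  expect_equal(r0$alignment_length, 0)
  expect_error(align_local("", "MK"), "empty")
})

test_that("align_local equals the brute-force DP oracle on random peptides", {
  withr::local_seed(1234)
  n_pairs <- 250
  for (i in seq_len(n_pairs)) {
    a <- random_peptide(sample(5:30, 1))
    b <- if (i %% 4 == 0) {
      # related pair with an indel, to exercise affine gaps
      ins <- sample(nchar(a), 1)
      paste0(substr(a, 1, ins), random_peptide(sample(1:4, 1)),
             substr(a, ins + 1, nchar(a)))
    } else random_peptide(sample(5:30, 1))
    expect_equal(align_local(a, b)$raw_score, sw_oracle_score(a, b),
                 info = paste(a, b))
  }
})

test_that("protein-mode score is symmetric", {
  withr::local_seed(99)
  for (i in 1:50) {
    a <- random_peptide(sample(8:25, 1))
    b <- random_peptide(sample(8:25, 1))
    expect_equal(align_local(a, b)$raw_score, align_local(b, a)$raw_score)
  }
})

test_that("bit score and E-value follow the Karlin-Altschul formulae", {
  m <- scoring_model()
  be0 <- bits_and_evalue(0, m, m = 250, n = 4000)
  expect_equal(be0$evalue, 250 * 4000 * 2^(-be0$bitscore))
  be <- bits_and_evalue(40, m, m = 1, n = 1)
  expect_equal(be$bitscore, (0.267 * 40 - log(0.041)) / log(2),
               tolerance = 1e-12)
  expect_equal(round(be$bitscore, 2), 20.02)
  # strict monotonicity in the raw score at fixed search space
  ev <- bits_and_evalue(0:50, m, m = 100, n = 1000)$evalue
  expect_true(all(diff(ev) < 0))
  # linear in m
  expect_equal(bits_and_evalue(30, m, m = 200, n = 50)$evalue,
               2 * bits_and_evalue(30, m, m = 100, n = 50)$evalue)
  expect_error(scoring_model(lambda = -1), "lambda")
  expect_error(bits_and_evalue(-3, m), "raw_score")
})

test_that("translated search finds in-frame substrings on both strands", {
  g <- small_genome()
  gn <- g$genes[3, ]
  cds <- substr(g$sequence, gn$start + 1, gn$start + 108)
  hits <- homology_search(c(r = cds), genome_proteins(g),
                          mode = "translated")
  expect_gt(nrow(hits), 0)
  top <- hits[1, ]
  expect_identical(top$sseqid, paste(g$genome_id, gn$gene_id, sep = "|"))
  expect_equal(top$pident, 100)
  hits_rc <- homology_search(c(r = revcomp(cds)), genome_proteins(g),
                             mode = "translated")
  expect_identical(hits_rc$sseqid[1], top$sseqid)
  expect_equal(hits_rc$frame[1], -top$frame)
  expect_equal(hits_rc$bitscore[1], top$bitscore)
  # empty subject set is an empty result, not an error
  expect_equal(nrow(homology_search(c(r = cds),
                                    stats::setNames(character(), character()),
                                    mode = "translated")), 0)
})

test_that("random reads rarely reach E <= 1e-3 against a decoy proteome", {
  withr::local_seed(77)
  nt <- c("A", "C", "G", "T")
  reads <- vapply(1:1000, function(i)
    paste(sample(nt, 150, replace = TRUE), collapse = ""), character(1))
  names(reads) <- sprintf("rnd%04d", 1:1000)
  decoys <- vapply(1:50, function(i) random_peptide(200), character(1))
  names(decoys) <- sprintf("dec%02d", 1:50)
  hits <- homology_search(reads, decoys, mode = "translated",
                          max_evalue = 1e-3)
  expect_lt(length(unique(hits$qseqid)) / 1000, 0.01)
})

test_that("the k-mer prefilter does not change confidently ranked results", {
  g <- small_genome()
  child <- evolve_genome(g, 0.3, seed = 17, genome_id = "gchild")
  q <- genome_proteins(child); s <- genome_proteins(g)
  h1 <- homology_search(q, s, mode = "protein", max_evalue = 1e-5,
                        min_bitscore = 50, prefilter = TRUE)
  h2 <- homology_search(q, s, mode = "protein", max_evalue = 1e-5,
                        min_bitscore = 50, prefilter = FALSE)
  key <- function(h) paste(h$qseqid, h$sseqid, h$bitscore)
  expect_true(all(key(h1) %in% key(h2)))
  # at these thresholds (50 bits on ~70% identical proteins) nothing is lost
  expect_identical(key(h1), key(h2))
})

test_that("hit tables round-trip through the 12-column tabular format", {
  g <- small_genome()
  hits <- homology_search(genome_proteins(g)[1:3], genome_proteins(g),
                          mode = "protein")
  td <- withr::local_tempdir()
  path <- file.path(td, "hits.tsv")
  write_hits(hits, path)
  back <- read_hits(path)
  expect_equal(nrow(back), nrow(hits))
  for (col in c("qseqid", "sseqid", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send"))
    expect_equal(back[[col]], hits[[col]])
  expect_equal(back$pident, hits$pident, tolerance = 1e-3)
  expect_equal(back$bitscore, hits$bitscore, tolerance = 0.05)
  expect_equal(back$evalue, hits$evalue, tolerance = 1e-3)
  # reader tolerates extra trailing columns
  lines <- readLines(path)
  writeLines(paste0(lines, "\textra\t42"), path)
  expect_equal(nrow(read_hits(path)), nrow(hits))
  # empty file -> empty list
  writeLines(character(), path)
  expect_equal(nrow(read_hits(path)), 0)
  # malformed row names its line
  writeLines(c(lines[1], sub("\t[0-9.]+$", "\tnot_a_number", lines[2])),
             path)
  expect_error(read_hits(path), "line 2")
})
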