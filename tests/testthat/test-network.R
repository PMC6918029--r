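test_that("protein graph applies inclusive edge thresholds and max-weight", {
  h <- rbind(
    fake_hit("A|g1", "B|g1", 50, 80, 1e-4, bitscore = 90),  # evalue too high
    fake_hit("A|g2", "B|g2", 50, 80, 1e-9, bitscore = 49),  # bits too low
    fake_hit("A|g3", "B|g3", 50, 80, 1e-9, bitscore = 55),
    fake_hit("B|g3", "A|g3", 50, 80, 1e-9, bitscore = 60),  # reciprocal
    fake_hit("A|g4", "A|g4", 99, 99, 1e-30, bitscore = 300))
  g <- build_protein_graph(h)
  expect_setequal(g$nodes, c("A|g1", "B|g1", "A|g2", "B|g2", "A|g3",
                             "B|g3", "A|g4"))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 60) # max over the two directions
})

test_that("MCL separates disconnected components and isolates", {
  nodes <- c("a1", "a2", "a3", "b1", "b2", "b3", "iso")
  M <- matrix(0, 7, 7, dimnames = list(nodes, nodes))
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    M[p[1], p[2]] <- M[p[2], p[1]] <- 1
  cl <- mcl(M)
  expect_true(attr(cl, "converged"))
  sizes <- sort(unname(vapply(cl, length, numeric(1))))
  expect_equal(sizes, c(1, 3, 3))
  expect_true(any(vapply(cl, function(x) setequal(x, c("a1", "a2", "a3")),
                         logical(1))))
  expect_true(any(vapply(cl, identical, logical(1), "iso")))
})

test_that("MCL output is a partition, stable under node permutation", {
  withr::local_seed(505)
  for (i in 1:10) {
    p <- random_graph_problem(n = 10, p = 0.3)
    M <- graph_problem_matrix(p)
    cl <- mcl(M)
    members <- unlist(cl)
    expect_setequal(members, rownames(M)) # coverage
    expect_equal(anyDuplicated(members), 0) # disjointness
    perm <- sample(nrow(M))
    cl2 <- mcl(M[perm, perm])
    canon <- function(x) paste(sort(vapply(lapply(x, sort), paste,
                                           character(1), collapse = ",")),
                               collapse = ";")
    expect_identical(canon(cl), canon(cl2))
  }
})

test_that("MCL matches the independent reference implementation", {
  withr::local_seed(606)
  problems <- lapply(1:20, function(i) random_graph_problem(n = 8))
  ours <- lapply(problems, function(p) {
    nodes <- sprintf("n%02d", seq_len(p$n))
    lapply(mcl(graph_problem_matrix(p)), function(cl) match(cl, nodes))
  })
  ref <- mcl_oracle(problems)
  for (i in seq_along(problems))
    expect_identical(canonical_partition(ours[[i]]),
                     canonical_partition(ref[[i]]), info = paste("graph", i))
})

test_that("hypergeometric similarity matches exact tail enumeration", {
  expect_equal(hypergeometric_similarity(character(), c("c1"), 10), 0)
  expect_equal(hypergeometric_similarity(c("c1", "c2"), c("c3", "c4"), 10), 0)
  # universe 4, |A|=|B|=2, c=2: P = 1/C(4,2) = 1/6
  s <- hypergeometric_similarity(c("c1", "c2"), c("c1", "c2"), 4)
  expect_equal(s, -log10(1 / 6), tolerance = 1e-10)
  # non-decreasing in the overlap at fixed sizes
  u <- paste0("c", 1:20)
  scores <- vapply(0:5, function(cc) {
    a <- u[1:5]
    b <- c(u[seq_len(cc)], u[6:(10 - cc)])
    hypergeometric_similarity(a, b, 20)
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_error(hypergeometric_similarity(u[1:5], u[6:10], 8), "universe")
  # extreme overlap is capped, not infinite
  big <- paste0("c", 1:400)
  expect_lte(hypergeometric_similarity(big, big, 500), 300)
})

test_that("genome network keeps pairs at or above the cutoff only", {
  # |A|=1, |B|=1, c=1, universe 10: P = 1/10, score exactly 1
  profiles <- structure(list(A = "c1", B = "c1", C = "c2"),
                        class = "genome_profiles", universe = 10)
  net <- build_genome_network(profiles, universe = 10, cutoff = 1)
  expect_equal(nrow(net), 1)
  expect_setequal(c(net$genome_a, net$genome_b), c("A", "B"))
  expect_equal(net$score, 1)
  # just below the cutoff is dropped: universe 9 gives P = 1/9, score ~0.95
  net2 <- build_genome_network(profiles, universe = 9, cutoff = 1)
  expect_equal(nrow(net2), 0)
  # disjoint profiles never link
  expect_equal(nrow(build_genome_network(
    structure(list(X = "c1", Y = "c2"), class = "genome_profiles",
              universe = 10))), 0)
})

test_that("viral clusters recover synthetic families and leave singletons", {
  fams <- lapply(1:2, function(i)
    make_genome_family(n_members = 3, divergence = 0.2,
                       group = paste0("fam", i), seed = 3000 + i,
                       n_genes = 25, mean_gene_len = 150))
  singles <- lapply(1:2, function(i)
    generate_genome(n_genes = 25, mean_gene_len = 150, seed = 3100 + i,
                    genome_id = paste0("solo", i)))
  genomes <- c(unlist(lapply(fams, `[[`, "members"), recursive = FALSE),
               singles)
  prots <- genome_proteins(genomes)
  hits <- homology_search(prots, prots, mode = "protein",
                          max_evalue = 1e-5, min_bitscore = 50)
  pcs <- mcl(build_protein_graph(hits))
  prof <- genome_profiles(pcs)
  net <- build_genome_network(prof)
  vc <- detect_viral_clusters(
    net, genomes = vapply(genomes, function(g) g$genome_id, character(1)))
  expect_length(vc$clusters, 2)
  expect_setequal(vc$unclustered, c("solo1", "solo2"))
  expect_true(any(vapply(vc$clusters, setequal, logical(1),
                         c("fam1_m1", "fam1_m2", "fam1_m3"))))
  expect_true(any(vapply(vc$clusters, setequal, logical(1),
                         c("fam2_m1", "fam2_m2", "fam2_m3"))))
  # one family alone (scored against the full cluster universe) -> one
  # cluster; the universe must extend beyond the family itself, since a
  # profile overlap that exhausts the universe has tail probability 1
  fam1 <- c("fam1_m1", "fam1_m2", "fam1_m3")
  net1 <- build_genome_network(prof[fam1],
                               universe = attr(prof, "universe"))
  vc1 <- detect_viral_clusters(net1)
  expect_length(vc1$clusters, 1)
  expect_setequal(vc1$clusters[[1]], fam1)
  # empty edge list -> everything unclustered
  vc0 <- detect_viral_clusters(net[0, ], genomes = c("x", "y"))
  expect_length(vc0$clusters, 0)
  expect_setequal(vc0$unclustered, c("x", "y"))
})

test_that("network similarity is symmetric in its arguments", {
  withr::local_seed(42)
  u <- paste0("c", 1:50)
  for (i in 1:20) {
    a <- sample(u, sample(3:20, 1))
    b <- sample(u, sample(3:20, 1))
    expect_equal(hypergeometric_similarity(a, b, 50),
                 hypergeometric_similarity(b, a, 50))
  }
})

test_that("environmental contig filter applies both inclusive thresholds", {
  mkcontig <- function(id, len, n_genes) {
    genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)),
                        start = seq(0, by = 60, length.out = n_genes),
                        end = seq(33, by = 60, length.out = n_genes),
                        strand = "+", protein = strrep("M", 10),
                        stringsAsFactors = FALSE)
    annotated_genome(id, strrep("A", len), genes, kind = "env_contig")
  }
  focal <- annotated_genome("foc", strrep("A", 30000), kind = "phage",
                            group = "grp")
  contigs <- list(
    mkcontig("short", 19900, 10),   # long enough shared, too short
    mkcontig("lowsh", 25000, 10),   # long enough, only 10% shared
    mkcontig("edge", 20000, 10))    # exactly 20 kb and 20% shared
  pairs <- data.frame(
    gene_a = c(paste0("short|g0", 1:5), "lowsh|g01", "edge|g01", "edge|g02"),
    gene_b = "foc|g001",
    genome_a = c(rep("short", 5), "lowsh", "edge", "edge"),
    genome_b = "foc", stringsAsFactors = FALSE)
  kept <- filter_env_contigs(contigs, list(focal), pairs)
  expect_equal(vapply(kept, function(g) g$genome_id, character(1)), "edge")
  nogene <- annotated_genome("bare", strrep("A", 25000), kind = "env_contig")
  expect_warning(res <- filter_env_contigs(list(nogene), list(focal), pairs),
                 "0 genes")
  expect_length(res, 0)
})
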