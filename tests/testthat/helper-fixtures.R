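# Small shared fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

# a fully specified synthetic hit row, for threshold-boundary tests
fake_hit <- function(q, s, pident, qcovs, evalue, bitscore = 100) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = 100L,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
             sstart = 1L, send = 100L, evalue = evalue,
             bitscore = bitscore, raw_score = 260L, frame = 0L,
             qcovs = qcovs, stringsAsFactors = FALSE)
}

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_genome <- function() {
  fixture("small_genome", function()
    generate_genome(n_genes = 12, mean_gene_len = 150, gc = 0.45,
                    seed = 401, genome_id = "gsmall", group = "grpS"))
}

# a compact recruitment scenario for unit tests (the full-size one lives in
# the acceptance suite)
small_scenario <- function() {
  fixture("small_scenario", function()
    make_recruitment_scenario(n_reads = 2000, seed = 11))
}

# planted integration with references and error-free reads
small_integration <- function() {
  fixture("small_integration", function() {
    host <- generate_genome(n_genes = 15, mean_gene_len = 150, gc = 0.50,
                            seed = 501, genome_id = "hostI", kind = "host")
    phage <- generate_genome(n_genes = 25, mean_gene_len = 150, gc = 0.45,
                             seed = 502, genome_id = "phageI")
    tr <- plant_integration(host, phage, core_len = 24, seed = 503)
    reads <- simulate_virome(
      list(tr$lysogen), 1,
      n_reads = round(20 * genome_length(tr$lysogen) / 150),
      read_len = 150, error_rate = 0, seed = 504)
    list(host = host, phage = phage, truth = tr, reads = reads)
  })
}
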