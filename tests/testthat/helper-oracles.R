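# Independent oracles used to validate the package's own implementations.

# Brute-force affine-gap Smith-Waterman (score only), written directly from
# the recurrences with the substitution matrix taken from Biostrings --
# deliberately sharing no code or data with the package's C++ kernel.
sw_oracle_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  if (!exists("BLOSUM62", inherits = TRUE))
    data("BLOSUM62", package = "Biostrings",
         envir = environment(sw_oracle_score))
  mat <- get("BLOSUM62", envir = environment(sw_oracle_score))
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_peptide <- function(len) {
  paste(sample(phagenomics:::AA20, len, replace = TRUE), collapse = "")
}

# Run the independent Python/numpy MCL reference on a list of problems.
# Each problem: list(n =, edges = list of c(i, j, w)) with 1-based indices.
mcl_oracle <- function(problems, inflation = 2, expansion = 2) {
  script <- system.file("oracles", "mcl_oracle.py", package = "phagenomics")
  stopifnot(nzchar(script))
  payload <- lapply(problems, function(p)
    list(n = p$n, inflation = inflation, expansion = expansion,
         edges = lapply(p$edges, function(e) list(e[[1]], e[[2]], e[[3]]))))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  out <- system2("python", script, input = as.character(json), stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

# canonical string form of a partition given as list of integer vectors
canonical_partition <- function(parts) {
  parts <- lapply(parts, function(p) sort(as.integer(unlist(p))))
  parts <- parts[order(vapply(parts, `[`, integer(1), 1))]
  paste(vapply(parts, paste, character(1), collapse = ","), collapse = ";")
}

random_graph_problem <- function(n = 8, p = 0.35) {
  ed <- t(combn(n, 2))
  keep <- runif(nrow(ed)) < p
  ed <- ed[keep, , drop = FALSE]
  w <- round(runif(nrow(ed), 0.5, 2), 3)
  edges <- lapply(seq_len(nrow(ed)), function(i)
    c(ed[i, 1], ed[i, 2], w[i]))
  list(n = n, edges = edges, ed = ed, w = w)
}

graph_problem_matrix <- function(p) {
  nodes <- sprintf("n%02d", seq_len(p$n)) # zero-padded: lex order == index order
  M <- matrix(0, p$n, p$n, dimnames = list(nodes, nodes))
  if (nrow(p$ed)) {
    M[p$ed] <- p$w
    M[p$ed[, c(2, 1), drop = FALSE]] <- p$w
  }
  M
}
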