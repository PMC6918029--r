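#' Build the all-vs-all protein graph
#'
#' Nodes are every protein id appearing in the hit table (so proteins
#' whose only qualifying hit is to themselves become isolated nodes);
#' edges connect distinct proteins with at least one hit passing E-value
#' <= `max_evalue` and bitscore >= `min_bitscore`, weighted by the maximum
#' qualifying bitscore in either direction.
#'
#' @param hits hits data.frame from an all-vs-all protein search.
#' @param max_evalue,min_bitscore inclusive edge thresholds.
#' @return list of class `protein_graph` with `nodes` (character) and
#'   `edges` (data.frame `from`, `to`, `weight`).
#' @export
build_protein_graph <- function(hits, max_evalue = 1e-5, min_bitscore = 50) {
  nodes <- sort(unique(c(hits$qseqid, hits$sseqid)))
  keep <- hits$evalue <= max_evalue & hits$bitscore >= min_bitscore &
    hits$qseqid != hits$sseqid
  h <- hits[keep, , drop = FALSE]
  if (nrow(h)) {
    a <- pmin(h$qseqid, h$sseqid)
    b <- pmax(h$qseqid, h$sseqid)
    key <- paste(a, b, sep = "\r")
    w <- tapply(h$bitscore, key, max)
    ab <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    edges <- data.frame(from = ab[, 1], to = ab[, 2],
                        weight = as.numeric(w), stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "protein_graph")
}

graph_to_matrix <- function(x) {
  if (inherits(x, "protein_graph")) {
    nodes <- x$nodes; edges <- x$edges
  } else if (is.data.frame(x)) {
    nodes <- sort(unique(c(x$from, x$to))); edges <- x
  } else if (is.matrix(x)) {
    if (is.null(rownames(x)))
      dimnames(x) <- list(sprintf("n%d", seq_len(nrow(x))),
                          sprintf("n%d", seq_len(nrow(x))))
    # force general (non-symmetric, non-triangular) sparse storage
    return(as(as(as(Matrix::Matrix(x), "CsparseMatrix"), "generalMatrix"),
              "dMatrix"))
  } else stop("unsupported graph input")
  n <- length(nodes)
  i <- match(edges$from, nodes); j <- match(edges$to, nodes)
  M <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(edges$weight, 2), dims = c(n, n),
                            dimnames = list(nodes, nodes))
  M
}

col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  zero <- cs == 0
  if (any(zero)) {
    idx <- which(zero)
    M[cbind(idx, idx)] <- 1
    cs[zero] <- 1
  }
  M %*% Matrix::Diagonal(x = 1 / cs)
}

#' Markov clustering (MCL)
#'
#' Full MCL on a weighted undirected graph: self-loops are added with
#' weight equal to each node's maximum incident edge weight (1 for
#' isolated nodes), columns are normalized to stochastic, and expansion
#' (matrix power) alternates with inflation (elementwise power followed by
#' column renormalization and pruning of entries below
#' `prune_threshold`) until the maximum entrywise change falls below
#' `tol` or `max_iter` iterations have run (the latter yields the current
#' clustering with a warning).  Clusters are read off attractor rows;
#' every node is assigned exactly once, overlaps being resolved by higher
#' flow mass and then lexicographically.
#'
#' @param x a `protein_graph`, an edge data.frame (`from`, `to`,
#'   `weight`), or a symmetric weighted adjacency matrix.
#' @param inflation inflation exponent (default 2).
#' @param expansion expansion power (default 2).
#' @param prune_threshold entries below this are zeroed each iteration.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the maximum entrywise change.
#' @return list of character vectors (the clusters, named `PC_1`, `PC_2`,
#'   ... in decreasing size order), of class `mcl_clusters`, with
#'   attributes `converged` and `iterations`.
#' @export
mcl <- function(x, inflation = 2, expansion = 2, prune_threshold = 1e-5,
                max_iter = 100, tol = 1e-8) {
  M <- graph_to_matrix(x)
  if (any(M@x < 0)) stop("edge weights must be non-negative")
  nodes <- rownames(M)
  n <- nrow(M)
  if (n == 0) return(structure(list(), class = "mcl_clusters",
                               converged = TRUE, iterations = 0L))
  # self-loops: max incident weight (1 for isolated nodes)
  mx <- apply_col_max(M)
  mx[mx == 0] <- 1
  Matrix::diag(M) <- mx
  M <- col_normalize(M)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    E <- M
    for (e in seq_len(expansion - 1L)) E <- E %*% M
    E <- E^inflation
    E <- col_normalize(E)
    E <- Matrix::drop0(E * (E >= prune_threshold))
    E <- col_normalize(E)
    delta <- max(abs(E - M))
    M <- E
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter, " iterations")
  clusters <- interpret_mcl(M, nodes)
  structure(clusters, class = "mcl_clusters", converged = converged,
            iterations = iter)
}

apply_col_max <- function(M) {
  M2 <- M
  Matrix::diag(M2) <- 0
  M2 <- Matrix::drop0(M2)
  out <- numeric(nrow(M2))
  cm <- as(M2, "CsparseMatrix")
  if (length(cm@x)) {
    colidx <- rep(seq_len(ncol(cm)), diff(cm@p))
    cmax <- tapply(cm@x, colidx, max)
    out[as.integer(names(cmax))] <- cmax
  }
  out
}

# Read a hard partition from a converged MCL matrix.
interpret_mcl <- function(M, nodes) {
  M <- as(M, "CsparseMatrix")
  d <- Matrix::diag(M)
  att <- which(d > 0)
  n <- length(nodes)
  if (!length(att)) att <- seq_len(n) # degenerate guard
  # attractor systems: connected components of attractor-attractor support
  A <- M[att, att, drop = FALSE]
  A <- (A + Matrix::t(A)) > 0
  na <- length(att)
  comp <- integer(na)
  cid <- 0L
  for (s in seq_len(na)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(A[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  nsys <- cid
  # flow of every node toward each attractor system
  flow <- matrix(0, nsys, n)
  Ma <- M[att, , drop = FALSE]
  for (s in seq_len(nsys))
    flow[s, ] <- Matrix::colSums(Ma[comp == s, , drop = FALSE])
  sys_minname <- vapply(seq_len(nsys), function(s)
    min(nodes[att[comp == s]]), character(1))
  assign <- integer(n)
  for (j in seq_len(n)) {
    f <- flow[, j]
    best <- which(f == max(f))
    if (length(best) > 1 && max(f) == 0) {
      assign[j] <- 0L # unattracted: own singleton
    } else if (length(best) > 1) {
      assign[j] <- best[order(sys_minname[best])][1]
    } else assign[j] <- best
  }
  clusters <- list()
  for (s in seq_len(nsys)) {
    mem <- nodes[assign == s]
    if (length(mem)) clusters[[length(clusters) + 1L]] <- sort(mem)
  }
  for (j in which(assign == 0L))
    clusters[[length(clusters) + 1L]] <- nodes[j]
  ord <- order(-vapply(clusters, length, numeric(1)),
               vapply(clusters, `[`, character(1), 1))
  clusters <- clusters[ord]
  names(clusters) <- sprintf("PC_%d", seq_along(clusters))
  clusters
}

#' Genome profiles over protein clusters
#'
#' Maps each genome to the set of protein clusters containing at least one
#' of its proteins.  Protein ids must be genome-qualified
#' (`genomeID|geneID`).
#'
#' @param clusters `mcl_clusters` from [mcl()] on the protein graph.
#' @return named list of character vectors (cluster ids per genome), of
#'   class `genome_profiles`, with attribute `universe` = total number of
#'   protein clusters.
#' @export
genome_profiles <- function(clusters) {
  genome <- lapply(clusters, genome_of)
  long_g <- unlist(genome, use.names = FALSE)
  long_c <- rep(names(clusters), lengths(genome))
  prof <- lapply(split(long_c, long_g), unique)
  structure(prof, class = "genome_profiles", universe = length(clusters))
}

#' Hypergeometric gene-content similarity of two genomes
#'
#' The similarity score is `-log10` of the hypergeometric tail probability
#' of observing at least the shared number of protein clusters, given each
#' genome's cluster count and the cluster universe; the score is capped at
#' 300 and no multiple-comparison correction is applied.
#'
#' @param a,b character vectors of cluster ids (genome profiles).
#' @param universe total number of protein clusters under comparison.
#' @return numeric similarity score >= 0.
#' @export
hypergeometric_similarity <- function(a, b, universe) {
  a <- unique(a); b <- unique(b)
  if (universe < length(union(a, b)))
    stop("universe smaller than profile union")
  cc <- length(intersect(a, b))
  if (cc == 0) return(0)
  p <- phyper(cc - 1, length(a), universe - length(a), length(b),
              lower.tail = FALSE)
  min(-log10(p), 300)
}

#' Build the genome similarity network
#'
#' Scores every unordered genome pair with
#' [hypergeometric_similarity()] and retains pairs with score >= `cutoff`
#' (inclusive).
#'
#' @param profiles `genome_profiles`.
#' @param universe cluster universe; defaults to the profiles' attribute.
#' @param cutoff minimum retained similarity score (default 1).
#' @return data.frame with `genome_a`, `genome_b`, `score`.
#' @export
build_genome_network <- function(profiles, universe = NULL, cutoff = 1) {
  universe <- universe %||% attr(profiles, "universe")
  ids <- sort(names(profiles))
  out <- list()
  if (length(ids) >= 2) {
    cmb <- combn(ids, 2)
    for (k in seq_len(ncol(cmb))) {
      s <- hypergeometric_similarity(profiles[[cmb[1, k]]],
                                     profiles[[cmb[2, k]]], universe)
      if (s >= cutoff)
        out[[length(out) + 1L]] <- data.frame(genome_a = cmb[1, k],
                                              genome_b = cmb[2, k],
                                              score = s,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(genome_a = character(), genome_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Detect viral clusters from the genome network
#'
#' Clusters the genome similarity network with MCL (inflation 2 by
#' default); connected components are available as a fallback method.
#' Clusters with at least two members are reported as viral clusters;
#' all other genomes (including any passed via `genomes` that have no
#' retained edges) are reported as unclustered.
#'
#' @param edges edge data.frame from [build_genome_network()].
#' @param genomes optional character vector of all genome ids under
#'   analysis, so that edge-less genomes appear as unclustered.
#' @param inflation MCL inflation.
#' @param method "mcl" or "components".
#' @return list with `clusters` (named list `VC_1`, ... of member id
#'   vectors) and `unclustered` (character vector).
#' @export
detect_viral_clusters <- function(edges, genomes = NULL, inflation = 2,
                                  method = c("mcl", "components")) {
  method <- match.arg(method)
  genomes <- sort(unique(c(genomes, edges$genome_a, edges$genome_b)))
  if (!nrow(edges))
    return(list(clusters = stats::setNames(list(), character()),
                unclustered = genomes))
  ed <- data.frame(from = edges$genome_a, to = edges$genome_b,
                   weight = edges$score, stringsAsFactors = FALSE)
  in_graph <- sort(unique(c(ed$from, ed$to)))
  if (method == "mcl") {
    parts <- mcl(ed, inflation = inflation)
  } else {
    M <- graph_to_matrix(ed)
    lab <- components_labels(M)
    parts <- split(in_graph, lab)
  }
  sizes <- vapply(parts, length, numeric(1))
  clusters <- parts[sizes >= 2]
  clusters <- clusters[order(-vapply(clusters, length, numeric(1)),
                             vapply(clusters, `[`, character(1), 1))]
  clusters <- lapply(clusters, sort)
  names(clusters) <- if (length(clusters))
    sprintf("VC_%d", seq_along(clusters)) else character()
  unclustered <- sort(setdiff(genomes, unlist(clusters) %||% character()))
  list(clusters = clusters, unclustered = unclustered)
}

components_labels <- function(M) {
  n <- nrow(M)
  lab <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cid <- cid + 1L
    queue <- s; lab[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(M[v, ] != 0 & lab == 0L)
      lab[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Filter environmental contigs for network inclusion
#'
#' Keeps contigs that are at least `min_length` bp long and share at
#' least a fraction `min_shared` of their genes with some single focal
#' genome (contig-relative, inclusive thresholds).  Contigs with zero
#' genes are excluded with a warning.
#'
#' @param contigs list of [annotated_genome()] contigs.
#' @param focal list of focal [annotated_genome()] objects.
#' @param pairs homolog pairs from [call_homologs()] computed
#'   contigs-vs-focal.
#' @param min_length minimum contig length in bp (default 20000).
#' @param min_shared minimum shared-gene fraction (default 0.20).
#' @return the retained subset of `contigs`.
#' @export
filter_env_contigs <- function(contigs, focal, pairs, min_length = 20000,
                               min_shared = 0.20) {
  focal_ids <- vapply(focal, function(g) g$genome_id, character(1))
  keep <- vapply(contigs, function(ct) {
    if (!nrow(ct$genes)) {
      warning("contig ", ct$genome_id, " has 0 genes; excluded")
      return(FALSE)
    }
    if (genome_length(ct) < min_length) return(FALSE)
    fr <- vapply(focal_ids, function(f)
      length(genes_with_homolog(ct$genome_id, f, pairs)) / nrow(ct$genes),
      numeric(1))
    any(fr >= min_shared)
  }, logical(1))
  contigs[keep]
}
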