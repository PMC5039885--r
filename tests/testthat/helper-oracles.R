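# Independent brute-force oracles and tiny in-code fixtures. The oracles are
# deliberately naive (dense matrices, explicit loops) so they share no code
# path with the package implementation.

# Edge-clustering-coefficient weights by explicit common-neighbour counting
# on a dense adjacency matrix.
oracle_pil_weights <- function(edges, universe) {
  n <- length(universe)
  adj <- matrix(FALSE, n, n, dimnames = list(universe, universe))
  for (r in seq_len(nrow(edges))) {
    a <- edges$protein_a[r]; b <- edges$protein_b[r]
    adj[a, b] <- TRUE; adj[b, a] <- TRUE
  }
  out <- list()
  for (r in seq_len(nrow(edges))) {
    a <- edges$protein_a[r]; b <- edges$protein_b[r]
    na <- sum(adj[a, ]); nb <- sum(adj[b, ])
    if (na <= 1 || nb <= 1) next
    common <- 0
    for (k in seq_len(n)) if (adj[a, k] && adj[b, k]) common <- common + 1
    w <- common^2 / ((na - 1) * (nb - 1))
    if (w > 0) out[[paste(min(a, b), max(a, b))]] <- w
  }
  out
}

# Naive composite scoring: dense per-layer weighted adjacency, row
# normalization, then an explicit triple loop over layers, neighbours and
# terms.
oracle_composite <- function(net, query, ann_sets, ic = 2^(-seq_along(net$layers))) {
  universe <- net$universe
  n <- length(universe)
  scores <- list()
  for (li in seq_along(net$layers)) {
    layer <- net$layers[[li]]
    W <- matrix(0, n, n, dimnames = list(universe, universe))
    for (r in seq_len(nrow(layer))) {
      a <- layer$protein_a[r]; b <- layer$protein_b[r]
      W[a, b] <- layer$weight[r]; W[b, a] <- layer$weight[r]
    }
    rs <- sum(W[query, ])
    if (rs == 0) next
    for (p in universe) {
      if (W[query, p] == 0) next
      w <- W[query, p] / rs
      for (f in ann_sets[[p]]) {
        prev <- if (is.null(scores[[f]])) 0 else scores[[f]]
        scores[[f]] <- prev + ic[li] * w
      }
    }
  }
  out <- unlist(scores)
  if (is.null(out)) out <- setNames(numeric(0), character(0))
  out
}

# A small random dataset wired through the real generator.
small_synth <- function(seed, n = 20) {
  random_mpn(n_proteins = n, n_terms = 6, terms_per_protein = 1:2,
             ppi_density = 0.15, n_domains = 8, domain_size = 2:3,
             n_complexes = 6, complex_size = 2:3, p_share = 0.5, seed = seed)
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

with_seed_sample <- function(seed, x, n) {
  withr::with_seed(seed + 1000L, sample(x, min(n, length(x))))
}
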