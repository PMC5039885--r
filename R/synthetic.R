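# Deterministic fixtures: the five-function worked-example network, and
# parameterized random multilayer networks with planted function structure
# (co-annotated proteins preferentially share edges, domains and
# complexes), so the whole pipeline can be exercised without external
# downloads.

#' Worked-example fixture: one query protein over three layers
#'
#' Builds the small multilayer network used to illustrate the scoring
#' arithmetic: query protein `A` has one shared-complex neighbour annotated
#' `{f3, f4}` (normalized weight 1), two shared-domain neighbours with
#' normalized weights 0.28 (annotated `{f1, f2}`) and 0.72 (annotated
#' `{f3, f4}`), and two equally weighted physical-interaction neighbours
#' annotated `{f1, f2, f5}` and `{f3, f4}`. The resulting per-layer scores
#' are SCL `f3 = f4 = 1`; SDL `f1 = f2 = 0.28`, `f3 = f4 = 0.72`; PIL
#' `f1 ... f5 = 0.5` each, and the composite scores under the
#' `1/2^i` schedule are `f3 = f4 = 0.7425`, `f1 = f2 = 0.1325`,
#' `f5 = 0.0625`. The fixture is specified at the level of these normalized
#' per-layer scores; the raw edge weights chosen here are one concrete
#' realization that row-normalizes to them.
#'
#' @return A list with elements `net` (multilayer network), `tensor`
#'   (normalized view), `ann` (annotation map of the neighbours, aspect BP),
#'   `truth` (character vector: the query's held-out annotations `f3`, `f4`)
#'   and `query` (`"A"`).
#' @export
fig5_fixture <- function() {
  universe <- c("A", "B", "C", "D", "E", "F")
  scl <- new_layer(tibble(protein_a = "A", protein_b = "B", weight = 1),
                   "SCL", universe)
  sdl <- new_layer(tibble(protein_a = c("A", "A"), protein_b = c("C", "D"),
                          weight = c(0.28, 0.72)),
                   "SDL", universe)
  pil <- new_layer(tibble(protein_a = c("A", "A"), protein_b = c("E", "F"),
                          weight = c(0.5, 0.5)),
                   "PIL", universe)
  net <- assemble(list(scl, sdl, pil), order = c("SCL", "SDL", "PIL"))
  ann <- annotation_map(
    tibble(protein = c("B", "B", "C", "C", "D", "D", "E", "E", "E", "F", "F"),
           term = c("f3", "f4", "f1", "f2", "f3", "f4", "f1", "f2", "f5", "f3", "f4")),
    aspect = "BP", proteins = universe)
  list(net = net, tensor = normalize_tensor(net), ann = ann,
       truth = c("f3", "f4"), query = "A")
}

#' Generate a random multilayer network with planted function structure
#'
#' Each protein receives a small random set of GO terms. Interactions,
#' domain groups and complexes are then generated with a planted
#' label-assortativity dial `p_share`: with probability `p_share` an
#' interaction is drawn between two co-annotated proteins (and a domain or
#' complex group is drawn from the carriers of a single term), otherwise
#' uniformly at random. At `p_share = 0` the layers carry no functional
#' signal; at `p_share = 1` every connection joins proteins sharing a term,
#' so with one term per protein every annotated neighbour carries the
#' query's own term and leave-one-out recall on predicted proteins is forced
#' to 1. Generation is a pure function of `seed`.
#'
#' @param n_proteins Number of proteins.
#' @param n_terms Number of distinct GO terms.
#' @param terms_per_protein Integer vector of allowed annotation-set sizes
#'   (sampled uniformly per protein).
#' @param ppi_density Expected fraction of protein pairs that interact.
#' @param n_domains,domain_size Number of domain groups and allowed group
#'   sizes.
#' @param n_complexes,complex_size Number of complexes and allowed sizes.
#' @param p_share Probability in `[0, 1]` that an edge / group is planted on
#'   co-annotated proteins.
#' @param seed Integer seed (mandatory).
#' @return A list with elements `universe`, `edges`, `domains`, `complexes`,
#'   `ann` - the parsed-input containers consumed by [build_pil()],
#'   [build_sdl()], [build_scl()] and the evaluation harness.
#' @export
random_mpn <- function(n_proteins = 200, n_terms = 20, terms_per_protein = 1:3,
                       ppi_density = 0.03, n_domains = 60, domain_size = 2:4,
                       n_complexes = 40, complex_size = 2:5,
                       p_share = 0.5, seed) {
  stopifnot(p_share >= 0, p_share <= 1, n_proteins >= 3, n_terms >= 2)
  if (missing(seed)) abort("`seed` is mandatory")
  with_rng(seed, {
    universe <- sprintf("P%04d", seq_len(n_proteins))
    terms <- sprintf("T%03d", seq_len(n_terms))
    sets <- lapply(seq_len(n_proteins), function(i) {
      k <- if (length(terms_per_protein) == 1L) terms_per_protein else sample(terms_per_protein, 1L)
      sort(sample(terms, min(k, n_terms)))
    })
    names(sets) <- universe
    ann <- annotation_map(tibble(protein = rep(universe, lengths(sets)),
                                 term = unlist(sets)),
                          aspect = "BP", proteins = universe)
    carriers <- split(rep(universe, lengths(sets)), unlist(sets))
    shared_pool <- names(carriers)[lengths(carriers) >= 2L]
    if (p_share > 0 && length(shared_pool) == 0L) {
      abort("infeasible: p_share > 0 but no two proteins share a term")
    }
    draw_shared_pair <- function() {
      t <- sample(shared_pool, 1L)
      sample(carriers[[t]], 2L)
    }
    n_edges <- round(ppi_density * n_proteins * (n_proteins - 1) / 2)
    seen <- character(0)
    ea <- character(0)
    eb <- character(0)
    guard <- 0L
    while (length(ea) < n_edges && guard < 50L * n_edges) {
      guard <- guard + 1L
      pair <- if (stats::runif(1) < p_share) draw_shared_pair() else sample(universe, 2L)
      key <- paste(min(pair), max(pair), sep = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      ea <- c(ea, min(pair))
      eb <- c(eb, max(pair))
    }
    edges <- new_edge_list(tibble(protein_a = ea, protein_b = eb), universe)
    draw_group <- function(size_range) {
      s <- if (length(size_range) == 1L) size_range else sample(size_range, 1L)
      if (stats::runif(1) < p_share) {
        t <- sample(shared_pool, 1L)
        pool <- carriers[[t]]
        sample(pool, min(s, length(pool)))
      } else {
        sample(universe, min(s, n_proteins))
      }
    }
    dom_groups <- lapply(seq_len(n_domains), function(i) draw_group(domain_size))
    domains <- structure(
      distinct(tibble(protein = unlist(dom_groups),
                      domain = rep(sprintf("PF%05d", seq_len(n_domains)),
                                   lengths(dom_groups)))),
      universe = universe, class = c("fpmpn_domains", class(tibble())))
    cpx_groups <- lapply(seq_len(n_complexes), function(i) draw_group(complex_size))
    cpx_groups <- cpx_groups[lengths(cpx_groups) >= 2L]
    complexes <- structure(
      tibble(complex = rep(sprintf("cpx%d", seq_along(cpx_groups)),
                           lengths(cpx_groups)),
             protein = unlist(cpx_groups)),
      universe = universe, class = c("fpmpn_complexes", class(tibble())))
    list(universe = universe, edges = edges, domains = domains,
         complexes = complexes, ann = ann)
  })
}

#' Assemble a synthetic dataset into a multilayer network
#'
#' Convenience wrapper: builds the three layers from a [random_mpn()] result
#' and assembles them in the given access order.
#'
#' @param synth A list as returned by [random_mpn()].
#' @param order Layer access order (default SCL, SDL, PIL).
#' @return A multilayer network.
#' @export
synthetic_network <- function(synth, order = c("SCL", "SDL", "PIL")) {
  assemble(list(build_scl(synth$complexes, synth$universe),
                build_sdl(synth$domains, synth$universe),
                build_pil(synth$edges, synth$universe)),
           order = order)
}

#' Write a synthetic dataset as the four input files
#'
#' Files are written in the dialects the readers expect: `ppi.tsv`,
#' `domains.tsv`, `complexes.tsv`, `annotations.tsv`.
#'
#' @param synth A list from [random_mpn()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ppi_edges(synth$edges, file.path(dir, "ppi.tsv"))
  write_domains(synth$domains, file.path(dir, "domains.tsv"))
  write_complexes(synth$complexes, file.path(dir, "complexes.tsv"))
  write_annotations(synth$ann, file.path(dir, "annotations.tsv"))
  invisible(dir)
}
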