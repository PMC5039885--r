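# Construction of the three weighted layers and their assembly into a
# multilayer protein network with a row-normalized tensor view.
#
# All three weighting schemes are squared-overlap similarities, so every
# stored weight lies in (0, 1]: |X  Y|^2 <= |X| * |Y| for the domain and
# complex layers, and for adjacent nodes |N_i  N_j| <= min(|N_i| - 1,
# |N_j| - 1) for the edge clustering coefficient. Zero-weight pairs are never
# stored.

new_layer <- function(pairs, layer_id, universe) {
  pairs <- as_tibble(pairs)
  lo <- pmin(pairs$protein_a, pairs$protein_b)
  hi <- pmax(pairs$protein_a, pairs$protein_b)
  out <- tibble(protein_a = lo, protein_b = hi, weight = pairs$weight)
  out <- arrange(out, .data$protein_a, .data$protein_b)
  structure(out, layer_id = layer_id, universe = universe,
            class = c("fpmpn_layer", class(tibble())))
}

#' Layer identifier of a layer graph
#' @param layer A layer graph built by [build_pil()], [build_sdl()] or
#'   [build_scl()].
#' @return The layer identifier string (e.g. `"PIL"`).
#' @export
layer_id <- function(layer) attr(layer, "layer_id")

#' Build the physical-interaction layer (PIL)
#'
#' Weights each experimentally observed interaction by a variant of the edge
#' clustering coefficient: for an edge \eqn{(v_i, v_j)},
#' \eqn{W = |N_i \cap N_j|^2 / ((|N_i| - 1)(|N_j| - 1))} where \eqn{N_i} is
#' the set of direct neighbours of \eqn{v_i}. Edges where either endpoint has
#' degree 1, or with no common neighbour, receive weight 0 and are omitted;
#' the layer's support is always a subset of the input edge set.
#'
#' @param edges An edge list from [read_ppi_edges()].
#' @param universe Protein universe (defaults to the edge list's).
#' @return A layer graph: tibble of `(protein_a, protein_b, weight)`.
#' @export
build_pil <- function(edges, universe = protein_universe(edges)) {
  nbrs <- split(c(edges$protein_b, edges$protein_a),
                c(edges$protein_a, edges$protein_b))
  deg <- lengths(nbrs)
  common <- mapply(function(a, b) length(intersect(nbrs[[a]], nbrs[[b]])),
                   edges$protein_a, edges$protein_b, USE.NAMES = FALSE)
  da <- deg[edges$protein_a]
  db <- deg[edges$protein_b]
  w <- numeric(length(common))
  ok <- da > 1 & db > 1
  w[ok] <- common[ok]^2 / ((da[ok] - 1) * (db[ok] - 1))
  keep <- w > 0
  new_layer(tibble(protein_a = edges$protein_a[keep],
                   protein_b = edges$protein_b[keep],
                   weight = unname(w[keep])),
            "PIL", universe)
}

# Shared machinery for the two membership-overlap layers: connect every pair
# sharing at least one group, weighted by |G_i n G_j|^2 / (|G_i| * |G_j|).
squared_overlap_layer <- function(membership, layer_id, universe) {
  # membership: tibble(protein, group)
  sets <- split(membership$group, membership$protein)
  sizes <- lengths(sets)
  by_group <- split(membership$protein, membership$group)
  pair_rows <- lapply(by_group, function(members) {
    if (length(members) < 2L) return(NULL)
    members <- sort(members)
    idx <- utils::combn(length(members), 2L)
    tibble(protein_a = members[idx[1L, ]], protein_b = members[idx[2L, ]])
  })
  pairs <- distinct(bind_rows(pair_rows))
  if (nrow(pairs) == 0L) {
    return(new_layer(tibble(protein_a = character(), protein_b = character(),
                            weight = numeric()), layer_id, universe))
  }
  shared <- mapply(function(a, b) length(intersect(sets[[a]], sets[[b]])),
                   pairs$protein_a, pairs$protein_b, USE.NAMES = FALSE)
  w <- shared^2 / (sizes[pairs$protein_a] * sizes[pairs$protein_b])
  new_layer(tibble(protein_a = pairs$protein_a, protein_b = pairs$protein_b,
                   weight = unname(w)),
            layer_id, universe)
}

#' Build the shared-domain layer (SDL)
#'
#' Two proteins are connected if they share at least one domain type, with
#' weight \eqn{|D_i \cap D_j|^2 / (|D_i| |D_j|)} where \eqn{D_i} is the set
#' of distinct domain types of protein \eqn{v_i}.
#'
#' @param domains A domain assignment from [read_domains()].
#' @param universe Protein universe (defaults to the assignment's).
#' @return A layer graph.
#' @export
build_sdl <- function(domains, universe = protein_universe(domains)) {
  squared_overlap_layer(tibble(protein = domains$protein, group = domains$domain),
                        "SDL", universe)
}

#' Build the shared-complex layer (SCL)
#'
#' Two proteins are connected if they are members of at least one common
#' complex, with weight \eqn{|C_i \cap C_j|^2 / (|C_i| |C_j|)} where
#' \eqn{C_i} is the set of complexes containing protein \eqn{v_i}.
#'
#' @param complexes A complex catalog from [read_complexes()].
#' @param universe Protein universe (defaults to the catalog's).
#' @return A layer graph.
#' @export
build_scl <- function(complexes, universe = protein_universe(complexes)) {
  squared_overlap_layer(tibble(protein = complexes$protein, group = complexes$complex),
                        "SCL", universe)
}

#' Assemble weighted layers into a multilayer protein network
#'
#' The access order of the layers is part of the network: layer 1 is visited
#' first during prediction and carries the largest importance coefficient.
#' The default order SCL, SDL, PIL follows the ranking of the layers by their
#' standalone predictive power (see [determine_layer_order()]).
#'
#' @param layers A list of layer graphs (in any order).
#' @param order Character vector: a permutation of the layer identifiers
#'   giving the access order. Defaults to `SCL, SDL, PIL` restricted to the
#'   identifiers present, followed by any additional layers.
#' @return A multilayer network: list with elements `universe` and `layers`
#'   (named list of layer graphs in access order).
#' @export
assemble <- function(layers, order = NULL) {
  ids <- vapply(layers, layer_id, "")
  if (anyDuplicated(ids)) abort("duplicate layer identifiers")
  names(layers) <- ids
  if (is.null(order)) {
    order <- c(intersect(c("SCL", "SDL", "PIL"), ids), setdiff(ids, c("SCL", "SDL", "PIL")))
  }
  if (anyDuplicated(order) || !setequal(order, ids)) {
    abort("`order` must be a permutation of the layer identifiers")
  }
  universes <- unique(lapply(layers, protein_universe))
  if (length(universes) != 1L) abort("all layers must share the same universe")
  structure(list(universe = universes[[1L]], layers = layers[order]),
            class = "fpmpn_mpn")
}

#' @export
print.fpmpn_mpn <- function(x, ...) {
  cat(sprintf("Multilayer protein network: %d proteins, %d layers (%s)\n",
              length(x$universe), length(x$layers),
              paste(names(x$layers), collapse = " > ")))
  for (id in names(x$layers)) {
    cat(sprintf("  %s: %d weighted connections\n", id, nrow(x$layers[[id]])))
  }
  invisible(x)
}

#' Row-normalize a multilayer network into its tensor view
#'
#' Divides every row of each layer's weighted adjacency matrix by its row
#' sum, so each row sums to exactly 1 (proteins with at least one connection
#' on the layer) or 0 (isolated proteins). The sparsity pattern is unchanged.
#'
#' @param net A multilayer network from [assemble()].
#' @return A normalized tensor: list with elements `universe` and `layers`
#'   (named list of row-normalized sparse matrices in access order).
#' @export
normalize_tensor <- function(net) {
  n <- length(net$universe)
  mats <- lapply(net$layers, function(layer) {
    i <- match(layer$protein_a, net$universe)
    j <- match(layer$protein_b, net$universe)
    m <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                              x = c(layer$weight, layer$weight),
                              dims = c(n, n),
                              dimnames = list(net$universe, net$universe))
    rs <- Matrix::rowSums(m)
    scale <- ifelse(rs > 0, 1 / rs, 0)
    out <- Matrix::Diagonal(x = scale) %*% m
    dimnames(out) <- dimnames(m)
    methods::as(out, "CsparseMatrix")
  })
  structure(list(universe = net$universe, layers = mats), class = "fpmpn_tensor")
}

#' Serialize / load a multilayer network as a directory of TSV files
#'
#' Each layer is written as a weighted edge TSV (`protein_a`, `protein_b`,
#' `weight`, `layer`); a `manifest.tsv` records the universe order and the
#' layer access order.
#'
#' @param net A multilayer network.
#' @param dir Directory to write into (created if needed).
#' @return `dir` (or, for `read_mpn`, the network), invisibly.
#' @export
write_mpn <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(net$layers)) {
    layer <- net$layers[[id]]
    df <- data.frame(protein_a = layer$protein_a, protein_b = layer$protein_b,
                     weight = sprintf("%.15g", layer$weight), layer = id)
    write.table(df, file.path(dir, paste0("layer_", id, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = TRUE)
  }
  manifest <- data.frame(
    key = c(rep("layer", length(net$layers)), rep("protein", length(net$universe))),
    value = c(names(net$layers), net$universe))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(dir)
}

#' @rdname write_mpn
#' @export
read_mpn <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, colClasses = "character")
  order <- manifest$value[manifest$key == "layer"]
  universe <- validate_universe(manifest$value[manifest$key == "protein"])
  layers <- lapply(order, function(id) {
    df <- utils::read.table(file.path(dir, paste0("layer_", id, ".tsv")), sep = "\t",
                            header = TRUE,
                            colClasses = c("character", "character", "numeric", "character"))
    new_layer(tibble(protein_a = df$protein_a, protein_b = df$protein_b,
                     weight = df$weight), id, universe)
  })
  assemble(layers, order)
}
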