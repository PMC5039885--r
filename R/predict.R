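# Function prediction on a multilayer protein network. Layers are visited in
# access order; each layer contributes a weighted-neighbour score per GO term
# (weights taken from the row-normalized tensor), and per-layer scores are
# combined with geometrically decaying importance coefficients 1/2^i. The
# number of selected terms is bounded by the annotation count of the
# annotated neighbour with the highest raw weight across all layers.

#' Importance-coefficient schedule for layer positions
#'
#' The i-th visited layer carries importance coefficient \eqn{1/2^i}, so the
#' schedule is strictly decreasing and sums to \eqn{1 - 2^{-L} < 1}. Because
#' every per-layer score is at most 1, composite scores are guaranteed to lie
#' in \eqn{[0, 1)} and can be read as probabilities.
#'
#' @param n_layers Number of layers L.
#' @return Numeric vector of coefficients, one per layer position.
#' @export
ic_schedule <- function(n_layers) {
  stopifnot(n_layers >= 1)
  2^(-(seq_len(n_layers)))
}

# Internal per-protein adjacency index over raw and normalized weights.
# Raw weights drive the anchor-neighbour selection; normalized weights drive
# the per-layer scores.
mpn_index <- function(net, tensor = NULL) {
  if (is.null(tensor)) tensor <- normalize_tensor(net)
  stopifnot(identical(names(net$layers), names(tensor$layers)))
  universe <- net$universe
  adj <- lapply(names(net$layers), function(id) {
    layer <- net$layers[[id]]
    norm <- tensor$layers[[id]]
    nbr <- split(c(layer$protein_b, layer$protein_a),
                 factor(c(layer$protein_a, layer$protein_b), levels = universe))
    raw <- split(c(layer$weight, layer$weight),
                 factor(c(layer$protein_a, layer$protein_b), levels = universe))
    list(nbr = nbr, raw = raw, norm = norm)
  })
  names(adj) <- names(net$layers)
  list(universe = universe, order = names(net$layers), adj = adj)
}

#' Per-layer neighbour score of candidate functions
#'
#' For a query protein and one layer, scores every GO term carried by at
#' least one annotated neighbour on the layer:
#' \eqn{S(f_j) = \sum_i W(u, p_i) t_{ij}}, where \eqn{W(u, p_i)} is the
#' row-normalized weight of the connection and \eqn{t_{ij}} indicates that
#' neighbour \eqn{p_i} carries \eqn{f_j}. Since normalized weights in a row
#' sum to at most 1, \eqn{S \le 1} always.
#'
#' @param tensor A normalized tensor from [normalize_tensor()].
#' @param layer Layer identifier or 1-based position in access order.
#' @param query Protein identifier.
#' @param ann An annotation map (the query's own annotations, if present,
#'   are not masked here; mask before calling in cross-validation).
#' @return A named numeric vector, term -> score; empty if the query has no
#'   annotated neighbour on the layer.
#' @export
layer_score <- function(tensor, layer, query, ann) {
  if (!(query %in% tensor$universe)) abort(paste0("unknown query protein: ", query))
  m <- if (is.numeric(layer)) tensor$layers[[layer]] else tensor$layers[[as.character(layer)]]
  if (is.null(m)) abort("unknown layer")
  row <- m[match(query, tensor$universe), ]
  idx <- which(row > 0)
  layer_score_from_pairs(tensor$universe[idx], unname(row[idx]), annotation_sets(ann))
}

layer_score_from_pairs <- function(neighbors, weights, ann_sets) {
  scores <- numeric(0)
  for (k in seq_along(neighbors)) {
    terms <- ann_sets[[neighbors[k]]]
    if (is.null(terms)) next
    present <- terms %in% names(scores)
    scores[terms[present]] <- scores[terms[present]] + weights[k]
    if (any(!present)) {
      add <- setNames(rep(weights[k], sum(!present)), terms[!present])
      scores <- c(scores, add)
    }
  }
  scores
}

#' Combine per-layer scores into composite scores
#'
#' \eqn{Score(f) = \sum_{i=1}^{L} IC(i) S_i(f)}, with \eqn{S_i(f) = 0} when
#' the term was not scored on layer i. A term scored on several layers
#' accumulates contributions from all of them.
#'
#' @param per_layer A list (in access order) of named numeric vectors as
#'   returned by [layer_score()].
#' @param ic Importance coefficients, one per layer (default
#'   [ic_schedule()] of the list length).
#' @return A named numeric vector, term -> composite score, each in
#'   \eqn{[0, 1)}.
#' @export
composite_score <- function(per_layer, ic = ic_schedule(length(per_layer))) {
  stopifnot(length(per_layer) <= length(ic))
  terms <- sort(unique(unlist(lapply(per_layer, names))))
  out <- setNames(numeric(length(terms)), terms)
  for (i in seq_along(per_layer)) {
    s <- per_layer[[i]]
    if (length(s)) out[names(s)] <- out[names(s)] + ic[i] * s
  }
  out
}

#' Prediction-size limit from the closest annotated neighbour
#'
#' The number of functions assigned to a query is capped by the annotation
#' count of its anchor neighbour: the annotated neighbour with the highest
#' raw connection weight over all layers (raw weights are comparable across
#' layers before row normalization makes rows sum to one). Weight ties are
#' broken toward the lexicographically smaller protein identifier.
#'
#' @param net A multilayer network.
#' @param query Protein identifier.
#' @param ann An annotation map for the current aspect.
#' @return A list with `n_limit` (0 when no annotated neighbour exists on
#'   any layer) and `anchor` (protein identifier or `NA`).
#' @export
select_n <- function(net, query, ann) {
  index <- mpn_index(net, structure(list(universe = net$universe,
                                         layers = lapply(net$layers, function(l) NULL)),
                                    class = "fpmpn_tensor"))
  select_n_from_index(index, query, annotation_sets(ann))
}

select_n_from_index <- function(index, query, ann_sets, layers = index$order) {
  best_w <- -Inf
  anchor <- NA_character_
  for (id in layers) {
    nbr <- index$adj[[id]]$nbr[[query]]
    if (is.null(nbr) || length(nbr) == 0L) next
    w <- index$adj[[id]]$raw[[query]]
    annotated <- nbr %in% names(ann_sets)
    for (k in which(annotated)) {
      if (w[k] > best_w || (w[k] == best_w && nbr[k] < anchor)) {
        best_w <- w[k]
        anchor <- nbr[k]
      }
    }
  }
  if (is.na(anchor)) return(list(n_limit = 0L, anchor = NA_character_))
  list(n_limit = length(ann_sets[[anchor]]), anchor = anchor)
}

predict_core <- function(index, query, ann_sets, ic) {
  per_layer <- lapply(index$order, function(id) {
    nbr <- index$adj[[id]]$nbr[[query]]
    if (is.null(nbr) || length(nbr) == 0L) return(numeric(0))
    raw <- index$adj[[id]]$raw[[query]]
    w <- raw / sum(raw)
    layer_score_from_pairs(nbr, w, ann_sets)
  })
  names(per_layer) <- index$order
  comp <- composite_score(per_layer, ic)
  sel <- select_n_from_index(index, query, ann_sets)
  ord <- if (length(comp)) order(-comp, names(comp)) else integer(0)
  ranked_terms <- as.character(names(comp)[ord])
  ranked_scores <- as.numeric(comp[ord])
  list(per_layer = per_layer,
       terms = ranked_terms,
       scores = ranked_scores,
       n_limit = sel$n_limit,
       anchor = sel$anchor)
}

#' Predict functions for one query protein
#'
#' Visits every layer of the network in access order, scores candidate terms
#' from annotated neighbours ([layer_score()]), combines scores across layers
#' with the importance-coefficient schedule ([composite_score()]), ranks by
#' descending composite score (ties broken by ascending term identifier) and
#' selects the top `n_limit` terms ([select_n()]).
#'
#' In cross-validation the query's own annotations must be masked from `ann`
#' by the caller before prediction.
#'
#' @param net A multilayer network from [assemble()].
#' @param query Protein identifier (must be in the universe).
#' @param ann An annotation map for one GO aspect.
#' @param tensor Optional precomputed [normalize_tensor()] view of `net`.
#' @param ic Importance-coefficient schedule (default `ic_schedule()`).
#' @return A prediction result: a tibble of the ranked candidates with
#'   columns `query`, `term`, `score`, `rank`, `selected`, carrying the
#'   per-layer scores, `n_limit` and `anchor` as attributes. Use [tidy()] /
#'   [glance()] to extract them.
#' @export
predict_functions <- function(net, query, ann, tensor = NULL,
                              ic = ic_schedule(length(net$layers))) {
  if (!(query %in% net$universe)) abort(paste0("unknown query protein: ", query))
  index <- mpn_index(net, tensor)
  res <- predict_core(index, query, annotation_sets(ann), ic)
  new_prediction(query, res)
}

new_prediction <- function(query, res) {
  n <- length(res$terms)
  tb <- tibble(query = rep(query, n), term = res$terms, score = res$scores,
               rank = seq_len(n),
               selected = seq_len(n) <= res$n_limit)
  structure(tb,
            per_layer = res$per_layer,
            n_limit = res$n_limit,
            anchor = res$anchor,
            class = c("fpmpn_prediction", class(tibble())))
}

#' Selected terms of a prediction result
#' @param pred A prediction result.
#' @return Character vector of the selected top-N terms (may be empty).
#' @export
selected_terms <- function(pred) pred$term[pred$selected]

#' Neighbour-counting baseline on a single layer
#'
#' Leave-one-out neighbour counting: for each annotated protein, its own
#' annotations are masked and candidate terms are ranked by their occurrence
#' frequency among the protein's direct neighbours on this single layer
#' (ties broken by ascending term identifier). The number of selected terms
#' follows the same anchor rule as the full method, restricted to this
#' layer: the annotation count of the highest-raw-weight annotated
#' neighbour.
#'
#' @param layer A layer graph.
#' @param ann An annotation map.
#' @return A tibble of predictions: `protein`, `term`, `freq`, `rank`,
#'   `selected`.
#' @export
nc_layer_baseline <- function(layer, ann) {
  universe <- protein_universe(layer)
  nbr <- split(c(layer$protein_b, layer$protein_a),
               factor(c(layer$protein_a, layer$protein_b), levels = universe))
  wts <- split(c(layer$weight, layer$weight),
               factor(c(layer$protein_a, layer$protein_b), levels = universe))
  sets <- annotation_sets(ann)
  rows <- list()
  for (p in intersect(names(sets), universe)) {
    neighbors <- nbr[[p]]
    if (length(neighbors) == 0L) next
    masked <- sets[setdiff(names(sets), p)]
    annotated <- neighbors %in% names(masked)
    if (!any(annotated)) next
    freq <- sort(table(unlist(masked[neighbors[annotated]])), decreasing = TRUE)
    terms <- names(freq)
    ord <- order(-as.integer(freq), terms)
    terms <- terms[ord]
    freq <- as.integer(freq)[ord]
    w <- wts[[p]][annotated]
    na <- neighbors[annotated]
    best <- order(-w, na)[1L]
    n_limit <- length(masked[[na[best]]])
    rows[[p]] <- tibble(protein = p, term = terms, freq = freq,
                        rank = seq_along(terms),
                        selected = seq_along(terms) <= n_limit)
  }
  if (length(rows) == 0L) {
    return(tibble(protein = character(), term = character(), freq = integer(),
                  rank = integer(), selected = logical()))
  }
  bind_rows(rows)
}

#' Annotation bookkeeping per layer
#'
#' For each layer, counts the proteins with at least one neighbour on the
#' layer, how many of those carry at least one annotation in the current
#' aspect, and the corresponding percentage - the statistic used to motivate
#' the layer access order.
#'
#' @param net A multilayer network.
#' @param ann An annotation map.
#' @return A tibble with columns `layer`, `n_with_neighbors`, `n_annotated`,
#'   `pct_annotated`.
#' @export
layer_annotation_stats <- function(net, ann) {
  annotated <- unique(ann$protein)
  bind_rows(lapply(names(net$layers), function(id) {
    layer <- net$layers[[id]]
    with_nbr <- unique(c(layer$protein_a, layer$protein_b))
    n_ann <- sum(with_nbr %in% annotated)
    tibble(layer = id,
           n_with_neighbors = length(with_nbr),
           n_annotated = n_ann,
           pct_annotated = annotated_proportion(n_ann, length(with_nbr)))
  }))
}

#' Percentage of annotated proteins among those with neighbours
#'
#' @param n_annotated,n_with_neighbors Counts.
#' @return The percentage `100 * n_annotated / n_with_neighbors` (0 when the
#'   denominator is 0).
#' @export
annotated_proportion <- function(n_annotated, n_with_neighbors) {
  ifelse(n_with_neighbors > 0, 100 * n_annotated / n_with_neighbors, 0)
}

#' Data-driven layer access order
#'
#' Runs the leave-one-out neighbour-counting baseline on every layer
#' independently, evaluates each with macro-averaged precision and recall,
#' and orders layers by F-measure descending (ties by annotated-protein
#' count descending, then layer identifier). Layers on which no protein is
#' predictable are placed last.
#'
#' @param net A multilayer network.
#' @param ann An annotation map.
#' @return A tibble of per-layer statistics (`layer`, `n_proteins`,
#'   `precision`, `recall`, `f_measure`), sorted into the recommended access
#'   order which is also available as `attr(x, "order")`.
#' @export
determine_layer_order <- function(net, ann) {
  sets <- annotation_sets(ann)
  stats <- bind_rows(lapply(names(net$layers), function(id) {
    preds <- nc_layer_baseline(net$layers[[id]], ann)
    if (nrow(preds) == 0L) {
      inform(paste0("layer ", id, " has no predictable annotated protein; placed last"))
      return(tibble(layer = id, n_proteins = 0L,
                    precision = 0, recall = 0, f_measure = 0))
    }
    sel <- split(preds$term[preds$selected], preds$protein[preds$selected])
    proteins <- unique(preds$protein)
    counts <- bind_rows(lapply(proteins, function(p) {
      mc <- match_counts(sets[[p]], sel[[p]])
      tibble(protein = p, tp = mc[["tp"]], fp = mc[["fp"]], fn = mc[["fn"]])
    }))
    agg <- aggregate_metrics(counts)
    tibble(layer = id, n_proteins = length(proteins),
           precision = agg$precision, recall = agg$recall,
           f_measure = agg$f_measure)
  }))
  stats <- arrange(stats, desc(.data$f_measure), desc(.data$n_proteins), .data$layer)
  structure(stats, order = stats$layer,
            class = c("fpmpn_layer_order", class(tibble())))
}
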