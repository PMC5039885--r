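# Assessment protocol: per-protein match counts, macro-averaged precision /
# recall / F-measure, coverage rate, leave-one-out and k-fold
# cross-validation, precision-recall curves over top-K with AUC, FP/TP
# curves, and the function-overlap statistics.

#' Match a predicted function set against the known one
#'
#' Matching is exact term-identifier equality; no partial credit is given
#' through the GO hierarchy.
#'
#' @param known Character vector of known GO terms.
#' @param predicted Character vector of predicted GO terms.
#' @return A named integer vector with elements `tp` (predicted and known),
#'   `fp` (predicted, not known) and `fn` (known, not predicted).
#' @export
match_counts <- function(known, predicted) {
  known <- unique(known)
  predicted <- unique(predicted)
  tp <- length(intersect(known, predicted))
  c(tp = tp, fp = length(predicted) - tp, fn = length(known) - tp)
}

#' Aggregate per-protein match counts into averaged metrics
#'
#' Precision and recall are macro averages of the per-protein values over
#' proteins that received at least one prediction (optionally over all
#' proteins, counting unpredicted ones as zero); the F-measure is the
#' harmonic mean of the two averages. The coverage rate CR is the global
#' ratio \eqn{\sum_i |KF_i \cap PF_i| / \sum_i |KF_i|} over all testing
#' proteins, predicted or not, and `mp` counts proteins with at least one
#' matched function.
#'
#' @param counts A data frame with one row per testing protein and columns
#'   `tp`, `fp`, `fn`.
#' @param include_unpredicted If `TRUE`, proteins with no prediction enter
#'   the precision/recall averages with value 0 (default `FALSE`).
#' @return A one-row tibble: `n_proteins`, `n_predicted`, `mp`, `precision`,
#'   `recall`, `f_measure`, `cr`.
#' @export
aggregate_metrics <- function(counts, include_unpredicted = FALSE) {
  if (nrow(counts) == 0L) abort("empty evaluation set")
  predicted <- counts$tp + counts$fp > 0
  prec_i <- ifelse(predicted, counts$tp / pmax(counts$tp + counts$fp, 1L), 0)
  rec_i <- ifelse(counts$tp + counts$fn > 0, counts$tp / pmax(counts$tp + counts$fn, 1L), 0)
  idx <- if (include_unpredicted) rep(TRUE, nrow(counts)) else predicted
  if (!any(idx)) {
    precision <- 0
    recall <- 0
  } else {
    precision <- mean(prec_i[idx])
    recall <- mean(rec_i[idx])
  }
  tibble(n_proteins = nrow(counts),
         n_predicted = sum(predicted),
         mp = sum(counts$tp >= 1),
         precision = precision,
         recall = recall,
         f_measure = f_measure(precision, recall),
         cr = sum(counts$tp) / max(sum(counts$tp + counts$fn), 1L))
}

#' Harmonic mean of averaged precision and recall
#' @param precision,recall Averaged precision and recall.
#' @return `2 * precision * recall / (precision + recall)`, or 0 when both
#'   are 0.
#' @export
f_measure <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

#' Cross-validation fold assignment
#'
#' Leave-one-out gives every annotated protein its own fold (deterministic);
#' k-fold partitions the annotated proteins uniformly at random into k folds
#' whose sizes differ by at most one. k-fold with `k` equal to the number of
#' annotated proteins reproduces leave-one-out exactly.
#'
#' @param ann An annotation map.
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k Number of folds for `"kfold"`.
#' @param seed Integer seed (required for `"kfold"`).
#' @return A tibble with columns `protein`, `fold`.
#' @export
cv_split <- function(ann, scheme = c("loocv", "kfold"), k = 10, seed = NULL) {
  scheme <- match.arg(scheme)
  proteins <- sort(unique(ann$protein))
  if (scheme == "loocv") {
    return(tibble(protein = proteins, fold = seq_along(proteins)))
  }
  if (is.null(seed)) abort("k-fold cross-validation requires a seed")
  stopifnot(k >= 2, k <= length(proteins))
  perm <- with_rng(seed, sample.int(length(proteins)))
  fold <- rep(seq_len(k), length.out = length(proteins))[order(perm)]
  tibble(protein = proteins, fold = fold)
}

#' Run cross-validated function prediction and evaluate it
#'
#' For every fold, the testing proteins' annotations are masked from the
#' annotation map (the proteins remain network nodes), each testing protein
#' is predicted with [predict_functions()], and per-protein match counts are
#' pooled across folds into a single report with averaged metrics, the
#' precision-recall curve over top-K cutoffs with its AUC, and the FP/TP
#' curve with summary statistics. The network itself is annotation-free, so
#' masking cannot leak through the layer weights.
#'
#' @param net A multilayer network.
#' @param ann An annotation map for one aspect.
#' @param scheme,k,seed Passed to [cv_split()].
#' @param k_max Largest top-K cutoff for the curves (default 50).
#' @param ic Importance-coefficient schedule.
#' @return An evaluation report object; see [glance()], [tidy()],
#'   [autoplot.fpmpn_eval()].
#' @export
run_cv <- function(net, ann, scheme = c("loocv", "kfold"), k = 10, seed = NULL,
                   k_max = 50, ic = ic_schedule(length(net$layers))) {
  scheme <- match.arg(scheme)
  split_tb <- cv_split(ann, scheme, k = k, seed = seed)
  index <- mpn_index(net)
  sets <- annotation_sets(ann)
  pred_rows <- list()
  count_rows <- list()
  for (f in sort(unique(split_tb$fold))) {
    test_proteins <- split_tb$protein[split_tb$fold == f]
    masked <- sets[setdiff(names(sets), test_proteins)]
    for (p in test_proteins) {
      res <- predict_core(index, p, masked, ic)
      known <- sets[[p]]
      sel <- res$terms[seq_len(res$n_limit)]
      mc <- match_counts(known, sel[!is.na(sel)])
      count_rows[[p]] <- tibble(protein = p, tp = mc[["tp"]], fp = mc[["fp"]],
                                fn = mc[["fn"]])
      if (length(res$terms) > 0L) {
        pred_rows[[p]] <- tibble(protein = p, term = res$terms,
                                 score = res$scores,
                                 rank = seq_along(res$terms))
      }
    }
  }
  counts <- arrange(bind_rows(count_rows), .data$protein)
  ranked <- if (length(pred_rows)) {
    arrange(bind_rows(pred_rows), .data$protein, .data$rank)
  } else {
    tibble(protein = character(), term = character(), score = numeric(), rank = integer())
  }
  truth <- sets[sort(unique(split_tb$protein))]
  summary <- aggregate_metrics(counts)
  pr <- pr_curve_auc(ranked, truth, k_max)
  ft <- tryCatch(fptp_curve(ranked, truth, k_max),
                 error = function(e) list(curve = tibble(k = integer(), fp_total = integer(), tp_total = integer()),
                                          stats = tibble(maximum = NA_real_, minimum = NA_real_,
                                                         average = NA_real_, middle = NA_real_)))
  structure(list(aspect = annotation_aspect(ann),
                 scheme = scheme,
                 counts = counts,
                 ranked = ranked,
                 summary = summary,
                 pr_curve = pr$curve,
                 auc = pr$auc,
                 fptp_curve = ft$curve,
                 fptp_stats = ft$stats),
            class = "fpmpn_eval")
}

#' @export
print.fpmpn_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Cross-validated function prediction (%s, %s)\n", x$aspect, x$scheme))
  cat(sprintf("  proteins evaluated: %d (predicted: %d, matched: %d)\n",
              s$n_proteins, s$n_predicted, s$mp))
  cat(sprintf("  precision %.4f  recall %.4f  F-measure %.4f  CR %.4f  AUC %.4f\n",
              s$precision, s$recall, s$f_measure, s$cr, x$auc))
  invisible(x)
}

topk_counts <- function(ranked, truth, k) {
  sub <- ranked[ranked$rank <= k, , drop = FALSE]
  sel <- split(sub$term, sub$protein)
  proteins <- names(sel)
  tp <- integer(length(proteins))
  np <- integer(length(proteins))
  nk <- integer(length(proteins))
  for (i in seq_along(proteins)) {
    known <- truth[[proteins[i]]]
    tp[i] <- length(intersect(known, sel[[i]]))
    np[i] <- length(sel[[i]])
    nk[i] <- length(known)
  }
  list(proteins = proteins, tp = tp, n_pred = np, n_known = nk)
}

#' Precision-recall curve over top-K cutoffs, with AUC
#'
#' For each K from 1 to `k_max`, every protein's top-K ranked terms are taken
#' as its prediction and the macro-averaged precision and recall over
#' predicted proteins give one curve point. The AUC is computed by the
#' trapezoidal rule over the curve sorted by recall ascending, collapsing
#' duplicate recall values to their maximum precision.
#'
#' @param ranked A tibble of pooled ranked predictions with columns
#'   `protein`, `term`, `rank`.
#' @param truth Named list mapping each testing protein to its known terms.
#' @param k_max Largest cutoff (at least 2 for a non-degenerate curve).
#' @return A list with `curve` (tibble `k`, `precision`, `recall`) and
#'   `auc`.
#' @export
pr_curve_auc <- function(ranked, truth, k_max = 50) {
  stopifnot(k_max >= 1)
  points <- lapply(seq_len(k_max), function(k) {
    tc <- topk_counts(ranked, truth, k)
    if (length(tc$proteins) == 0L) {
      return(tibble(k = k, precision = 0, recall = 0))
    }
    tibble(k = k,
           precision = mean(tc$tp / pmax(tc$n_pred, 1L)),
           recall = mean(ifelse(tc$n_known > 0, tc$tp / pmax(tc$n_known, 1L), 0)))
  })
  curve <- bind_rows(points)
  list(curve = curve, auc = trapezoid_auc(curve$recall, curve$precision))
}

trapezoid_auc <- function(recall, precision) {
  if (length(recall) == 0L) return(0)
  collapsed <- vapply(split(precision, recall), max, 0)
  r <- as.numeric(names(collapsed))
  ord <- order(r)
  r <- r[ord]
  p <- unname(collapsed[ord])
  if (length(r) < 2L) return(0)
  sum(diff(r) * (head(p, -1L) + p[-1L]) / 2)
}

#' FP/TP curve over top-K cutoffs with summary statistics
#'
#' For each K, the true-positive and false-positive counts of all testing
#' proteins' top-K predictions are pooled into one (FP, TP) pair. The
#' summary statistics are the maximum, minimum, average and middle (median)
#' of the FP/TP ratios across K; cutoffs with a pooled TP of zero are
#' excluded from the ratios.
#'
#' @inheritParams pr_curve_auc
#' @return A list with `curve` (tibble `k`, `fp_total`, `tp_total`) and
#'   `stats` (one-row tibble `maximum`, `minimum`, `average`, `middle`).
#' @export
fptp_curve <- function(ranked, truth, k_max = 50) {
  stopifnot(k_max >= 1)
  curve <- bind_rows(lapply(seq_len(k_max), function(k) {
    tc <- topk_counts(ranked, truth, k)
    tibble(k = k,
           fp_total = sum(tc$n_pred - tc$tp),
           tp_total = sum(tc$tp))
  }))
  usable <- curve$tp_total > 0
  if (!any(usable)) abort("no top-K cutoff yields a pooled true positive; FP/TP statistics undefined")
  if (any(!usable)) {
    inform(sprintf("%d cutoff(s) with zero pooled TP excluded from FP/TP statistics", sum(!usable)))
  }
  ratios <- curve$fp_total[usable] / curve$tp_total[usable]
  list(curve = curve,
       stats = tibble(maximum = max(ratios), minimum = min(ratios),
                      average = mean(ratios), middle = median(ratios)))
}

#' Function-overlap score of two proteins
#'
#' \eqn{OS(u, v) = |F_u \cap F_v|^2 / (|F_u| |F_v|)} where \eqn{F_u} is the
#' function set of protein u; 0 when either set is empty.
#'
#' @param fu,fv Character vectors of GO terms.
#' @return A number in \eqn{[0, 1]}.
#' @export
overlap_score <- function(fu, fv) {
  fu <- unique(fu)
  fv <- unique(fv)
  if (length(fu) == 0L || length(fv) == 0L) return(0)
  length(intersect(fu, fv))^2 / (length(fu) * length(fv))
}

#' Distribution of pairwise function-overlap scores
#'
#' Computes the overlap score for every unordered pair of annotated proteins
#' that share at least one function and bins the positive scores. With
#' `exclude_single = TRUE`, proteins with only one function are left out
#' first - many proteins carry a single function, which forces their
#' pairwise overlaps to the extremes.
#'
#' @param ann An annotation map.
#' @param breaks Bin boundaries for intervals `(b[i], b[i+1]]` (default
#'   `0, 0.2, 0.4, 0.6, 0.8, 1`).
#' @param exclude_single Drop proteins with a single function first.
#' @return A tibble with columns `bin`, `n_pairs`, `proportion`; the
#'   proportions sum to 1.
#' @export
overlap_histogram <- function(ann, breaks = seq(0, 1, by = 0.2),
                              exclude_single = FALSE) {
  sets <- annotation_sets(ann)
  if (exclude_single) sets <- sets[lengths(sets) >= 2L]
  if (length(sets) < 2L) abort("no qualifying protein pairs")
  # pairs sharing >= 1 term, via the term -> protein inverted index
  inv <- split(rep(names(sets), lengths(sets)), unlist(sets))
  pair_rows <- lapply(inv, function(members) {
    members <- intersect(members, names(sets))
    if (length(members) < 2L) return(NULL)
    members <- sort(members)
    idx <- utils::combn(length(members), 2L)
    tibble(a = members[idx[1L, ]], b = members[idx[2L, ]])
  })
  pairs <- distinct(bind_rows(pair_rows))
  if (nrow(pairs) == 0L) abort("no qualifying protein pairs")
  os <- mapply(function(a, b) overlap_score(sets[[a]], sets[[b]]),
               pairs$a, pairs$b, USE.NAMES = FALSE)
  os <- os[os > 0]
  if (length(os) == 0L) abort("no qualifying protein pairs")
  bin <- cut(os, breaks = breaks, include.lowest = FALSE)
  tb <- table(bin)
  tibble(bin = names(tb),
         n_pairs = as.integer(tb),
         proportion = as.integer(tb) / length(os))
}
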