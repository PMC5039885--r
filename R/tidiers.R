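# broom-style accessors for the two result objects.

#' Tidy a prediction result
#'
#' @param x A prediction result from [predict_functions()].
#' @param ... Unused.
#' @return The ranked candidate tibble (`query`, `term`, `score`, `rank`,
#'   `selected`) with plain tibble class.
#' @exportS3Method generics::tidy
tidy.fpmpn_prediction <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a prediction result
#'
#' @inheritParams tidy.fpmpn_prediction
#' @return A one-row tibble: `query`, `n_candidates`, `n_limit`, `anchor`,
#'   `top_term`, `top_score`.
#' @exportS3Method generics::glance
glance.fpmpn_prediction <- function(x, ...) {
  tibble(query = if (nrow(x)) x$query[1L] else NA_character_,
         n_candidates = nrow(x),
         n_limit = attr(x, "n_limit"),
         anchor = attr(x, "anchor"),
         top_term = if (nrow(x)) x$term[1L] else NA_character_,
         top_score = if (nrow(x)) x$score[1L] else NA_real_)
}

#' Per-layer scores of a prediction result
#'
#' @param pred A prediction result.
#' @return A tibble with columns `layer`, `position`, `term`, `s` (the
#'   per-layer neighbour score before importance weighting).
#' @export
per_layer_scores <- function(pred) {
  pl <- attr(pred, "per_layer")
  empty <- tibble(layer = character(), position = integer(),
                  term = character(), s = numeric())
  bind_rows(c(list(empty), lapply(seq_along(pl), function(i) {
    s <- pl[[i]]
    if (length(s) == 0L) return(NULL)
    tibble(layer = names(pl)[i], position = i, term = names(s), s = unname(s))
  })))
}

#' Tidy an evaluation report
#'
#' @param x An evaluation report from [run_cv()].
#' @param curve Which curve to return: `"pr"` (default) or `"fptp"`.
#' @param ... Unused.
#' @return The requested curve as a tibble.
#' @exportS3Method generics::tidy
tidy.fpmpn_eval <- function(x, curve = c("pr", "fptp"), ...) {
  curve <- match.arg(curve)
  if (curve == "pr") x$pr_curve else x$fptp_curve
}

#' One-row summary of an evaluation report
#'
#' @inheritParams tidy.fpmpn_eval
#' @return A one-row tibble with the averaged metrics, coverage rate, AUC
#'   and the FP/TP summary statistics.
#' @exportS3Method generics::glance
glance.fpmpn_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble(aspect = x$aspect, scheme = x$scheme),
    x$summary,
    tibble(auc = x$auc,
           fptp_maximum = x$fptp_stats$maximum,
           fptp_minimum = x$fptp_stats$minimum,
           fptp_average = x$fptp_stats$average,
           fptp_middle = x$fptp_stats$middle))
}
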