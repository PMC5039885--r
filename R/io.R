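# Readers and writers for the four input formats. Everything downstream
# consumes only the parsed containers built here: an edge list with a frozen
# protein universe, long tibbles of domain / complex membership, and a
# per-aspect annotation map.

#' Protein universe of a parsed object
#'
#' The universe is the ordered set of protein identifiers over which all
#' layers and tensors are indexed. Ordering is the insertion order of first
#' appearance in the input, then frozen, so matrix indices are reproducible.
#'
#' @param x An object returned by one of the `read_*()` functions,
#'   [assemble()] or [normalize_tensor()].
#' @return A character vector of unique protein identifiers.
#' @export
protein_universe <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$universe)) {
    return(x$universe)
  }
  attr(x, "universe")
}

validate_universe <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) abort("protein identifiers must be unique")
  if (any(!nzchar(ids)) || anyNA(ids)) abort("protein identifiers must be non-empty")
  if (any(grepl("[[:space:]]", ids))) abort("protein identifiers must not contain whitespace")
  ids
}

new_edge_list <- function(pairs, universe) {
  structure(pairs, universe = validate_universe(universe),
            class = c("fpmpn_edges", class(tibble())))
}

#' Read a protein-protein interaction edge list
#'
#' Parses a DIP-style tab-separated export: the first two columns of each
#' line are protein identifiers, lines starting with `#` are comments.
#' Self-interactions and repeated interactions are filtered out.
#'
#' @param path Path to the TSV file.
#' @param universe Optional character vector. When `NULL` (the default) the
#'   universe grows to contain every identifier seen, in order of first
#'   appearance; otherwise edges are restricted to the supplied universe and
#'   edges touching unknown proteins are dropped with a warning.
#' @return A tibble with columns `protein_a`, `protein_b` (one row per
#'   unordered interaction, `protein_a < protein_b`), carrying the universe
#'   as an attribute retrievable with [protein_universe()].
#' @export
read_ppi_edges <- function(path, universe = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) abort(paste0("no interaction records in ", path))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf("line %d of %s has fewer than 2 columns", idx[bad[1L]], path))
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  if (is.null(universe)) {
    universe <- unique(c(rbind(a, b)))
  } else {
    universe <- validate_universe(universe)
    known <- a %in% universe & b %in% universe
    if (any(!known)) {
      warn(sprintf("dropped %d edge(s) with proteins outside the universe", sum(!known)))
      a <- a[known]
      b <- b[known]
    }
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep_edge <- lo != hi & !duplicated(paste(lo, hi, sep = "\r"))
  new_edge_list(tibble(protein_a = lo[keep_edge], protein_b = hi[keep_edge]),
                universe)
}

#' Read protein-to-domain assignments
#'
#' Two-column TSV of protein identifier and domain accession (Pfam-style).
#' Records for proteins outside the universe are skipped with a warning;
#' proteins absent from the file simply have no domains.
#'
#' @param path Path to the TSV file.
#' @param universe Character vector of protein identifiers (see
#'   [protein_universe()]).
#' @return A tibble with columns `protein`, `domain`, deduplicated, carrying
#'   the universe attribute.
#' @export
read_domains <- function(path, universe) {
  universe <- validate_universe(universe)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  out <- tibble(protein = character(), domain = character())
  if (any(keep)) {
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 2L)
    if (length(bad) > 0L) {
      abort(sprintf("line %d of %s has fewer than 2 columns", which(keep)[bad[1L]], path))
    }
    p <- vapply(fields, `[[`, "", 1L)
    d <- vapply(fields, `[[`, "", 2L)
    unknown <- !(p %in% universe)
    if (any(unknown)) {
      warn(sprintf("skipped %d domain record(s) for proteins outside the universe (e.g. %s)",
                   sum(unknown), p[unknown][1L]))
    }
    out <- distinct(tibble(protein = p[!unknown], domain = d[!unknown]))
  }
  structure(out, universe = universe,
            class = c("fpmpn_domains", class(tibble())))
}

#' Read a protein-complex catalog
#'
#' CYC2008-style format: one complex per line, tab-separated member protein
#' identifiers, optionally preceded by a complex-name column. Members outside
#' the universe are dropped; complexes left with fewer than two members are
#' discarded.
#'
#' @param path Path to the file.
#' @param universe Character vector of protein identifiers.
#' @param has_names If `TRUE` the first column of each line is a complex
#'   identifier; otherwise complexes are numbered `cpx1`, `cpx2`, ... in file
#'   order.
#' @return A tibble with columns `complex`, `protein` (one row per
#'   membership), carrying the universe attribute.
#' @export
read_complexes <- function(path, universe, has_names = FALSE) {
  universe <- validate_universe(universe)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- list()
  n_dropped <- 0L
  cid <- 0L
  for (line in lines[keep]) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    cid <- cid + 1L
    if (has_names) {
      name <- fields[1L]
      members <- fields[-1L]
    } else {
      name <- paste0("cpx", cid)
      members <- fields
    }
    members <- unique(members[members %in% universe])
    if (length(members) < 2L) {
      n_dropped <- n_dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble(complex = name, protein = members)
  }
  if (n_dropped > 0L) {
    inform(sprintf("dropped %d complex(es) with fewer than 2 members in the universe", n_dropped))
  }
  out <- if (length(rows)) bind_rows(rows) else tibble(complex = character(), protein = character())
  structure(out, universe = universe,
            class = c("fpmpn_complexes", class(tibble())))
}

new_annotation_map <- function(records, aspect, proteins) {
  records <- as_tibble(records)[, c("protein", "term")]
  records$protein <- unname(as.character(records$protein))
  records$term <- unname(as.character(records$term))
  records <- distinct(records)
  records <- arrange(records, .data$protein, .data$term)
  structure(records, aspect = aspect,
            proteins = unique(c(proteins, records$protein)),
            class = c("fpmpn_annotations", class(tibble())))
}

#' Build an annotation map from a protein/term table
#'
#' @param records A data frame with columns `protein` and `term`.
#' @param aspect One of `"BP"`, `"MF"`, `"CC"`.
#' @param proteins Optional character vector of proteins known to the map
#'   even if unannotated (kept so that term filtering can leave a protein
#'   with an empty set without forgetting it).
#' @return An annotation map: a tibble of `(protein, term)` rows with the
#'   aspect and protein roster as attributes.
#' @export
annotation_map <- function(records, aspect = c("BP", "MF", "CC"), proteins = NULL) {
  aspect <- match.arg(aspect)
  new_annotation_map(records, aspect, proteins)
}

#' Read GO annotations
#'
#' Accepts either GAF 2.x (columns 2, 4, 5 and 9: object identifier,
#' qualifier, GO identifier, aspect letter) or a plain three-column TSV of
#' protein, GO term, aspect. Only records of the requested aspect are kept;
#' GAF records with a `NOT` qualifier are dropped. Aspect letters map
#' P to BP, F to MF, C to CC.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @param aspect One of `"BP"`, `"MF"`, `"CC"`.
#' @return An annotation map (see [annotation_map()]).
#' @export
read_annotations <- function(path, format = c("tsv", "gaf"), aspect = c("BP", "MF", "CC")) {
  format <- match.arg(format)
  aspect <- match.arg(aspect)
  aspect_letters <- c(P = "BP", F = "MF", C = "CC")
  lines <- readLines(path)
  keep <- !grepl("^[!#]", lines) & nzchar(trimws(lines))
  records <- tibble(protein = character(), term = character())
  if (any(keep)) {
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    if (format == "tsv") {
      bad <- which(lengths(fields) < 3L)
      if (length(bad) > 0L) {
        abort(sprintf("line %d of %s has fewer than 3 columns", which(keep)[bad[1L]], path))
      }
      p <- vapply(fields, `[[`, "", 1L)
      g <- vapply(fields, `[[`, "", 2L)
      a <- vapply(fields, `[[`, "", 3L)
    } else {
      bad <- which(lengths(fields) < 9L)
      if (length(bad) > 0L) {
        abort(sprintf("line %d of %s has fewer than 9 columns (GAF 2.x)", which(keep)[bad[1L]], path))
      }
      p <- vapply(fields, `[[`, "", 2L)
      qualifier <- vapply(fields, `[[`, "", 4L)
      g <- vapply(fields, `[[`, "", 5L)
      a_letter <- vapply(fields, `[[`, "", 9L)
      negated <- grepl("(^|\\|)NOT($|\\|)", qualifier)
      a <- unname(aspect_letters[a_letter])
      unknown <- is.na(a) & !negated
      if (any(unknown)) {
        warn(sprintf("skipped %d record(s) with unknown aspect letter", sum(unknown)))
      }
      keep_rec <- !negated & !is.na(a)
      p <- p[keep_rec]; g <- g[keep_rec]; a <- a[keep_rec]
    }
    if (format == "tsv") {
      a <- ifelse(a %in% names(aspect_letters), unname(aspect_letters[a]), a)
      unknown <- !(a %in% c("BP", "MF", "CC"))
      if (any(unknown)) {
        warn(sprintf("skipped %d record(s) with unknown aspect", sum(unknown)))
        p <- p[!unknown]; g <- g[!unknown]; a <- a[!unknown]
      }
    }
    records <- tibble(protein = p[a == aspect], term = g[a == aspect])
  }
  new_annotation_map(records, aspect, proteins = NULL)
}

#' Restrict an annotation map to terms of intermediate specificity
#'
#' Terms annotating very few proteins are too specific to transfer and terms
#' annotating very many are too general to be informative; only terms
#' annotating between `min_count` and `max_count` proteins (inclusive) are
#' kept. Proteins whose annotation set becomes empty stay in the map's
#' protein roster as unannotated proteins.
#'
#' @param ann An annotation map.
#' @param min_count,max_count Inclusive bounds on the number of proteins a
#'   retained term annotates (defaults 10 and 200).
#' @return A filtered annotation map.
#' @export
filter_terms <- function(ann, min_count = 10, max_count = 200) {
  stopifnot(min_count >= 1, max_count >= min_count)
  counts <- table(ann$term)
  keep_terms <- names(counts)[counts >= min_count & counts <= max_count]
  new_annotation_map(ann[ann$term %in% keep_terms, , drop = FALSE],
                     annotation_aspect(ann), attr(ann, "proteins"))
}

#' Aspect of an annotation map
#' @param ann An annotation map.
#' @return `"BP"`, `"MF"` or `"CC"`.
#' @export
annotation_aspect <- function(ann) attr(ann, "aspect")

#' Per-protein annotation sets
#'
#' @param ann An annotation map.
#' @return A named list mapping each annotated protein to its sorted
#'   character vector of GO term identifiers.
#' @export
annotation_sets <- function(ann) {
  split(ann$term, ann$protein)
}

#' Per-term protein sets (transpose of [annotation_sets()])
#' @param ann An annotation map.
#' @return A named list mapping each term to the proteins it annotates.
#' @export
term_sets <- function(ann) {
  split(ann$protein, ann$term)
}

restrict_annotations <- function(ann, universe) {
  new_annotation_map(ann[ann$protein %in% universe, , drop = FALSE],
                     annotation_aspect(ann),
                     intersect(attr(ann, "proteins"), universe))
}

mask_annotations <- function(ann, proteins) {
  new_annotation_map(ann[!(ann$protein %in% proteins), , drop = FALSE],
                     annotation_aspect(ann), attr(ann, "proteins"))
}

# ---- writers ---------------------------------------------------------------

#' Write an edge list / annotation map back to its input dialect
#'
#' @param x The object to serialize.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ppi_edges <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ppi_edges
#' @export
write_annotations <- function(x, path) {
  df <- data.frame(protein = x$protein, term = x$term,
                   aspect = annotation_aspect(x))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ppi_edges
#' @export
write_domains <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ppi_edges
#' @export
write_complexes <- function(x, path) {
  lines <- vapply(split(x$protein, x$complex)[unique(x$complex)],
                  paste, "", collapse = "\t")
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write ranked predictions as TSV
#'
#' Columns: query, term, composite score (12 decimal places), rank, selected
#' flag, anchor neighbour and its annotation count.
#'
#' @param pred A prediction result (see [predict_functions()]) or a tibble of
#'   pooled predictions.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  tb <- tidy(pred)
  tb$score <- sprintf("%.12f", tb$score)
  write.table(as.data.frame(tb), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an evaluation report as flat key=value lines
#'
#' @param report An evaluation report (see [run_cv()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  g <- glance(report)
  writeLines(sprintf("%s=%s", names(g), vapply(g, format, "", digits = 12)), path)
  invisible(path)
}
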