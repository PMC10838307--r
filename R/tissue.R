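# Histology scoring: marker-status calling from DAB optical density,
# ideal-reference derivation, the per-cell senescence score (CSS) and the
# per-sample tissue senescence score (TSS).

#' Call marker status from DAB nuclear mean intensity
#'
#' Cells are marker-positive (e.g. p21-positive) when their DAB nuclear
#' mean optical density strictly exceeds the threshold (default 0.2).
#'
#' @param cells Tissue cell table with a `dab_od_mean` column.
#' @param threshold OD cutoff (default 0.2, strict `>`).
#' @param column Name of the intensity column.
#' @return Integer vector (1 = positive, 0 = negative), one per row.
#' @export
classify_marker_status <- function(cells, threshold = 0.2,
                                   column = "dab_od_mean") {
  if (!column %in% names(cells) || all(is.na(cells[[column]]))) {
    stop("DAB intensity column '", column, "' is missing", call. = FALSE)
  }
  if (anyNA(cells[[column]])) {
    stop("DAB intensity contains missing values", call. = FALSE)
  }
  assert_scalar_number(threshold, "threshold")
  as.integer(cells[[column]] > threshold)
}

#' Derive the ideal normal / senescent reference pair
#'
#' The ideal normal cell `P^N` is the per-feature mean over all
#' marker-negative cells; the ideal senescent cell `P^S` is the per-feature
#' mean over the `top_k` marker-positive cells ranked by DAB intensity
#' (descending; ties broken by cell id so the derivation is
#' order-invariant). Each feature's weight is
#' `w_i = |P^N_i / P^S_i| / sum_j |P^N_j / P^S_j|`, so the weights sum to 1.
#'
#' @param cells Tissue cell table (tissue6 features + `dab_od_mean`).
#' @param status Optional 0/1 marker status per row; derived with
#'   [classify_marker_status()] when omitted.
#' @param top_k Number of top-ranked positive cells (default 100).
#' @param feature_set Schema (default tissue6).
#' @param id_column Tie-break id column (default `"cell_id"`; row order
#'   is used when absent).
#' @return An object of class `ideal_reference`: list with `p_normal`,
#'   `p_senescent`, `weights` (all named over the schema), `n_negative`,
#'   `top_k`, `feature_set`.
#' @export
derive_ideal_reference <- function(cells, status = NULL, top_k = 100L,
                                   feature_set = "tissue6",
                                   id_column = "cell_id") {
  fset <- as_feature_set(feature_set)
  validate_feature_columns(cells, fset)
  assert_scalar_number(top_k, "top_k", lower = 1)
  status <- status %||% classify_marker_status(cells)
  if (length(status) != nrow(cells)) {
    stop("status must have one value per cell", call. = FALSE)
  }
  pos <- which(status == 1)
  neg <- which(status == 0)
  if (length(pos) < top_k) {
    stop("need at least ", top_k, " marker-positive cells, have ",
         length(pos), call. = FALSE)
  }
  if (length(neg) < 1L) {
    stop("need at least one marker-negative cell", call. = FALSE)
  }
  ids <- if (id_column %in% names(cells)) cells[[id_column]] else
    seq_len(nrow(cells))
  ord <- pos[order(-cells$dab_od_mean[pos], ids[pos])]
  top <- ord[seq_len(top_k)]
  p_n <- colMeans(cells[neg, fset$features, drop = FALSE])
  p_s <- colMeans(cells[top, fset$features, drop = FALSE])
  new_ideal_reference(p_n, p_s, fset,
                      n_negative = length(neg), top_k = as.integer(top_k))
}

new_ideal_reference <- function(p_normal, p_senescent, fset,
                                n_negative = NA_integer_,
                                top_k = NA_integer_) {
  fset <- as_feature_set(fset)
  p_normal <- p_normal[fset$features]
  p_senescent <- p_senescent[fset$features]
  if (anyNA(p_normal) || anyNA(p_senescent)) {
    stop("reference values missing for some features", call. = FALSE)
  }
  degen <- fset$features[p_senescent == p_normal]
  if (length(degen) > 0L) {
    stop("degenerate reference: P^S equals P^N for ",
         paste(degen, collapse = ", "), call. = FALSE)
  }
  if (any(p_senescent == 0)) {
    stop("degenerate reference: P^S is zero for some feature", call. = FALSE)
  }
  w <- abs(p_normal / p_senescent)
  w <- w / sum(w)
  structure(list(p_normal = p_normal, p_senescent = p_senescent,
                 weights = w, feature_set = fset,
                 n_negative = n_negative, top_k = top_k),
            class = "ideal_reference")
}

#' Construct an ideal reference pair from explicit values
#'
#' @param p_normal,p_senescent Named numeric vectors of per-feature ideal
#'   values; `P^S_i` must differ from `P^N_i` for every feature.
#' @param feature_set Schema (default tissue6).
#' @return An `ideal_reference`.
#' @export
ideal_reference <- function(p_normal, p_senescent, feature_set = "tissue6") {
  new_ideal_reference(p_normal, p_senescent, feature_set)
}

#' @export
print.ideal_reference <- function(x, ...) {
  cat("<ideal_reference>", format(x$feature_set), "\n")
  print(round(rbind(P_N = x$p_normal, P_S = x$p_senescent,
                    weight = x$weights), 4))
  invisible(x)
}

#' Per-cell senescence score (CSS)
#'
#' Scores each cell's nuclear features against the ideal reference pair:
#' `CSS = sum_i w_i * (p_i - P^N_i) / (P^S_i - P^N_i)` with normalized
#' weights `w_i = |P^N_i / P^S_i| / sum_j |P^N_j / P^S_j|`. A cell exactly
#' at the ideal normal reference scores 0, at the ideal senescent
#' reference 1; more extreme senescence-like features score above 1 (the
#' score is unbounded in both directions).
#'
#' `literal = TRUE` instead evaluates the printed composition of the
#' scoring formula (per-feature terms divided by the summed absolute
#' reference differences and twice by the feature count); it does not meet
#' the 0/1 endpoint contract and is kept for comparison only.
#'
#' @param cells Tissue cell table (or a single named feature vector).
#' @param reference An `ideal_reference`.
#' @param literal Use the literal printed composition (default `FALSE`).
#' @return Numeric CSS per cell.
#' @export
cell_senescence_score <- function(cells, reference, literal = FALSE) {
  stopifnot(inherits(reference, "ideal_reference"))
  fset <- reference$feature_set
  if (is.numeric(cells) && !is.null(names(cells))) {
    cells <- as.data.frame(as.list(cells))
  }
  validate_feature_columns(cells, fset)
  p <- as.matrix(cells[, fset$features, drop = FALSE])
  pn <- reference$p_normal
  ps <- reference$p_senescent
  unit <- sweep(sweep(p, 2L, pn), 2L, ps - pn, "/")
  if (literal) {
    n <- length(fset$features)
    t_sum <- sum(abs(ps - pn))
    w_lit <- abs(pn / ps) / t_sum
    drop(unit %*% w_lit) / n^2
  } else {
    drop(unit %*% reference$weights)
  }
}

#' Tissue senescence score (TSS)
#'
#' The percentage of a sample's cells whose CSS falls inside the scoring
#' window (default the closed interval `[1, 5]`, the range of CSS values
#' associated with senescent nuclear features).
#'
#' @param css Numeric CSS values (at least one).
#' @param window Closed scoring window (default `c(1, 5)`).
#' @return TSS in `[0, 100]`.
#' @export
tissue_senescence_score <- function(css, window = c(1, 5)) {
  if (length(css) == 0L) stop("no cells to score", call. = FALSE)
  if (length(window) != 2L || window[1] > window[2]) {
    stop("'window' must be c(lower, upper)", call. = FALSE)
  }
  100 * mean(css >= window[1] & css <= window[2])
}

#' Filter a tissue sample before scoring
#'
#' Applies the optional hepatocyte circularity filter (cells must have
#' circularity strictly above 0.7; used for human patient samples, where
#' low-circularity nuclei mostly belong to fibroblasts or immune cells)
#' and the sample-level minimum cell count (samples with fewer than 10,000
#' surviving cells are excluded from analysis). Exclusion is a logged
#' outcome, not a failure.
#'
#' @param cells Tissue cell table.
#' @param circularity_min Circularity cutoff (default 0.7; cells with
#'   circularity <= cutoff are dropped when the filter is on).
#' @param min_cells Minimum surviving cells per sample (default 10000,
#'   strict: a sample with fewer cells is excluded).
#' @param hepatocyte_filter Apply the circularity filter (default `FALSE`).
#' @return List with `cells` (filtered table), `sample_excluded` (flag),
#'   `log` (data frame of exclusion reasons and counts).
#' @export
filter_tissue_sample <- function(cells, circularity_min = 0.7,
                                 min_cells = 10000L,
                                 hepatocyte_filter = FALSE) {
  n0 <- nrow(cells)
  log <- data.frame(reason = character(), n = integer())
  if (hepatocyte_filter) {
    keep <- cells$Circularity > circularity_min
    log <- rbind(log, data.frame(reason = "circularity", n = sum(!keep)))
    cells <- cells[keep, , drop = FALSE]
  }
  sample_excluded <- nrow(cells) < min_cells
  if (sample_excluded) {
    log <- rbind(log, data.frame(reason = "min-cells", n = nrow(cells)))
  }
  list(cells = cells, sample_excluded = sample_excluded, log = log,
       n_before = n0, n_after = nrow(cells))
}

#' Score a tissue sample end to end
#'
#' Convenience wrapper: filter, score each cell, and summarize.
#'
#' @param cells Tissue cell table.
#' @param reference An `ideal_reference`.
#' @param window CSS window (default `c(1, 5)`).
#' @param ... Passed to [filter_tissue_sample()].
#' @return List of class `tissue_score_report`: `css` (per surviving
#'   cell), `tss`, `sample_excluded`, `n_before`, `n_after`, `log`.
#' @export
score_tissue_sample <- function(cells, reference, window = c(1, 5), ...) {
  flt <- filter_tissue_sample(cells, ...)
  if (flt$sample_excluded || nrow(flt$cells) == 0L) {
    return(structure(list(css = numeric(), tss = NA_real_,
                          sample_excluded = TRUE, n_before = flt$n_before,
                          n_after = flt$n_after, log = flt$log),
                     class = "tissue_score_report"))
  }
  css <- cell_senescence_score(flt$cells, reference)
  structure(list(css = css, tss = tissue_senescence_score(css, window),
                 sample_excluded = FALSE, n_before = flt$n_before,
                 n_after = flt$n_after, log = flt$log),
            class = "tissue_score_report")
}

#' Save / load an ideal reference as JSON
#'
#' @param reference An `ideal_reference`.
#' @param path File path.
#' @return `save_reference` the path invisibly; `load_reference` the
#'   reference object.
#' @export
save_reference <- function(reference, path) {
  stopifnot(inherits(reference, "ideal_reference"))
  payload <- list(
    format = "senomorph-reference", version = 1L,
    feature_set = reference$feature_set$name,
    p_normal = as.list(reference$p_normal),
    p_senescent = as.list(reference$p_senescent),
    n_negative = reference$n_negative, top_k = reference$top_k
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_reference
#' @export
load_reference <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "senomorph-reference")) {
    stop("not a senomorph reference file: ", path, call. = FALSE)
  }
  new_ideal_reference(unlist(payload$p_normal), unlist(payload$p_senescent),
                      payload$feature_set,
                      n_negative = payload$n_negative %||% NA_integer_,
                      top_k = payload$top_k %||% NA_integer_)
}
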