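# Drug-screen normalization and hit calling: toxicity exclusion against
# positive-control viability, two-way median-polish B-scores, replicate
# hit calling, and cross-line selectivity classes.

#' Exclude toxic drug wells from a plate set
#'
#' A drug well is toxic when its cell count is strictly below 40% of the
#' mean positive-control count of its own plate (the viability reference is
#' per plate and replicate). Exclusions are logged before normalization;
#' control and empty wells are never excluded.
#'
#' @param plates A `plate_set` (long format, see
#'   [generate_screen_plates()] or [read_plate_table()]).
#' @param viability_threshold Fraction of the positive-control mean count
#'   below which a well is toxic (default 0.40, strict `<`).
#' @return List with `plates` (the plate set with toxic wells' `excluded`
#'   flag set), `exclusions` (data frame of excluded wells with the
#'   reference count) and `toxic_drugs` (drug ids excluded in at least one
#'   replicate).
#' @export
toxicity_filter <- function(plates, viability_threshold = 0.40) {
  stopifnot(is.data.frame(plates))
  assert_scalar_number(viability_threshold, "viability_threshold", 0, 1)
  key <- interaction(plates$replicate, plates$plate, drop = TRUE)
  excluded <- logical(nrow(plates))
  ref <- numeric(nrow(plates))
  for (k in levels(key)) {
    sel <- key == k
    pc <- plates$count[sel & plates$role == "pos_control"]
    if (length(pc) == 0L || all(is.na(pc))) {
      stop("no positive-control wells on plate group ", k, call. = FALSE)
    }
    m <- mean(pc, na.rm = TRUE)
    ref[sel] <- m
    excluded[sel] <- plates$role[sel] == "drug" &
      !is.na(plates$count[sel]) &
      plates$count[sel] < viability_threshold * m
  }
  plates$excluded <- excluded
  exclusions <- plates[excluded, , drop = FALSE]
  if (nrow(exclusions) > 0L) {
    exclusions$reference_count <- ref[excluded]
    exclusions$reason <- "toxicity"
  }
  list(plates = plates,
       exclusions = exclusions,
       toxic_drugs = sort(unique(exclusions$drug_id)))
}

#' Two-way median polish
#'
#' Alternately sweeps row and column medians out of a matrix until the
#' largest change falls below `tol` (relative to the data scale) or
#' `max_iter` sweeps. `NA` cells are ignored by the medians and remain
#' `NA` in the residuals.
#'
#' @param x Numeric matrix (at least 2 x 2).
#' @param tol Convergence tolerance (default 1e-8).
#' @param max_iter Maximum sweeps (default 20).
#' @return List with `residuals`, `overall`, `row`, `col` effects.
#' @keywords internal
median_polish <- function(x, tol = 1e-8, max_iter = 20L) {
  if (!is.matrix(x) || nrow(x) < 2L || ncol(x) < 2L) {
    stop("median polish needs a matrix with at least 2 rows and 2 columns",
         call. = FALSE)
  }
  r <- x
  overall <- 0
  row_eff <- numeric(nrow(x))
  col_eff <- numeric(ncol(x))
  scale <- max(abs(x), na.rm = TRUE)
  if (!is.finite(scale) || scale == 0) scale <- 1
  for (it in seq_len(max_iter)) {
    rm_ <- apply(r, 1L, stats::median, na.rm = TRUE)
    rm_[is.na(rm_)] <- 0
    r <- r - rm_
    row_eff <- row_eff + rm_
    cm_ <- apply(r, 2L, stats::median, na.rm = TRUE)
    cm_[is.na(cm_)] <- 0
    r <- sweep(r, 2L, cm_)
    col_eff <- col_eff + cm_
    if (max(abs(c(rm_, cm_))) < tol * scale) break
  }
  med_r <- stats::median(row_eff)
  med_c <- stats::median(col_eff)
  overall <- med_r + med_c
  row_eff <- row_eff - med_r
  col_eff <- col_eff - med_c
  list(residuals = r, overall = overall, row = row_eff, col = col_eff)
}

#' B-score normalization of a plate matrix
#'
#' Removes row/column positional artifacts by Tukey two-way median polish
#' and scales the residuals by the plate's robust spread:
#' `B_ij = r_ij / (1.4826 * median|r|)`. A constant plate (zero spread)
#' yields B-scores of 0 by convention.
#'
#' @param plate Numeric plate matrix (rows x columns); `NA` marks missing
#'   or excluded wells.
#' @param tol,max_iter Median-polish convergence controls.
#' @return An object of class `bscore_result`: list with `bscore` (matrix),
#'   `residuals`, `scale` (the MAD), `row`, `col`, `overall`.
#' @export
bscore_normalize <- function(plate, tol = 1e-8, max_iter = 20L) {
  mp <- median_polish(plate, tol = tol, max_iter = max_iter)
  r <- mp$residuals
  mad_r <- stats::median(abs(r), na.rm = TRUE) * 1.4826
  b <- if (mad_r > 0) r / mad_r else r * 0
  structure(list(bscore = b, residuals = r, scale = mad_r,
                 row = mp$row, col = mp$col, overall = mp$overall),
            class = "bscore_result")
}

#' B-score a whole plate set
#'
#' Runs [bscore_normalize()] on the percent-senescent matrix of every
#' (replicate, plate) group, after masking toxicity-excluded wells, and
#' returns per-drug per-replicate B-scores. Control wells participate in
#' the polish but carry no drug id and are never hit-eligible.
#'
#' @param plates A `plate_set`, ideally after [toxicity_filter()] (the
#'   `excluded` column, when present, masks wells from scoring).
#' @param value Column to normalize (default `"pct_senescent"`).
#' @return Data frame with `drug_id`, `replicate`, `plate`, `row`, `col`,
#'   `bscore` for non-excluded drug wells.
#' @export
bscore_plates <- function(plates, value = "pct_senescent") {
  stopifnot(is.data.frame(plates), value %in% names(plates))
  if (!"excluded" %in% names(plates)) plates$excluded <- FALSE
  groups <- unique(plates[, c("replicate", "plate")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- plates$replicate == groups$replicate[i] &
      plates$plate == groups$plate[i]
    sub <- plates[sel, ]
    nr <- max(sub$row); nc <- max(sub$col)
    m <- matrix(NA_real_, nr, nc)
    keep <- !sub$excluded & !is.na(sub[[value]])
    m[cbind(sub$row[keep], sub$col[keep])] <- sub[[value]][keep]
    bs <- bscore_normalize(m)
    drug <- sub[sub$role == "drug" & !sub$excluded, ]
    if (nrow(drug) == 0L) return(NULL)
    data.frame(drug_id = drug$drug_id, replicate = drug$replicate,
               plate = drug$plate, row = drug$row, col = drug$col,
               bscore = bs$bscore[cbind(drug$row, drug$col)])
  })
  do.call(rbind, out)
}

#' Call screen hits from replicate B-scores
#'
#' A drug is a hit when at least `min_replicates` of its replicates have a
#' B-score strictly greater than `threshold` (defaults: B > 15 in at least
#' 2 of 3 replicates). Replicates excluded by toxicity are absent from the
#' input and count toward neither side.
#'
#' @param bscores Data frame with `drug_id`, `replicate`, `bscore` (from
#'   [bscore_plates()]).
#' @param threshold B-score threshold (default 15, strict `>`).
#' @param min_replicates Minimum qualifying replicates (default 2).
#' @return Data frame with `drug_id`, `n_replicates`, `n_above`, `hit`.
#' @export
call_hits <- function(bscores, threshold = 15, min_replicates = 2L) {
  stopifnot(is.data.frame(bscores),
            all(c("drug_id", "bscore") %in% names(bscores)))
  ids <- sort(unique(bscores$drug_id))
  n_rep <- as.integer(table(factor(bscores$drug_id, levels = ids)))
  n_above <- vapply(ids, function(d) {
    sum(bscores$bscore[bscores$drug_id == d] > threshold)
  }, numeric(1))
  data.frame(drug_id = ids, n_replicates = n_rep,
             n_above = as.integer(n_above),
             hit = n_above >= min_replicates)
}

#' Classify cross-line selectivity of screen hits
#'
#' Partitions a common drug library into drugs inducing senescence only in
#' line A, only in line B, in both, or in neither.
#'
#' @param hits_a,hits_b Hit tables from [call_hits()] for the two cell
#'   lines; they must cover the same drug universe.
#' @param line_a,line_b Display names of the lines.
#' @return An object of class `hit_table`: data frame with `drug_id`,
#'   `hit_a`, `hit_b`, `selectivity` in
#'   `{lineA_only, lineB_only, both, none}`, plus a `counts` attribute.
#' @export
classify_selectivity <- function(hits_a, hits_b, line_a = "lineA",
                                 line_b = "lineB") {
  if (!setequal(hits_a$drug_id, hits_b$drug_id)) {
    stop("hit tables cover different drug universes", call. = FALSE)
  }
  ids <- sort(unique(hits_a$drug_id))
  ha <- hits_a$hit[match(ids, hits_a$drug_id)]
  hb <- hits_b$hit[match(ids, hits_b$drug_id)]
  sel <- ifelse(ha & hb, "both",
         ifelse(ha, "lineA_only",
         ifelse(hb, "lineB_only", "none")))
  out <- data.frame(drug_id = ids, hit_a = ha, hit_b = hb,
                    selectivity = sel)
  counts <- c(lineA_only = sum(sel == "lineA_only"),
              lineB_only = sum(sel == "lineB_only"),
              both = sum(sel == "both"), none = sum(sel == "none"))
  structure(out, class = c("hit_table", "data.frame"), counts = counts,
            lines = c(line_a, line_b))
}
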