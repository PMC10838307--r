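# Synthetic drug-screen plates with positional artifacts and spiked drugs.

#' Specification of a synthetic senescence-induction screen
#'
#' Emulates a multi-plate screen (by default 676 drugs in biological
#' triplicate, mirroring the screen design): each plate carries a positive
#' control column (senescence inducer) and a negative control column
#' (vehicle), drug wells drawn from a null distribution of predicted
#' percent-senescent values plus additive row/column artifacts, spiked
#' active drugs with an additive effect on percent senescent, and spiked
#' toxic drugs whose cell counts fall to `(1 - kill_fraction)` of the
#' positive-control mean count.
#'
#' @param rows,cols Plate geometry (default 16 x 24).
#' @param n_drugs Number of library drugs (default 676).
#' @param n_replicates Biological replicates (default 3).
#' @param pos_control_col,neg_control_col Columns reserved for positive /
#'   negative controls on every plate.
#' @param active_drugs Character vector of drug ids spiked as actives (use
#'   ids `"drug0001"`, ...), or an integer count to pick the first k drugs.
#' @param active_effect Percentage-point increase of percent senescent for
#'   active wells (default 30; chosen so a true active clears the B > 15
#'   hit threshold at the default null noise).
#' @param toxic_drugs Drug ids (or count) spiked as toxic.
#' @param kill_fraction Fraction of cells killed by toxic drugs (default 0.7).
#' @param null_mean,null_sd Null distribution of percent senescent in drug
#'   and negative-control wells (default mean 5, sd 1.5).
#' @param pos_control_pct Mean percent senescent in positive-control wells
#'   (default 40).
#' @param control_count Mean cell count of healthy wells (default 1000,
#'   s.d. 5%).
#' @param row_artifact_sd,col_artifact_sd Standard deviation of per-plate
#'   additive row/column effects on percent senescent (default 2 each).
#' @param n_plates Plates per replicate; defaults to the minimum needed to
#'   host the library. Supplying too few is a layout error at generation.
#' @param cell_line Label attached to the plate set.
#' @param seed Integer seed.
#' @return An object of class `screen_spec`.
#' @export
screen_spec <- function(rows = 16L, cols = 24L, n_drugs = 676L,
                        n_replicates = 3L, pos_control_col = 1L,
                        neg_control_col = NULL, active_drugs = character(),
                        active_effect = 30, toxic_drugs = character(),
                        kill_fraction = 0.7, null_mean = 5, null_sd = 1.5,
                        pos_control_pct = 40, control_count = 1000,
                        row_artifact_sd = 2, col_artifact_sd = 2,
                        n_plates = NULL, cell_line = "lineA", seed = 1L) {
  neg_control_col <- neg_control_col %||% cols
  assert_scalar_number(rows, "rows", lower = 2)
  assert_scalar_number(cols, "cols", lower = 3)
  assert_scalar_number(n_drugs, "n_drugs", lower = 1)
  assert_scalar_number(n_replicates, "n_replicates", lower = 1)
  assert_scalar_number(kill_fraction, "kill_fraction", 0, 1)
  if (pos_control_col == neg_control_col) {
    stop("positive and negative control columns must differ", call. = FALSE)
  }
  drug_ids <- sprintf("drug%04d", seq_len(n_drugs))
  # counts are expanded to seeded random draws so spikes scatter over the
  # plate layout instead of clustering in one row
  if (is.numeric(active_drugs)) {
    active_drugs <- with_seed(child_seed(seed, "noise"),
                              sort(sample(drug_ids, active_drugs)))
  }
  if (is.numeric(toxic_drugs)) {
    toxic_drugs <- with_seed(child_seed(seed, "noise") + 1L,
                             sort(sample(setdiff(drug_ids, active_drugs),
                                         toxic_drugs)))
  }
  if (!all(active_drugs %in% drug_ids) || !all(toxic_drugs %in% drug_ids)) {
    stop("spiked drug ids must belong to the drug library", call. = FALSE)
  }
  wells_per_plate <- rows * (cols - 2L)
  structure(list(
    rows = as.integer(rows), cols = as.integer(cols),
    n_drugs = as.integer(n_drugs), n_replicates = as.integer(n_replicates),
    pos_control_col = as.integer(pos_control_col),
    neg_control_col = as.integer(neg_control_col),
    drug_ids = drug_ids, active_drugs = active_drugs,
    active_effect = active_effect, toxic_drugs = toxic_drugs,
    kill_fraction = kill_fraction, null_mean = null_mean, null_sd = null_sd,
    pos_control_pct = pos_control_pct, control_count = control_count,
    row_artifact_sd = row_artifact_sd, col_artifact_sd = col_artifact_sd,
    n_plates = as.integer(n_plates %||% ceiling(n_drugs / wells_per_plate)),
    cell_line = cell_line, seed = as.integer(seed)
  ), class = "screen_spec")
}

#' Generate synthetic screen plates
#'
#' Produces a long-format plate set with per-well cell counts and percent
#' predicted senescent. The drug layout (which drug sits in which well) is
#' fixed across replicates; noise and artifacts are redrawn per replicate.
#' Ground truth (spiked actives and toxics) is carried in attributes, not
#' in the table.
#'
#' @param spec A [screen_spec()].
#' @return A data frame of class `plate_set` with columns `plate`,
#'   `replicate`, `row`, `col`, `drug_id`, `role`, `count`,
#'   `pct_senescent`; attributes `spec`, `truth_active`, `truth_toxic`,
#'   `cell_line`.
#' @export
generate_screen_plates <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  drug_cols <- setdiff(seq_len(spec$cols),
                       c(spec$pos_control_col, spec$neg_control_col))
  wells_per_plate <- spec$rows * length(drug_cols)
  if (spec$n_drugs > wells_per_plate * spec$n_plates) {
    stop("layout error: ", spec$n_drugs, " drugs exceed ",
         wells_per_plate * spec$n_plates, " available drug wells",
         call. = FALSE)
  }
  # deterministic layout: drugs fill plates row-major over drug columns
  layout <- expand.grid(row = seq_len(spec$rows), col = drug_cols,
                        plate = seq_len(spec$n_plates))
  layout <- layout[order(layout$plate, layout$row, layout$col), ]
  layout$drug_id <- c(spec$drug_ids,
                      rep(NA_character_, nrow(layout) - spec$n_drugs))

  with_seed(child_seed(spec$seed, "screen"), {
    reps <- lapply(seq_len(spec$n_replicates), function(rep_i) {
      plates <- lapply(seq_len(spec$n_plates), function(pl) {
        grid <- expand.grid(row = seq_len(spec$rows), col = seq_len(spec$cols))
        grid$plate <- pl
        grid$replicate <- rep_i
        lay <- layout[layout$plate == pl, ]
        key <- paste(grid$row, grid$col)
        lk <- match(key, paste(lay$row, lay$col))
        grid$drug_id <- ifelse(is.na(lk), NA_character_, lay$drug_id[lk])
        grid$role <- ifelse(grid$col == spec$pos_control_col, "pos_control",
                     ifelse(grid$col == spec$neg_control_col, "neg_control",
                     ifelse(is.na(grid$drug_id), "empty", "drug")))
        n <- nrow(grid)
        pct <- stats::rnorm(n, spec$null_mean, spec$null_sd)
        pct[grid$role == "pos_control"] <-
          stats::rnorm(sum(grid$role == "pos_control"),
                       spec$pos_control_pct, spec$null_sd)
        active <- !is.na(grid$drug_id) & grid$drug_id %in% spec$active_drugs
        pct[active] <- pct[active] + spec$active_effect
        # additive positional artifacts, redrawn per plate and replicate
        re <- stats::rnorm(spec$rows, 0, spec$row_artifact_sd)
        ce <- stats::rnorm(spec$cols, 0, spec$col_artifact_sd)
        pct <- pct + re[grid$row] + ce[grid$col]
        pct <- pmin(pmax(pct, 0), 100)
        count <- stats::rnorm(n, spec$control_count, 0.05 * spec$control_count)
        toxic <- !is.na(grid$drug_id) & grid$drug_id %in% spec$toxic_drugs
        count[toxic] <- stats::rnorm(sum(toxic),
                                     (1 - spec$kill_fraction) * spec$control_count,
                                     0.05 * spec$control_count)
        grid$count <- pmax(0, round(count))
        grid$pct_senescent <- pct
        grid$pct_senescent[grid$role == "empty"] <- NA_real_
        grid$count[grid$role == "empty"] <- NA_real_
        grid
      })
      do.call(rbind, plates)
    })
    out <- do.call(rbind, reps)
    out <- out[, c("plate", "replicate", "row", "col", "drug_id", "role",
                   "count", "pct_senescent")]
    rownames(out) <- NULL
    structure(out, class = c("plate_set", "data.frame"), spec = spec,
              truth_active = spec$active_drugs, truth_toxic = spec$toxic_drugs,
              cell_line = spec$cell_line)
  })
}
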