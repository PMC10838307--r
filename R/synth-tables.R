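# Synthetic two-population feature tables and tissue detection tables.
#
# Per-feature marginals respect each feature's support: log-normal for
# strictly positive quantities (areas, lengths), logit-normal for ratio
# features bounded in (0, 1]. Parameters are (location, scale) where
# location is the natural-scale median and scale the log- or logit-scale
# standard deviation. An optional correlation matrix induces dependence
# through a Gaussian copula.

.default_population_params <- list(
  core7 = list(
    normal = list(
      Area = c(140, 0.25), FormFactor = c(0.88, 0.5),
      Elongation = c(0.78, 0.5), Compactness = c(4.4, 0.15),
      ChordRatio = c(0.75, 0.5), GyrationRadius = c(4.8, 0.15),
      Displacement = c(0.06, 0.5)
    ),
    senescent = list(
      Area = c(260, 0.30), FormFactor = c(0.80, 0.6),
      Elongation = c(0.70, 0.6), Compactness = c(6.0, 0.18),
      ChordRatio = c(0.68, 0.6), GyrationRadius = c(6.6, 0.18),
      Displacement = c(0.09, 0.6)
    )
  ),
  tissue6 = list(
    normal = list(
      Area = c(55, 0.25), Perimeter = c(27, 0.14), Circularity = c(0.86, 0.5),
      MaxCaliper = c(9.5, 0.16), MinCaliper = c(7.4, 0.16),
      Eccentricity = c(0.55, 0.4)
    ),
    senescent = list(
      Area = c(110, 0.30), Perimeter = c(39, 0.17), Circularity = c(0.74, 0.5),
      MaxCaliper = c(14, 0.19), MinCaliper = c(10, 0.19),
      Eccentricity = c(0.68, 0.4)
    )
  )
)

feature_dist_kind <- function(fset, feature) {
  u <- fset$units[[feature]]
  if (identical(u, "ratio")) "logitnormal" else "lognormal"
}

validate_class_params <- function(params, fset, who) {
  missing <- setdiff(fset$features, names(params))
  if (length(missing) > 0L) {
    stop(who, " parameters missing features: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(params), fset$features)
  if (length(unknown) > 0L) {
    stop(who, " parameters name unknown features: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (f in fset$features) {
    p <- params[[f]]
    if (length(p) != 2L || any(!is.finite(p)) || p[2] <= 0) {
      stop(who, " parameter for ", f,
           " must be c(location, scale) with scale > 0", call. = FALSE)
    }
    if (feature_dist_kind(fset, f) == "logitnormal" &&
        (p[1] <= 0 || p[1] >= 1)) {
      stop(who, " location for ratio feature ", f,
           " must lie in (0, 1)", call. = FALSE)
    }
    if (feature_dist_kind(fset, f) == "lognormal" && p[1] <= 0) {
      stop(who, " location for ", f, " must be positive", call. = FALSE)
    }
  }
  params[fset$features]
}

#' Specification of a synthetic two-population cell culture
#'
#' Describes a mixture of normal and senescent cells over one feature
#' schema. Defaults emulate the measured shifts between control and
#' senescence-induced cultures: senescent nuclei larger in area and
#' gyration radius, with lower circularity/form factor and elongation.
#'
#' @param n_cells Number of cells to generate.
#' @param senescent_fraction Proportion of senescent cells in `[0, 1]`.
#' @param feature_set Schema name or `feature_set` (core7 or tissue6 have
#'   built-in defaults).
#' @param normal,senescent Named lists of `c(location, scale)` per feature;
#'   `NULL` uses the defaults. `effect_scale` linearly interpolates the
#'   senescent location between the normal location (0) and the senescent
#'   default (1) on the log/logit scale, giving a single effect-size dial.
#' @param effect_scale Effect-size multiplier (default 1).
#' @param correlation Optional feature correlation matrix (Gaussian copula).
#' @param seed Integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells = 2000, senescent_fraction = 0.5,
                            feature_set = "core7", normal = NULL,
                            senescent = NULL, effect_scale = 1,
                            correlation = NULL, seed = 1L) {
  fset <- as_feature_set(feature_set)
  assert_scalar_number(n_cells, "n_cells", lower = 1)
  assert_scalar_number(senescent_fraction, "senescent_fraction", 0, 1)
  assert_scalar_number(effect_scale, "effect_scale", lower = 0)
  defaults <- .default_population_params[[fset$name]]
  if (is.null(defaults) && (is.null(normal) || is.null(senescent))) {
    stop("no default population parameters for feature set '", fset$name,
         "'; supply 'normal' and 'senescent'", call. = FALSE)
  }
  normal <- validate_class_params(normal %||% defaults$normal, fset, "normal")
  senescent <- validate_class_params(senescent %||% defaults$senescent,
                                     fset, "senescent")
  if (effect_scale != 1) {
    # interpolate both location and scale so that effect_scale = 0 gives
    # literally identical class distributions
    for (f in fset$features) {
      kind <- feature_dist_kind(fset, f)
      tr <- if (kind == "lognormal") log else stats::qlogis
      inv <- if (kind == "lognormal") exp else stats::plogis
      loc <- tr(normal[[f]][1]) +
        effect_scale * (tr(senescent[[f]][1]) - tr(normal[[f]][1]))
      senescent[[f]][1] <- inv(loc)
      senescent[[f]][2] <- normal[[f]][2] +
        effect_scale * (senescent[[f]][2] - normal[[f]][2])
    }
  }
  if (!is.null(correlation)) {
    k <- length(fset$features)
    if (!is.matrix(correlation) || any(dim(correlation) != k) ||
        any(abs(correlation - t(correlation)) > 1e-12) ||
        any(diag(correlation) != 1)) {
      stop("'correlation' must be a symmetric ", k, "x", k,
           " matrix with unit diagonal", call. = FALSE)
    }
  }
  structure(list(n_cells = as.integer(n_cells),
                 senescent_fraction = senescent_fraction,
                 feature_set = fset, normal = normal, senescent = senescent,
                 correlation = correlation, seed = as.integer(seed)),
            class = "population_spec")
}

draw_class_features <- function(params, fset, n, correlation = NULL) {
  k <- length(fset$features)
  z <- matrix(stats::rnorm(n * k), n, k)
  if (!is.null(correlation) && n > 0) z <- z %*% chol(correlation)
  out <- matrix(NA_real_, n, k, dimnames = list(NULL, fset$features))
  for (j in seq_len(k)) {
    f <- fset$features[j]
    p <- params[[f]]
    out[, j] <- if (feature_dist_kind(fset, f) == "lognormal") {
      exp(log(p[1]) + p[2] * z[, j])
    } else {
      stats::plogis(stats::qlogis(p[1]) + p[2] * z[, j])
    }
  }
  as.data.frame(out)
}

#' Generate a synthetic two-population feature table
#'
#' Exactly `n_cells` rows; `round(n_cells * senescent_fraction)` of them
#' (round-half-even) are senescent. The hidden ground-truth label is stored
#' in the `.truth` column (0 = normal, 1 = senescent) and must only be
#' consumed through explicit evaluation calls, never by classifiers.
#'
#' @param spec A [population_spec()].
#' @return Data frame with the schema's feature columns plus `.truth`;
#'   rows shuffled, reproducible under the spec seed.
#' @export
generate_population_table <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n_sen <- as.integer(round_half_even(spec$n_cells * spec$senescent_fraction))
  n_norm <- spec$n_cells - n_sen
  with_seed(child_seed(spec$seed, "population"), {
    norm <- draw_class_features(spec$normal, spec$feature_set, n_norm,
                                spec$correlation)
    sen <- draw_class_features(spec$senescent, spec$feature_set, n_sen,
                               spec$correlation)
    tab <- rbind(norm, sen)
    tab$.truth <- rep(c(0L, 1L), c(n_norm, n_sen))
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    rownames(tab) <- NULL
    attr(tab, "feature_set") <- spec$feature_set$name
    tab
  })
}

#' Specification of a synthetic tissue detection table
#'
#' Emulates a per-cell slide-analysis export: tissue6 nuclear features plus
#' a DAB nuclear mean optical density linked to the hidden senescence
#' status through two overlapping intensity distributions (marker-positive
#' cells mostly above the 0.2 OD calling threshold, negative cells mostly
#' below). Senescent cells draw larger areas and calipers and lower
#' circularity.
#'
#' @param n_cells Number of cells.
#' @param senescent_fraction Proportion senescent in `[0, 1]`.
#' @param normal,senescent Optional per-feature `c(location, scale)` lists
#'   over the tissue6 schema.
#' @param dab_negative,dab_positive `c(median, sdlog)` of the log-normal
#'   DAB OD distribution for marker-negative / -positive cells.
#' @param seed Integer seed.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(n_cells = 5000, senescent_fraction = 0.1,
                        normal = NULL, senescent = NULL,
                        dab_negative = c(0.07, 0.5),
                        dab_positive = c(0.45, 0.5), seed = 1L) {
  assert_scalar_number(n_cells, "n_cells", lower = 1)
  assert_scalar_number(senescent_fraction, "senescent_fraction", 0, 1)
  for (nm in c("dab_negative", "dab_positive")) {
    p <- get(nm)
    if (length(p) != 2L || any(!is.finite(p)) || any(p <= 0)) {
      stop("'", nm, "' must be c(median, sdlog), both positive",
           call. = FALSE)
    }
  }
  fset <- feature_set("tissue6")
  defaults <- .default_population_params$tissue6
  normal <- validate_class_params(normal %||% defaults$normal, fset, "normal")
  senescent <- validate_class_params(senescent %||% defaults$senescent,
                                     fset, "senescent")
  structure(list(n_cells = as.integer(n_cells),
                 senescent_fraction = senescent_fraction,
                 feature_set = fset, normal = normal, senescent = senescent,
                 dab_negative = dab_negative, dab_positive = dab_positive,
                 seed = as.integer(seed)),
            class = "tissue_spec")
}

#' Generate a synthetic per-cell tissue table
#'
#' @param spec A [tissue_spec()].
#' @param sample_id Identifier copied to every row.
#' @return Data frame with `sample_id`, centroids, tissue6 features,
#'   `dab_od_mean` and the hidden `.truth` status column.
#' @export
generate_tissue_table <- function(spec, sample_id = "sample1") {
  stopifnot(inherits(spec, "tissue_spec"))
  n_sen <- as.integer(round_half_even(spec$n_cells * spec$senescent_fraction))
  n_norm <- spec$n_cells - n_sen
  with_seed(child_seed(spec$seed, "tissue"), {
    norm <- draw_class_features(spec$normal, spec$feature_set, n_norm)
    sen <- draw_class_features(spec$senescent, spec$feature_set, n_sen)
    tab <- rbind(norm, sen)
    truth <- rep(c(0L, 1L), c(n_norm, n_sen))
    dab <- numeric(nrow(tab))
    dab[truth == 0L] <- stats::rlnorm(n_norm, log(spec$dab_negative[1]),
                                      spec$dab_negative[2])
    dab[truth == 1L] <- stats::rlnorm(n_sen, log(spec$dab_positive[1]),
                                      spec$dab_positive[2])
    out <- data.frame(
      sample_id = sample_id,
      cell_id = seq_len(nrow(tab)),
      centroid_x = stats::runif(nrow(tab), 0, 5000),
      centroid_y = stats::runif(nrow(tab), 0, 5000),
      tab,
      dab_od_mean = dab,
      .truth = truth,
      check.names = FALSE
    )
    ord <- sample.int(nrow(out))
    out <- out[ord, , drop = FALSE]
    out$cell_id <- seq_len(nrow(out)) # ids assigned after shuffling
    rownames(out) <- NULL
    attr(out, "feature_set") <- "tissue6"
    out
  })
}
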