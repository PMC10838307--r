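#' Run configuration with the pipeline's published defaults
#'
#' Every threshold of the pipeline lives here, once, with its default:
#' 10,000 cells per training class; 30% tree holdout / 50% forest holdout;
#' forest probability cutoff 0.5 (strict); 40% toxicity viability
#' threshold (strict `<`); B-score hit threshold 15 (strict `>`) in at
#' least 2 of 3 replicates; DAB OD marker threshold 0.2 (strict `>`);
#' hepatocyte circularity cutoff 0.7; 10,000-cell sample minimum; CSS
#' scoring window 1--5 (closed); pixel size 0.5 um.
#'
#' @param ... Overrides of any default (unknown keys error).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    feature_set = "core7",
    pixel_size = 0.5,
    n_per_class = 10000L,
    tree_holdout = 0.3,
    forest_holdout = 0.5,
    forest_cutoff = 0.5,
    forest_trees = 100L,
    marker_threshold = NA_real_, # NA: derive from control percentile
    marker_percentile = 0.95,
    toxicity_threshold = 0.40,
    bscore_threshold = 15,
    min_hit_replicates = 2L,
    dab_threshold = 0.2,
    circularity_min = 0.7,
    min_cells = 10000L,
    css_window_low = 1,
    css_window_high = 5,
    top_k_positive = 100L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  positive <- c("pixel_size", "n_per_class", "forest_trees", "bscore_threshold",
                "min_hit_replicates", "min_cells", "top_k_positive")
  for (k in positive) {
    if (!is.na(cfg[[k]]) && cfg[[k]] <= 0) {
      stop("config key '", k, "' must be positive (got ", cfg[[k]], ")",
           call. = FALSE)
    }
  }
  frac <- c("tree_holdout", "forest_holdout", "forest_cutoff",
            "toxicity_threshold", "marker_percentile")
  for (k in frac) {
    if (!is.na(cfg[[k]]) && (cfg[[k]] < 0 || cfg[[k]] > 1)) {
      stop("config key '", k, "' must lie in [0, 1] (got ", cfg[[k]], ")",
           call. = FALSE)
    }
  }
  for (k in c("dab_threshold", "circularity_min")) {
    if (!is.na(cfg[[k]]) && cfg[[k]] < 0) {
      stop("config key '", k, "' must be non-negative (got ", cfg[[k]], ")",
           call. = FALSE)
    }
  }
  if (cfg$css_window_low > cfg$css_window_high) {
    stop("config key 'css_window_low' exceeds 'css_window_high'",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read / write a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored;
#' values parsed as numbers where possible. Round-trips losslessly through
#' [write_config()].
#'
#' @param path File path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed config lines: ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- lapply(kv, function(p) {
    v <- p[[2]]
    if (identical(v, "NA")) return(NA_real_)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- keys
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param cfg A `run_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lines <- vapply(names(cfg), function(k) {
    paste0(k, " = ", format(cfg[[k]], scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
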