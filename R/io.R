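# Readers/writers and column-dialect mapping for feature tables, plate
# tables and masks. Tables are UTF-8 CSV/TSV with "." decimal; unknown
# columns pass through untouched.

.dialects <- list(
  native = list(feature_set = NULL, map = character()),
  incarta_like = list(
    feature_set = "core7",
    map = c(
      "Nuclei Area" = "Area", "Nuclei Form Factor" = "FormFactor",
      "Nuclei Elongation" = "Elongation",
      "Nuclei Compactness" = "Compactness",
      "Nuclei Chord Ratio" = "ChordRatio",
      "Nuclei Gyration Radius" = "GyrationRadius",
      "Nuclei Displacement" = "Displacement"
    )
  ),
  cellprofiler_like = list(
    feature_set = "extended17",
    map = c(
      "AreaShape_Area" = "Area",
      "AreaShape_BoundingBoxArea" = "BoundingBoxArea",
      "AreaShape_Compactness" = "Compactness",
      "AreaShape_ConvexArea" = "ConvexArea",
      "AreaShape_Eccentricity" = "Eccentricity",
      "AreaShape_EquivalentDiameter" = "EquivalentDiameter",
      "AreaShape_Extent" = "Extent",
      "AreaShape_FormFactor" = "FormFactor",
      "AreaShape_MajorAxisLength" = "MajorAxisLength",
      "AreaShape_MaxFeretDiameter" = "MaxFeretDiameter",
      "AreaShape_MaximumRadius" = "MaxRadius",
      "AreaShape_MeanRadius" = "MeanRadius",
      "AreaShape_MedianRadius" = "MedianRadius",
      "AreaShape_MinFeretDiameter" = "MinFeretDiameter",
      "AreaShape_MinorAxisLength" = "MinorAxisLength",
      "AreaShape_Perimeter" = "Perimeter",
      "AreaShape_Solidity" = "Solidity"
    )
  ),
  qupath_like = list(
    feature_set = "tissue6",
    map = c(
      "Centroid X" = "centroid_x", "Centroid Y" = "centroid_y",
      "Nucleus: Area" = "Area", "Nucleus: Perimeter" = "Perimeter",
      "Nucleus: Circularity" = "Circularity",
      "Nucleus: Max caliper" = "MaxCaliper",
      "Nucleus: Min caliper" = "MinCaliper",
      "Nucleus: Eccentricity" = "Eccentricity",
      "DAB: Nucleus: Mean" = "dab_od_mean"
    )
  )
)

detect_dialect <- function(header) {
  for (d in c("incarta_like", "cellprofiler_like", "qupath_like")) {
    src <- names(.dialects[[d]]$map)
    if (mean(src %in% header) > 0.5) return(d)
  }
  "native"
}

#' Read a feature table in any supported column dialect
#'
#' Supported dialects: `native` (this package's canonical column names),
#' `incarta_like` (high-content analysis export, core7 schema),
#' `cellprofiler_like` (`AreaShape_*` columns, extended17 schema) and
#' `qupath_like` (`Nucleus: ...` detection-export columns, tissue6
#' schema). `"auto"` fingerprints the header. Unknown columns pass
#' through; rows with missing feature values are rejected with their line
#' numbers.
#'
#' @param path CSV or TSV file (separator inferred from the extension and
#'   header).
#' @param dialect Dialect id or `"auto"`.
#' @param feature_set Schema whose columns are mandatory; defaults to the
#'   dialect's natural schema, or (for native files) whichever schema
#'   matches the header.
#' @return Data frame with canonical column names; attributes `dialect`
#'   and `feature_set`.
#' @export
read_feature_table <- function(path, dialect = "auto", feature_set = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 2L)
  hint <- grepl("^#", first[1])
  sep <- if (grepl("\t", first[if (hint) 2L else 1L])) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (identical(dialect, "auto")) dialect <- detect_dialect(names(df))
  if (!dialect %in% names(.dialects)) {
    stop("unknown dialect: ", dialect, call. = FALSE)
  }
  map <- .dialects[[dialect]]$map
  hit <- names(df) %in% names(map)
  names(df)[hit] <- unname(map[names(df)[hit]])
  fset <- feature_set %||% .dialects[[dialect]]$feature_set
  if (is.null(fset)) {
    # native: pick the schema fully covered by the header, preferring the
    # most specific
    for (cand in c("extended17", "core7", "tissue6")) {
      if (all(feature_set(cand)$features %in% names(df))) {
        fset <- cand
        break
      }
    }
    if (is.null(fset)) fset <- "core7" # force the informative error below
  }
  fset <- as_feature_set(fset)
  missing <- setdiff(fset$features, names(df))
  if (length(missing) > 0L) {
    stop("file is missing mandatory columns (", fset$name, "): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[, fset$features, drop = FALSE]))
  if (length(bad) > 0L) {
    stop("malformed rows with missing feature values at lines: ",
         paste(utils::head(bad + 1L, 20), collapse = ", "), call. = FALSE)
  }
  attr(df, "dialect") <- dialect
  attr(df, "feature_set") <- fset$name
  df
}

#' Write a feature table in the native dialect
#'
#' Plain UTF-8 CSV with a `#`-comment tag line recording the dialect and
#' schema, then a header row. Round-trips through
#' [read_feature_table()] identically.
#'
#' @param df Data frame (feature table).
#' @param path Output path.
#' @param feature_set Schema name recorded in the tag line.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(df, path, feature_set = NULL) {
  fset <- feature_set %||% attr(df, "feature_set") %||% "core7"
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# senomorph feature table; dialect=native; feature_set=",
                    fset), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write long-format plate tables
#'
#' Columns: `plate`, `replicate`, `row`, `col`, `drug_id`, `role`,
#' `count`, `pct_senescent` (and optionally `excluded`).
#'
#' @param path CSV path.
#' @return `read_plate_table`: a `plate_set` data frame.
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("plate", "replicate", "row", "col", "drug_id", "role", "count",
            "pct_senescent")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("plate table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$drug_id[df$drug_id %in% c("", "NA")] <- NA_character_
  class(df) <- c("plate_set", "data.frame")
  df
}

#' @rdname read_plate_table
#' @param plates A `plate_set` data frame.
#' @export
write_plate_table <- function(plates, path) {
  utils::write.csv(as.data.frame(plates), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Write / read an integer label mask as PNG
#'
#' Masks are stored as 8-bit grayscale PNG with labels scaled by 1/255
#' (the available PNG writer is 8-bit), so label values must not exceed
#' 255. The round trip is exact.
#'
#' @param mask Integer matrix (0 = background).
#' @param path PNG path.
#' @return `write_mask_png` the path invisibly; `read_mask_png` the
#'   integer label matrix.
#' @export
write_mask_png <- function(mask, path) {
  if (max(mask) > 255L) {
    stop("labels exceed the 8-bit PNG range (255)", call. = FALSE)
  }
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}
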