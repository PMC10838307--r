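#' Nuclear feature schemas
#'
#' Three fixed schemas of nuclear shape descriptors are supported:
#'
#' * `core7` -- the high-content analysis set: Area, FormFactor, Elongation,
#'   Compactness, ChordRatio, GyrationRadius, Displacement.
#' * `extended17` -- the open-source image-analysis set of 17 descriptors
#'   (area, bounding box, convexity, Feret diameters, radii, axis lengths,
#'   perimeter, solidity, ...).
#' * `tissue6` -- the slide-analysis set used for histology scoring:
#'   Area, Perimeter, Circularity, MaxCaliper, MinCaliper, Eccentricity.
#'
#' Areas are in square micrometres, lengths in micrometres, ratio-type
#' features dimensionless.
#'
#' @param name One of `"core7"`, `"extended17"`, `"tissue6"`.
#' @return An object of class `feature_set`: a list with elements `name`,
#'   `features` (ordered character vector) and `units` (named character).
#' @examples
#' feature_set("tissue6")$features
#' @export
feature_set <- function(name = c("core7", "extended17", "tissue6")) {
  name <- match.arg(name)
  defs <- .feature_set_defs[[name]]
  structure(list(name = name, features = names(defs), units = defs),
            class = "feature_set")
}

.feature_set_defs <- list(
  core7 = c(
    Area = "um^2", FormFactor = "ratio", Elongation = "ratio",
    Compactness = "um", ChordRatio = "ratio", GyrationRadius = "um",
    Displacement = "ratio"
  ),
  extended17 = c(
    Area = "um^2", BoundingBoxArea = "um^2", Compactness = "um",
    ConvexArea = "um^2", Eccentricity = "ratio", EquivalentDiameter = "um",
    Extent = "ratio", FormFactor = "ratio", MajorAxisLength = "um",
    MaxFeretDiameter = "um", MaxRadius = "um", MeanRadius = "um",
    MedianRadius = "um", MinFeretDiameter = "um", MinorAxisLength = "um",
    Perimeter = "um", Solidity = "ratio"
  ),
  tissue6 = c(
    Area = "um^2", Perimeter = "um", Circularity = "ratio",
    MaxCaliper = "um", MinCaliper = "um", Eccentricity = "ratio"
  )
)

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set>", x$name, ":", length(x$features), "features\n")
  cat(" ", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.feature_set <- function(x, ...) {
  paste0(x$name, " [", length(x$features), " features]")
}

as_feature_set <- function(x) {
  if (inherits(x, "feature_set")) return(x)
  if (is.character(x) && length(x) == 1L) return(feature_set(x))
  stop("cannot interpret object as a feature_set", call. = FALSE)
}

#' Check that a data frame carries all features of a schema
#'
#' @param df A data frame.
#' @param fset A `feature_set` or schema name.
#' @return Invisibly `TRUE`; errors listing missing columns otherwise.
#' @export
validate_feature_columns <- function(df, fset) {
  fset <- as_feature_set(fset)
  missing <- setdiff(fset$features, names(df))
  if (length(missing) > 0L) {
    stop("feature table is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- fset$features[vapply(df[fset$features],
                              function(v) anyNA(v) || !is.numeric(v),
                              logical(1))]
  if (length(bad) > 0L) {
    stop("feature columns contain missing or non-numeric values: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
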