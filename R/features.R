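#' Acquisition quality-control parameters
#'
#' Mirrors the filters applied at image acquisition: a typical-diameter
#' window for true nuclei, a minimum DAPI mean intensity against
#' overexposure artifacts, and exclusion of objects touching image edges
#' (partially acquired nuclei).
#'
#' @param min_diameter,max_diameter Equivalent-diameter window in
#'   micrometres (default 5--40 um).
#' @param min_intensity Minimum mean intensity for the nuclear channel;
#'   `NULL` disables the intensity filter.
#' @param exclude_edge_objects Drop objects whose bounding box touches the
#'   image border (default `TRUE`).
#' @param pixel_size Micrometres per pixel; default 0.5.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_diameter = 5, max_diameter = 40,
                      min_intensity = NULL, exclude_edge_objects = TRUE,
                      pixel_size = 0.5) {
  assert_scalar_number(min_diameter, "min_diameter", lower = 0)
  assert_scalar_number(max_diameter, "max_diameter", lower = 0)
  if (min_diameter >= max_diameter) {
    stop("min_diameter must be smaller than max_diameter", call. = FALSE)
  }
  assert_scalar_number(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (!is.null(min_intensity)) {
    assert_scalar_number(min_intensity, "min_intensity")
  }
  structure(list(min_diameter = min_diameter, max_diameter = max_diameter,
                 min_intensity = min_intensity,
                 exclude_edge_objects = isTRUE(exclude_edge_objects),
                 pixel_size = pixel_size),
            class = "qc_params")
}

#' Segment a grayscale image into a labelled nucleus mask
#'
#' A deliberately simple global-threshold plus connected-components path
#' intended for synthetic images; it is not a general nucleus segmenter.
#'
#' @param image Numeric matrix (2-D, single channel).
#' @param threshold Either a numeric cutoff (foreground is strictly above
#'   it) or `"otsu"` for automatic selection.
#' @return Integer label matrix of the same dimension; background is 0 and
#'   each 8-connected foreground component gets a distinct positive label.
#' @export
segment_image <- function(image, threshold = "otsu") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("'image' must be a 2-D numeric matrix", call. = FALSE)
  }
  if (identical(threshold, "otsu")) {
    threshold <- otsu_threshold(image)
  }
  assert_scalar_number(threshold, "threshold")
  label_components(image > threshold)
}

# Otsu's method on a 256-bin histogram of the image range.
otsu_threshold <- function(image) {
  v <- as.vector(image)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1]) # flat image: nothing above threshold
  breaks <- seq(rng[1], rng[2], length.out = 257L)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = 256L)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# 8-connected component labelling by iterative frontier expansion.
label_components <- function(fg) {
  stopifnot(is.matrix(fg))
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  if (!any(fg)) return(lab)
  todo <- which(fg)
  visited <- !fg
  nbr_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nbr_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  current <- 0L
  for (start in todo) {
    if (visited[start]) next
    current <- current + 1L
    frontier <- start
    visited[start] <- TRUE
    lab[start] <- current
    while (length(frontier) > 0L) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      nr_all <- rep(r, each = 8L) + nbr_dr
      nc_all <- rep(c, each = 8L) + nbr_dc
      ok <- nr_all >= 1L & nr_all <= nr & nc_all >= 1L & nc_all <= nc
      idx <- unique(nr_all[ok] + (nc_all[ok] - 1L) * nr)
      idx <- idx[!visited[idx]]
      visited[idx] <- TRUE
      lab[idx] <- current
      frontier <- idx
    }
  }
  lab
}

# --- geometry primitives -------------------------------------------------

# pixel coordinates (row, col) of a region, 0-based
region_coords <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  cbind(row = ((idx - 1L) %% nr), col = ((idx - 1L) %/% nr))
}

# convex hull of the pixel centres of the region, as an n x 2 matrix of
# (row, col) vertices in hull order. Caliper diameters measured on this
# hull get +0.5 px added for the pixel extent (the centre hull undercuts
# the analytic support by 0-1 px depending on orientation).
pixel_center_hull <- function(coords) {
  h <- grDevices::chull(coords[, 2], coords[, 1])
  coords[h, , drop = FALSE]
}

# number of region-bbox pixel centres lying inside (or on) the convex hull
# of the region's pixel centres: the discretized convex area, so that
# solidity of a convex rasterized shape is ~1 by construction
convex_pixel_count <- function(coords) {
  h <- grDevices::chull(coords[, 2], coords[, 1])
  hull <- coords[h, , drop = FALSE]
  nh <- nrow(hull)
  if (nh < 3L) return(nrow(unique(coords)))
  rows <- seq(min(coords[, 1]), max(coords[, 1]))
  cols <- seq(min(coords[, 2]), max(coords[, 2]))
  pts <- cbind(rep(rows, times = length(cols)),
               rep(cols, each = length(rows)))
  inside <- rep(TRUE, nrow(pts))
  cen <- colMeans(hull)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    s <- sign((cen[1] - hull[i, 1]) * e[2] - (cen[2] - hull[i, 2]) * e[1])
    cr <- (pts[, 1] - hull[i, 1]) * e[2] - (pts[, 2] - hull[i, 2]) * e[1]
    inside <- inside & (s * cr >= -1e-9)
  }
  sum(inside)
}

# max Feret (caliper) diameter: max pairwise distance over hull vertices
max_feret <- function(hull) {
  d <- stats::dist(hull)
  max(d)
}

# min Feret diameter via rotating calipers: for a convex polygon the minimum
# width is attained with one caliper flush to an edge
min_feret <- function(hull) {
  n <- nrow(hull)
  if (n < 2L) return(0)
  if (n == 2L) return(0)
  widths <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    # distance of all vertices from the line through edge i-j
    d <- abs((hull[, 1] - hull[i, 1]) * e[2] - (hull[, 2] - hull[i, 2]) * e[1]) / len
    max(d)
  }, numeric(1))
  min(widths)
}

# Moore-neighbour boundary tracing; returns ordered boundary pixel coords
# (0-based, row/col). Assumes a single 8-connected region.
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  idx <- which(pad)
  start <- idx[1] # column-major: lowest column, then row -> leftmost-topmost
  sr <- ((start - 1L) %% (nr + 2L)) + 1L
  sc <- ((start - 1L) %/% (nr + 2L)) + 1L
  # clockwise Moore neighbourhood starting from W
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  boundary <- matrix(NA_integer_, nrow = 4L * (nr * nc), ncol = 2L)
  cr <- sr; cc <- sc; b <- 1L # backtrack direction index (came from W)
  nb <- 0L
  repeat {
    nb <- nb + 1L
    boundary[nb, ] <- c(cr, cc)
    found <- FALSE
    for (k in 0:7) {
      j <- ((b + k) %% 8L) + 1L
      tr <- cr + dr[j]; tc <- cc + dc[j]
      if (pad[tr, tc]) {
        # new backtrack: direction opposite the step that found the pixel,
        # rotated one past it
        b <- (j + 4L) %% 8L
        cr <- tr; cc <- tc
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel
    if (cr == sr && cc == sc) break
    if (nb >= nrow(boundary)) break
  }
  cbind(row = boundary[seq_len(nb), 1] - 1L, col = boundary[seq_len(nb), 2] - 1L)
}

# Chain-code perimeter with Vossepoel--Smeulders corrected step weights
# (0.948 per axial step, 1.340 per diagonal step); reduces the systematic
# overestimate of raw 1/sqrt(2) weights to well under 1% for smooth shapes.
chain_code_perimeter <- function(boundary) {
  n <- nrow(boundary)
  if (n < 2L) return(4) # single pixel: its own square outline
  nxt <- rbind(boundary[-1, , drop = FALSE], boundary[1, , drop = FALSE])
  step <- abs(nxt - boundary)
  axial <- sum(step[, 1] + step[, 2] == 1L)
  diag <- sum(step[, 1] == 1L & step[, 2] == 1L)
  0.948 * axial + 1.340 * diag
}

# boundary pixels without ordering: foreground with a 4-neighbour background
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !core
}

# --- feature computation -------------------------------------------------

#' Compute a nuclear feature vector from a mask region
#'
#' Computes one of the three feature schemas for a single connected region.
#' Coordinates are 0-based pixel indices; centroids sit at pixel centres;
#' areas are pixel counts scaled by `pixel_size^2`.
#'
#' Definitions (for a region R with pixel set P, centroid c):
#' * `FormFactor` / `Circularity`: `4*pi*Area / Perimeter^2` (1 for a circle).
#' * `Elongation`: minor/major axis of the second-moment best-fit ellipse.
#' * `GyrationRadius`: RMS distance of pixels from the centroid.
#' * `Compactness`: mean distance of pixels from the centroid.
#' * `ChordRatio`: MinFeret/MaxFeret (caliper diameters from the convex
#'   hull of pixel corners, min width by rotating calipers).
#' * `Displacement`: distance between the intensity-weighted and geometric
#'   centroids divided by the gyration radius; requires `intensity`.
#' * `Eccentricity`: `sqrt(1 - (minor/major)^2)`.
#'
#' @param mask Logical matrix selecting one region, or an integer label
#'   matrix combined with `label`.
#' @param fset A `feature_set` or schema name.
#' @param pixel_size Micrometres per pixel (default 0.5).
#' @param intensity Optional numeric matrix of matching dimension; needed
#'   for `Displacement`.
#' @param label Region label when `mask` is a label matrix.
#' @return Named numeric vector over the schema's features.
#' @export
compute_features <- function(mask, fset = "core7", pixel_size = 0.5,
                             intensity = NULL, label = NULL) {
  fset <- as_feature_set(fset)
  assert_scalar_number(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (!is.matrix(mask)) stop("'mask' must be a matrix", call. = FALSE)
  if (!is.logical(mask)) {
    if (is.null(label)) {
      mask <- mask > 0
    } else {
      mask <- mask == label
    }
  }
  npix <- sum(mask)
  if (npix < 4L) {
    stop("degenerate shape: region has ", npix,
         " pixels (minimum 4 required)", call. = FALSE)
  }
  if (!is.null(intensity) && !all(dim(intensity) == dim(mask))) {
    stop("'intensity' must match the mask dimensions", call. = FALSE)
  }

  co <- region_coords(mask)
  ps <- pixel_size
  area <- npix * ps^2
  cen <- colMeans(co)

  # central second moments with the 1/12 pixel-extent correction
  dr <- co[, 1] - cen[1]; dcc <- co[, 2] - cen[2]
  mu20 <- mean(dr^2) + 1 / 12
  mu02 <- mean(dcc^2) + 1 / 12
  mu11 <- mean(dr * dcc)
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2 # major eigenvalue
  l2 <- (mu20 + mu02 - common) / 2
  major_len <- 4 * sqrt(l1) * ps
  minor_len <- 4 * sqrt(max(l2, 0)) * ps
  axis_ratio <- if (major_len > 0) minor_len / major_len else 1
  ecc <- sqrt(max(0, 1 - axis_ratio^2))

  d <- sqrt(dr^2 + dcc^2) * ps
  gyration <- sqrt(mean(d^2))
  compact <- mean(d)

  bnd <- trace_boundary(mask)
  perim <- chain_code_perimeter(bnd) * ps
  form_factor <- 4 * pi * area / perim^2

  hull <- pixel_center_hull(co)
  fmax <- (max_feret(hull) + 0.5) * ps
  fmin <- (min_feret(hull) + 0.5) * ps
  chord_ratio <- if (fmax > 0) fmin / fmax else 1

  need <- fset$features
  out <- stats::setNames(numeric(length(need)), need)

  for (f in need) {
    out[[f]] <- switch(f,
      Area = area,
      FormFactor = min(form_factor, 1),
      Circularity = min(form_factor, 1),
      Elongation = axis_ratio,
      Compactness = compact,
      ChordRatio = chord_ratio,
      GyrationRadius = gyration,
      Displacement = {
        if (is.null(intensity)) {
          stop("Displacement requires an intensity image", call. = FALSE)
        }
        w <- intensity[mask]
        if (sum(w) <= 0) stop("non-positive intensity mass", call. = FALSE)
        icen <- c(sum(co[, 1] * w), sum(co[, 2] * w)) / sum(w)
        sqrt(sum((icen - cen)^2)) * ps / gyration
      },
      Eccentricity = ecc,
      MaxCaliper = fmax,
      MinCaliper = fmin,
      MaxFeretDiameter = fmax,
      MinFeretDiameter = fmin,
      Perimeter = perim,
      BoundingBoxArea = (diff(range(co[, 1])) + 1) * (diff(range(co[, 2])) + 1) * ps^2,
      ConvexArea = convex_pixel_count(co) * ps^2,
      EquivalentDiameter = sqrt(4 * area / pi),
      Extent = npix / ((diff(range(co[, 1])) + 1) * (diff(range(co[, 2])) + 1)),
      Solidity = min(1, npix / convex_pixel_count(co)),
      MajorAxisLength = major_len,
      MinorAxisLength = minor_len,
      MaxRadius = {
        bp <- region_coords(boundary_pixels(mask))
        max(sqrt((bp[, 1] - cen[1])^2 + (bp[, 2] - cen[2])^2)) * ps
      },
      MeanRadius = {
        bp <- region_coords(boundary_pixels(mask))
        mean(sqrt((bp[, 1] - cen[1])^2 + (bp[, 2] - cen[2])^2)) * ps
      },
      MedianRadius = {
        bp <- region_coords(boundary_pixels(mask))
        stats::median(sqrt((bp[, 1] - cen[1])^2 + (bp[, 2] - cen[2])^2)) * ps
      },
      stop("unsupported feature: ", f, call. = FALSE)
    )
  }
  out
}

#' Extract per-nucleus records from a labelled mask
#'
#' Runs [compute_features()] for every label and assembles a feature table
#' with identifiers, centroids (micrometres) and bounding-box information
#' needed by [qc_filter()].
#'
#' @param labels Integer label matrix (0 = background).
#' @param fset Feature schema.
#' @param pixel_size Micrometres per pixel.
#' @param intensity Optional intensity image (enables `Displacement` and
#'   records the per-nucleus mean intensity).
#' @param image_id Optional identifier copied to every row.
#' @return Data frame: one row per nucleus.
#' @export
extract_nuclei <- function(labels, fset = "core7", pixel_size = 0.5,
                           intensity = NULL, image_id = NA_character_) {
  fset <- as_feature_set(fset)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  rows <- lapply(ids, function(l) {
    m <- labels == l
    fv <- compute_features(m, fset, pixel_size, intensity = intensity)
    co <- region_coords(m)
    cen <- colMeans(co)
    data.frame(
      nucleus_id = l,
      image_id = image_id,
      centroid_x = cen[2] * pixel_size,
      centroid_y = cen[1] * pixel_size,
      bbox_min_row = min(co[, 1]), bbox_max_row = max(co[, 1]),
      bbox_min_col = min(co[, 2]), bbox_max_col = max(co[, 2]),
      mean_intensity = if (is.null(intensity)) NA_real_ else mean(intensity[m]),
      t(fv)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "feature_set") <- fset$name
  attr(out, "pixel_size") <- pixel_size
  attr(out, "image_dim") <- dim(labels)
  out
}

#' Apply acquisition quality-control filters to nucleus records
#'
#' Removes edge-touching objects, objects outside the equivalent-diameter
#' window, and under-intensity objects. Filters never fail: every exclusion
#' is logged with its reason.
#'
#' @param records Data frame from [extract_nuclei()] (or with compatible
#'   `bbox_*`, `Area` and optionally `mean_intensity` columns).
#' @param qc A `qc_params` object.
#' @param image_dim Image dimension `c(nrow, ncol)`; defaults to the
#'   attribute stored by [extract_nuclei()].
#' @return List with `kept` (data frame) and `excluded` (data frame with an
#'   added `reason` column, one of `"edge"`, `"diameter"`, `"intensity"`).
#' @export
qc_filter <- function(records, qc = qc_params(), image_dim = NULL) {
  stopifnot(inherits(qc, "qc_params"))
  image_dim <- image_dim %||% attr(records, "image_dim")
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  if (qc$exclude_edge_objects && !is.null(image_dim)) {
    edge <- records$bbox_min_row <= 0 | records$bbox_min_col <= 0 |
      records$bbox_max_row >= image_dim[1] - 1 |
      records$bbox_max_col >= image_dim[2] - 1
    reason[is.na(reason) & edge] <- "edge"
  }
  eqd <- sqrt(4 * records$Area / pi)
  out_d <- eqd < qc$min_diameter | eqd > qc$max_diameter
  reason[is.na(reason) & out_d] <- "diameter"
  if (!is.null(qc$min_intensity) && "mean_intensity" %in% names(records)) {
    dim_i <- !is.na(records$mean_intensity) &
      records$mean_intensity < qc$min_intensity
    reason[is.na(reason) & dim_i] <- "intensity"
  }
  keep <- is.na(reason)
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded) > 0L) excluded$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], excluded = excluded)
}
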