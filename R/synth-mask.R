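#' Generate a synthetic nucleus mask
#'
#' Rasterizes a perturbed ellipse standing in for a DAPI-stained nucleus.
#' The boundary is an ellipse whose polar radius is modulated by low-order
#' harmonic noise, `r(theta) = r_ell(theta) * (1 + sum_k c_k cos(k theta +
#' phi_k))`, k = 2..5. The senescent archetype draws larger axes and
#' stronger boundary perturbation than the normal archetype, mirroring the
#' enlarged, more irregular nuclei of senescent cells. The generating
#' parameters are returned so analytic oracles exist for every feature.
#'
#' @param archetype `"normal"` or `"senescent"`.
#' @param seed Integer seed; the mask is a pure function of
#'   archetype + seed + image_size.
#' @param image_size Side of the square output image in pixels.
#' @param perturbation Overall multiplier on the harmonic amplitudes; 0
#'   yields an exact rasterized ellipse.
#' @return List with `mask` (integer matrix, background 0 / nucleus 1),
#'   `params` (semi-axes `a`, `b` in pixels, `center`, `angle`, harmonic
#'   amplitudes and phases) and `archetype`.
#' @export
generate_nucleus_mask <- function(archetype = c("normal", "senescent"),
                                  seed = 1L, image_size = 96L,
                                  perturbation = 1) {
  archetype <- match.arg(archetype)
  assert_scalar_number(image_size, "image_size", lower = 8)
  assert_scalar_number(perturbation, "perturbation", lower = 0)
  params <- with_seed(child_seed(seed, "mask"), {
    if (archetype == "normal") {
      a <- stats::runif(1, 8, 12)
      amp_hi <- 0.04
    } else {
      a <- stats::runif(1, 14, 20)
      amp_hi <- 0.10
    }
    b <- a * stats::runif(1, 0.65, 0.95)
    list(
      a = a, b = b,
      angle = stats::runif(1, 0, pi),
      amplitudes = perturbation * stats::runif(4, 0.2 * amp_hi, amp_hi),
      phases = stats::runif(4, 0, 2 * pi),
      center = c(image_size / 2, image_size / 2)
    )
  })
  rmax <- params$a * (1 + sum(params$amplitudes))
  if (2 * rmax + 2 > image_size) {
    stop("image_size (", image_size, ") too small for semi-major axis a = ",
         round(params$a, 2), " with perturbation; need at least ",
         ceiling(2 * rmax + 2), call. = FALSE)
  }
  mask <- rasterize_perturbed_ellipse(params, image_size)
  list(mask = mask, params = params, archetype = archetype)
}

# inside test in polar coordinates around the center, pixel centres at
# integer coordinates (0-based)
rasterize_perturbed_ellipse <- function(p, n) {
  xs <- (0:(n - 1)) - p$center[2]
  ys <- (0:(n - 1)) - p$center[1]
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  xr <- X * cos(p$angle) + Y * sin(p$angle)
  yr <- -X * sin(p$angle) + Y * cos(p$angle)
  theta <- atan2(yr, xr)
  # ellipse polar radius
  rell <- p$a * p$b / sqrt((p$b * cos(theta))^2 + (p$a * sin(theta))^2)
  mod <- 1
  for (k in seq_along(p$amplitudes)) {
    mod <- mod + p$amplitudes[k] * cos((k + 1) * theta + p$phases[k])
  }
  r <- sqrt(xr^2 + yr^2)
  m <- matrix(0L, n, n)
  m[r <= rell * mod] <- 1L
  m
}
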