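# Analytic shape rasterizers used as oracles across the feature tests.

raster_disc <- function(r, n = 2 * r + 11) {
  cen <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - cen)^2 + (j - cen)^2 <= r^2)
}

raster_ellipse <- function(a, b, theta = 0, n = 2 * a + 11) {
  cen <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) {
    x <- j - cen; y <- i - cen
    xr <- x * cos(theta) + y * sin(theta)
    yr <- -x * sin(theta) + y * cos(theta)
    (xr / a)^2 + (yr / b)^2 <= 1
  })
}

# Ramanujan's ellipse perimeter approximation (error << test tolerances)
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

flat_intensity <- function(mask) matrix(1, nrow(mask), ncol(mask))

# random valid tissue6 reference pair (strictly positive, P^S != P^N)
random_reference <- function() {
  fs <- feature_set("tissue6")
  p_n <- stats::setNames(runif(6, 0.2, 50), fs$features)
  # senescent values shift up for some features and down for others
  p_s <- p_n * runif(6, 1.05, 4)^sample(c(-1, 1), 6, replace = TRUE)
  ideal_reference(p_n, p_s)
}

small_training_set <- function(n_per_class = 500, effect = 1, seed = 1) {
  build_training_set(
    generate_population_table(
      population_spec(n_per_class * 2, 0, effect_scale = effect,
                      seed = seed * 1000 + 1)),
    generate_population_table(
      population_spec(n_per_class * 2, 1, effect_scale = effect,
                      seed = seed * 1000 + 2)),
    n_per_class = n_per_class, seed = seed)
}
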