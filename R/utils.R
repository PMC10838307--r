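# Internal helpers shared across modules.

# One global seed expands to per-stage child seeds by a fixed affine scheme:
# child = (seed * 48271 + stage_offset) mod (2^31 - 1), stage offsets fixed
# per stage name. Documented in the methods vignette; keeps all generators
# independent of call order while driven by a single user seed.
.stage_offsets <- c(
  mask = 101L, population = 211L, screen = 307L, tissue = 401L,
  training = 503L, forest = 601L, holdout = 701L, noise = 811L
)

child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  off <- .stage_offsets[[stage]]
  if (is.null(off)) stop("unknown seed stage: ", stage, call. = FALSE)
  as.integer((as.numeric(seed) %% 40000 * 48271 + off) %% (2^31 - 1))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# round-half-even integer split of n into a "senescent" share
round_half_even <- function(x) round(x) # base R round() is half-to-even

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
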