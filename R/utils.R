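# Internal helpers: seed handling, argument checks, tensor containers.

# Derive a deterministic child seed for a named substream so that, e.g., the
# latency stream can be redrawn without perturbing the noise stream. Plain
# string hash folded into [0, 2^31 - 2].
substream_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.numeric(seed) * 48271 + h * 1009) %% 2147483647
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  x
}

check_count <- function(x, name, lower = 1) {
  check_number(x, name, lower = lower)
  if (x != round(x)) abort(sprintf("`%s` must be a whole number.", name))
  as.integer(x)
}

# population standard deviation (n denominator)
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

add_one_p <- function(n_extreme, n_total) {
  (1 + n_extreme) / (n_total + 1)
}
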