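# Shared small helpers. Internal only.

# trapezoid integral on an arbitrary increasing grid
trapz_int <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  pracma::trapz(x, y)
}

assert_increasing <- function(x, what = "grid") {
  if (any(!is.finite(x)) || any(diff(x) <= 0)) {
    abort(sprintf("%s must be a finite, strictly increasing numeric vector", what))
  }
  invisible(x)
}

# seeded evaluation without touching the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive a reproducible child seed below 2^31 from a root seed and a tag
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  (as.integer(seed) + (h %% 1000003L)) %% 2147483587L
}
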