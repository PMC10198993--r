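# shared input checks

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_number(x, name)
  if (x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

assert_probability <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

# run code under a fixed RNG seed without disturbing the caller's RNG stream
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

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "mirfish", mustWork = FALSE)
  if (identical(path, "")) {
    abort(sprintf("Packaged data file '%s' not found.", file))
  }
  path
}
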