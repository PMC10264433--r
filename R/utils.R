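#' @keywords internal
"_PACKAGE"

# Evaluate expr with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stop_labeled <- function(label, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(label, "forcepsml_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# population standard deviation (divides by n, not n - 1)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
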