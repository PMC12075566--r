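#' @keywords internal
"_PACKAGE"

# Internal assertion helper: stop() with a classed condition so callers and
# tests can distinguish user-input errors from config errors.
abort <- function(msg, class = "metscreen_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_input <- function(msg) abort(msg, class = c("metscreen_input_error", "metscreen_error"))
abort_config <- function(msg) abort(msg, class = c("metscreen_config_error", "metscreen_error"))

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Unit-normalize a vector; zero vectors are rejected.
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort_input("cannot normalize a zero-length vector")
  v / n
}

# Deterministic child seed derived from a base seed and a stream label.
# Keeps every derived seed a valid 32-bit integer.
child_seed <- function(seed, stream) {
  stopifnot(is_number(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(as.numeric(seed)) * 1009 + h * 7919) %% 2147483647)
}

# Run an expression under a local RNG state so library code never perturbs
# the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Sample (n-1) standard deviation wrapper, named for clarity at call sites.
sample_sd <- function(x) stats::sd(x)
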