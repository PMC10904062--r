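#' @keywords internal
"_PACKAGE"

# Derive a per-stay, per-purpose RNG seed below 2^31.  Constants kept small
# enough that every intermediate product stays exact in double precision.
substream_seed <- function(seed, stay_index, purpose = 0L) {
  base <- (as.numeric(seed) %% 94906249) + 1
  ((base * 10007 + as.numeric(stay_index) * 131 + as.numeric(purpose)) %%
     2147483629) + 1
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-broadcast addition of a vector to every row of a matrix.
add_rowvec <- function(m, v) m + rep(v, each = nrow(m))

`%||%` <- function(a, b) if (is.null(a)) b else a
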