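# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# integer-valued check that tolerates double storage
is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

stop_domain <- function(...) stop(..., call. = FALSE)

# derive a reproducible child seed < 2^31 from a parent seed and an index
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 + 104729 * as.numeric(index)) %% 2147483647)
}
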