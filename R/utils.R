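# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

# A/T and C/G pairs cannot be strand-resolved from alleles alone.
.is_palindromic <- function(a1, a2) {
  unname(.complement[a1] == a2)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .stopf("'%s' must be a single finite number", name)
  }
  invisible(x)
}
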