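#' @keywords internal
"_PACKAGE"

# Validation helper: stop with a consistent error class so callers can
# distinguish user-input problems from programming errors.
abort_invalid <- function(msg, class = "mrisim_validation_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is_scalar_number(x))
    abort_invalid(sprintf("'%s' must be a single finite number", name))
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    abort_invalid(sprintf("'%s' = %g out of range %s%g, %g]", name, x,
                          if (strict_lower) "(" else "[", lower, upper))
  invisible(x)
}

#' Derive a reproducible sub-stream seed from a root seed and a label
#'
#' Every stochastic stage of a simulation (phantom texture, thermal noise for
#' entry e slice s, ...) draws from its own seed derived deterministically
#' from the single root seed and a stage label, so that adding or removing
#' one artifact never perturbs the random stream of another.
#'
#' @param seed integer root seed.
#' @param label character stage label, e.g. `"noise/entry1/slice3"`.
#' @return an integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# 2-D fftshift / inverse fftshift (DC <-> matrix centre). For even N the two
# coincide; both are kept for odd-sized matrices.
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(seq(floor(nr / 2) + 1L, nr), seq_len(floor(nr / 2))),
    c(seq(floor(nc / 2) + 1L, nc), seq_len(floor(nc / 2)))]
}

ifftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(seq(nr - floor(nr / 2) + 1L, nr), seq_len(nr - floor(nr / 2))),
    c(seq(nc - floor(nc / 2) + 1L, nc), seq_len(nc - floor(nc / 2)))]
}

# index (1-based) of the DC row/column in a DC-centred matrix
dc_index <- function(n) floor(n / 2) + 1L
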