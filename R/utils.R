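#' @keywords internal
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_num <- function(x, field, lower = -Inf, upper = Inf, len = 1L,
                      integer = FALSE) {
  if (!is.numeric(x) || length(x) != len || anyNA(x))
    stop_field(field, sprintf("must be numeric of length %d", len))
  if (any(x < lower) || any(x > upper))
    stop_field(field, sprintf("must be in [%s, %s]", lower, upper))
  if (integer && any(x != round(x)))
    stop_field(field, "must be a whole number")
  invisible(x)
}

#' Derive a reproducible stream seed from a master seed
#'
#' Mixes a master seed with any number of integer-like components (stage
#' index, design index, replicate index, ...) through a multiplicative
#' congruential hash, so every stage of a pipeline run gets its own
#' deterministic seed below 2^31.
#'
#' @param master integer master seed.
#' @param ... integer components identifying the stream (characters are
#'   hashed by their UTF-8 bytes).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "simulate", 3, 1)
derive_seed <- function(master, ...) {
  parts <- list(...)
  s <- as.double(master) %% 2147483647
  mix <- function(s, k) ((s * 48271) %% 2147483647 + k) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(paste(p, collapse = ""))) else p <- as.double(p)
    s <- mix(s, p)
  }
  s <- mix(s, 17)
  as.integer(s %% 2147483645L + 1)
}

# quantile convention used for every P5/P95 in the package
pquant <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))
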