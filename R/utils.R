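#' @keywords internal
"_PACKAGE"

#' Derive a named sub-stream seed from a master seed
#'
#' All stochastic operations in the package draw their randomness from one
#' master seed via named sub-streams, so that individual stages of a pipeline
#' can be re-run in isolation with unchanged results.
#'
#' @param seed Integer master seed.
#' @param stream Character name of the sub-stream (e.g. `"simulate_choices"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483629  # large prime < 2^31
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(stream)) {
    h <- (h * 131 + k) %% m
  }
  as.integer(h)
}

# internal: set.seed on a sub-stream (NULL seed leaves the RNG untouched)
set_substream <- function(seed, stream) {
  if (!is.null(seed)) set.seed(substream_seed(seed, stream))
  invisible(NULL)
}

# internal: stopifnot with a formatted message
fail_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

# internal: canonical comma-joined representation of an allele set
set_to_string <- function(x) paste(sort(unique(x)), collapse = ",")

string_to_set <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
}
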