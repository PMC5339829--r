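#' Deterministic child seeds from a master seed
#'
#' Derives a reproducible 31-bit child seed from a master seed, a stream name
#' and an index, so that per-subject / per-stage randomness is independent of
#' execution order but fully determined by the master seed.
#'
#' @param master_seed integer master seed.
#' @param stream character stream label (e.g. `"subject"`, `"nulls"`).
#' @param index non-negative integer within the stream.
#' @return An integer in `[0, 2^31 - 1]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "subject", 3)
derive_seed <- function(master_seed, stream = "default", index = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(index), index >= 0)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  # 64-bit-safe mixing in double arithmetic, reduced mod 2^31 - 1
  m <- 2147483647
  x <- (as.double(master_seed) %% m)
  x <- (x * 48271 + h) %% m
  x <- (x * 48271 + as.double(index) + 1) %% m
  as.integer(x)
}

# round-half-up edge-count rule used by sparsity thresholding
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_param("`%s` must be a single number in [0, 1], got %s", name,
               paste(format(x), collapse = ","))
  invisible(x)
}
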