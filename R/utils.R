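`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded operations do not perturb the global stream.
#' A `NULL` seed evaluates `code` under the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Clip to the 14-bit range and round to camera units; returns an integer
## matrix and the number of clipped pixels as an attribute.
clip14 <- function(x) {
  d <- dim(x)
  n_clip <- sum(x < 0 | x > INTENSITY_MAX)
  x <- pmin.int(pmax.int(round(x), 0), INTENSITY_MAX)
  storage.mode(x) <- "integer"
  dim(x) <- d
  attr(x, "clipped_px") <- n_clip
  x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
msgf <- function(fmt, ...) message(sprintf(fmt, ...))

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

## Fast exact median of an integer vector (radix sort).
median_int <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  s <- sort.int(x, method = "radix")
  if (n %% 2L == 1L) as.numeric(s[(n + 1L) %/% 2L])
  else (as.numeric(s[n %/% 2L]) + as.numeric(s[n %/% 2L + 1L])) / 2
}
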