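#' Derive a reproducible substream seed
#'
#' Expands one global seed into independent per-component seeds via a
#' counter/hash scheme, so adding a pipeline stage never perturbs the random
#' stream of an earlier one.
#'
#' @param seed integer global seed.
#' @param tag character label of the component/stage.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, tag) {
  stopifnot(is.character(tag), length(tag) == 1L)
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

# validate a numeric scalar
.check_scalar <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  invisible(TRUE)
}

# coerce colours to an n x 3 numeric matrix
.as_color_matrix <- function(x, name = "colour") {
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L)
      stop(sprintf("'%s' must have 3 channels", name), call. = FALSE)
    x <- matrix(as.numeric(x), ncol = 3L, byrow = length(x) > 3L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("'%s' must have 3 columns", name), call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# lab image array (h x w x 3) -> n x 3 matrix and back
.flatten_lab <- function(lab) {
  stopifnot(length(dim(lab)) == 3L, dim(lab)[3] == 3L)
  dim(lab) <- c(prod(dim(lab)[1:2]), 3L)
  lab
}
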