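#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local, reproducible RNG state
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' stream afterwards, so seeded helpers do not perturb each other.
#'
#' @param seed Integer seed, or `NULL` to use the current stream as-is.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Geometric mean
#'
#' @param x Positive numeric vector.
#' @param na.rm Drop `NA`s first.
#' @return `exp(mean(log(x)))`; `NA` for an empty vector.
#' @export
#' @examples
#' geometric_mean(c(1e-4, 1e-2)) # 1e-3
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# log(sum(exp(x))) without overflow
log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# derive a child seed from a parent seed and a stage label, staying < 2^31
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
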