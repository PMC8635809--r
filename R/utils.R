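#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_dbl map_int map_lgl imap pmap
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom stats median var sd cor dhyper pt qnorm rnorm runif rlnorm
#'   rnbinom rbinom setNames complete.cases hclust cutree dist cor.test
#'   model.matrix
#' @importFrom utils head tail
NULL

# single place for input sanity checks so error wording stays uniform
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

# geometric mean ignoring nothing; caller guarantees positivity
geomean <- function(x) exp(mean(log(x)))

new_tbl_subclass <- function(x, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c(class, class(x))
  x
}
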