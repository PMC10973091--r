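#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows across n row_number if_else pull rename
#' @importFrom stats lm coef qnorm rnorm rpois sd setNames predict t.test
#'   approx median complete.cases
#' @importFrom utils head tail
NULL

# Multiplicative lognormal noise with unit mean: exp(N(-s^2/2, s^2)),
# s^2 = log(1 + cv^2), so E[noise] = 1 and sd/mean = cv.
lognormal_noise <- function(n, cv) {
  if (cv < 0) abort("`cv` must be non-negative.")
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

# Evaluate a function under a fixed RNG seed without disturbing the
# caller's RNG stream; seed = NULL uses the current stream.
with_sim_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

assert_number <- function(x, name, positive = FALSE, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be strictly positive.", name))
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s].", name, format(lower), format(upper)))
  }
  invisible(x)
}

assert_columns <- function(data, cols, name = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
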