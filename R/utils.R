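#' @importFrom stats plogis qlogis rnorm rbinom rexp rlogis runif sd cor
#'   quantile glm glm.fit lm binomial coef predict var pchisq setNames
#' @importFrom utils head
NULL

# Clip probabilities away from 0/1 before taking logs or logits.
clip_prob <- function(p, eps = 1e-6) {
  pmin(pmax(p, eps), 1 - eps)
}

# Derive a child seed from a base seed; kept within 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 997 * as.numeric(k)) %% 2147483647L)
}

stop_data <- function(...) stop(..., call. = FALSE)

check_binary <- function(y, name = "labels") {
  if (anyNA(y)) stop_data(name, " contain missing values")
  if (!all(y %in% c(0, 1))) stop_data(name, " must be binary 0/1")
  invisible(y)
}

check_two_classes <- function(y, name = "labels") {
  check_binary(y, name)
  if (length(unique(y)) < 2L)
    stop_data(name, " contain a single class (", sum(y), " cases of ",
              length(y), ")")
  invisible(y)
}
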