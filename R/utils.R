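# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows distinct across n pull rename row_number case_when
#' @importFrom purrr map map_dbl map_lgl imap list_rbind
#' @importFrom stats median rnorm rpois rbinom rnbinom runif rbeta rgamma
#'   setNames cor dist hclust quantile sd var pt dbinom
#' @importFrom utils head tail
NULL

# Stop with a classed condition so callers/tests can distinguish user error.
stop_input <- function(msg) {
  abort(msg, class = "concord_input_error")
}

check_positive_int <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x)) {
    stop_input(sprintf("`%s` must be a single positive integer, got %s",
                       name, deparse(x)))
  }
  as.integer(x)
}

# All stochastic entry points funnel through this so the caller's RNG
# state is never disturbed and the same seed always reproduces output.
with_seed <- function(seed, code) {
  seed <- check_positive_int(seed, "seed")
  withr::with_seed(seed, code)
}

# Derive distinct child seeds from one parent seed (kept < 2^31).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
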