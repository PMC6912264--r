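# Internal validation helpers shared across modules.

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min) {
    stop_config(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_number <- function(x, field, min = -Inf, max = Inf, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= min && x <= max
  if (!ok) stop_config(field, sprintf("must be a single number in [%s, %s]", min, max))
  as.numeric(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_config(field, "must be TRUE or FALSE")
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
group_id <- function(treatment, duration) paste(treatment, duration, sep = "_")

TREATMENTS <- c("si-NT", "si-hVDAC1")
DURATIONS <- c("short", "long")

#' The four experimental groups
#'
#' Group labels for the 2 x 2 design: treatment (non-targeting siRNA vs.
#' VDAC1-silencing siRNA) crossed with treatment duration (short vs. long).
#'
#' @return Character vector of the four group ids, `"<treatment>_<duration>"`.
#' @export
design_groups <- function() {
  as.vector(outer(TREATMENTS, DURATIONS, group_id))
}
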