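#' @importFrom stats coef lm median pnorm pt qnorm qt rbinom rexp rlnorm rnorm
#'   runif sd setNames t.test var complete.cases
#' @importFrom utils head tail
NULL

# Classed condition helpers: every recoverable pipeline failure carries a
# machine-readable class so process_cohort() can turn it into an exclusion
# reason code instead of aborting the run.
mf_stop <- function(class, message, ...) {
  stop(structure(
    class = c(class, "metflexr_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

mf_insufficient_data <- function(message) mf_stop("metflexr_insufficient_data", message)
mf_no_steady_state <- function(message) mf_stop("metflexr_no_steady_state", message)
mf_parse_error <- function(message) mf_stop("metflexr_parse_error", message)
mf_domain_error <- function(message) mf_stop("metflexr_domain_error", message)
mf_config_error <- function(message) mf_stop("metflexr_config_error", message)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
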