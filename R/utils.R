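#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Round half away from zero (the convention used for all displayed figures,
# matching how the reference tables were rounded). base::round() rounds half
# to even, which disagrees with printed per-case values.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

coi_error <- function(msg, class) {
  abort(msg, class = c(class, "coi_error"))
}

# Collapse a character vector for error messages.
oxford <- function(x) paste(x, collapse = ", ")
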