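#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
NULL

# Classed condition helper so callers/tests can match on error class.
# Classes look like "craburden_error_fit", "craburden_error_domain", ...
abort_craburden <- function(message, class, ...) {
  rlang::abort(message, class = paste0("craburden_error_", class), ...)
}

#' Round half away from zero
#'
#' Rounding used by the reporting layer so that printed values match the
#' conventional presentation of burden tables (2.5 -> 2.5 at 1 dp, 0.005 ->
#' 0.01 at 2 dp), rather than R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# draw-column helpers: draw values live in wide columns draw_1 ... draw_n
draw_cols <- function(tbl) grep("^draw_\\d+$", names(tbl), value = TRUE)

has_draws <- function(tbl) length(draw_cols(tbl)) > 0

draw_matrix <- function(tbl) {
  as.matrix(tbl[draw_cols(tbl)])
}
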