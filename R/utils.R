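#' Round half away from zero
#'
#' Decimal rounding where exact halves round up (away from zero), the
#' convention used for printed odds ratios and percentages in study reports.
#' Base R's `round()` follows IEC 60559 round-half-even, which turns a
#' cross-product odds ratio of exactly 44.855 into 44.85 rather than the
#' conventionally printed 44.86.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
#' @examples
#' round_half_up(44.855, 2) # 44.86
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

## effect classes recognised throughout the package
EFFECT_CLASSES <- c("synonymous", "missense", "inframe_indel", "ptv")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  stop_if(length(missing) > 0,
          sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  invisible(df)
}
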