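
# internal input checks ------------------------------------------------------

assert_cols <- function(x, cols, what = deparse(substitute(x))) {
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0L) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(x)
}

assert_scalar_num <- function(x, what, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  what, format(lower), format(upper)))
  }
  invisible(x)
}
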