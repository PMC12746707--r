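# Shared internal helpers.

# round() in R rounds half to even; printed tables in this field round half up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Three-significant-figure scientific notation, e.g. 4.23e-05.
format_sigfig <- function(x, digits = 3) {
  formatC(x, format = "e", digits = digits - 1L)
}

stop_if_not_df <- function(x, arg) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame, not %s.", arg, class(x)[1]))
  }
}

require_columns <- function(df, cols, arg) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf(
      "`%s` is missing required column%s: %s.",
      arg, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
}
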