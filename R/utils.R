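# shared input checks; all user-facing errors go through rlang::abort with
# the stable messages documented for each operation

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (finite && !is.finite(x)) abort(sprintf("`%s` must be finite", name))
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}

check_columns <- function(data, cols, name = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# scalar-or-function(t) profiles used by the waveform generator
as_profile <- function(x, name) {
  if (is.function(x)) return(x)
  check_number(x, name)
  force(x)
  function(t) rep_len(x, length(t))
}
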