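# internal helpers shared across modules

# stop() unless every element of x is finite; `name` is reported so the
# caller can see which input field was bad
check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    bad <- if (is.numeric(x)) which(!is.finite(x))[1L] else 1L
    stop(sprintf("non-finite value in '%s' (first at position %d)", name, bad),
         call. = FALSE)
  }
  invisible(x)
}

as_date_strict <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  d
}

# 1 = Monday ... 7 = Sunday (ISO weekday)
iso_weekday <- function(date) {
  as.integer(format(date, "%u"))
}

#' @importFrom stats setNames
named <- function(x, nm) setNames(x, nm)
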