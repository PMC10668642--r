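#' @keywords internal
"_PACKAGE"

# sprintf-style stop()/warning() without call noise
stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_prob <- function(x) is_num1(x) && x >= 0 && x <= 1
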