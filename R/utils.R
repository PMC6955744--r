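#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# scale tag on expression matrices: "linear" or "log2"
expr_scale <- function(x) attr(x, "scale", exact = TRUE) %||% "linear"

set_expr_scale <- function(x, scale) {
  scale <- match.arg(scale, c("linear", "log2"))
  attr(x, "scale") <- scale
  x
}

stop_if_not_scale <- function(x, scale, what = "matrix") {
  if (!identical(expr_scale(x), scale)) {
    stop(sprintf("%s must be on the %s scale (found '%s')",
                 what, scale, expr_scale(x)), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}
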