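#' @keywords internal
"_PACKAGE"

# Derive a deterministic sub-seed for a named stage from a master seed.
# Keeps all stage seeds < 2^31 and decorrelated across stage names.
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_facetdiv <- function(msg, class) {
  stop(structure(
    class = c(class, "facetdiv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

warn_facetdiv <- function(msg, class) {
  warning(structure(
    class = c(class, "facetdiv_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_facetdiv(sprintf("`%s` must be a single finite number", name),
                  "invalid_argument")
  invisible(x)
}
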