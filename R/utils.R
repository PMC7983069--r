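#' @keywords internal
"_PACKAGE"

# Internal validation helpers ------------------------------------------------

stop_orx <- function(fmt, ..., class = "orx_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

assert_matrix_image <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_orx("%s must be a numeric matrix", name, class = "orx_validation_error")
  if (anyNA(x))
    stop_orx("%s contains missing values", name, class = "orx_validation_error")
  if (any(x < 0))
    stop_orx("%s contains negative intensities", name, class = "orx_validation_error")
  invisible(x)
}

assert_same_dim <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop_orx("%s differ in dimension (%s vs %s)", what,
             paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"),
             class = "orx_validation_error")
  invisible(TRUE)
}

odd_ge <- function(x, lo = 3L) {
  x <- max(as.integer(round(x)), lo)
  if (x %% 2L == 0L) x <- x + 1L
  x
}

# Run an expression with a temporarily-seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Shift a matrix by integer (dy, dx), padding vacated cells with `fill`.
shift_matrix <- function(m, dy, dx, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  if (length(ys) < 1 || length(xs) < 1) return(out)
  out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}
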