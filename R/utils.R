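# Small internal helpers shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

is_rgb <- function(x) is.numeric(x) && length(x) == 3 && all(is.finite(x)) &&
  all(x >= 0) && all(x <= 1)

check_rgb <- function(x, what = "color") {
  if (!is_rgb(x)) stop(sprintf("%s must be 3 numbers in [0, 1]", what))
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

trimws2 <- function(x) gsub("^\\s+|\\s+$", "", x)
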