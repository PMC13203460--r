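#' @keywords internal
"_PACKAGE"

# ---- argument checking ----------------------------------------------------

ff_stop <- function(..., class = "ff_error") {
  stop(errorCondition(paste0(...), class = c(class, "ff_error")))
}

check_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ff_stop(name, " must be a single finite number", class = "ff_argument_error")
  if (x < lo || x > hi)
    ff_stop(name, " must be in [", lo, ", ", hi, "]", class = "ff_argument_error")
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x))
    ff_stop(name, " must be a single integer", class = "ff_argument_error")
  if (x < min)
    ff_stop(name, " must be >= ", min, class = "ff_argument_error")
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(pmax(x, 0), 1)

# ---- deterministic per-entity random streams ------------------------------

# Polynomial string hash folded into a 31-bit integer; combined with a base
# seed this gives each animal its own reproducible stream, independent of
# the order in which animals are processed. Arithmetic stays below 2^52 so
# it is exact in double precision.
hash_string31 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

stream_seed <- function(seed, id) {
  seed <- check_count(seed, "seed")
  as.integer((seed + hash_string31(as.character(id))) %% 2147483647)
}

with_stream <- function(seed, id, code) {
  withr::with_seed(stream_seed(seed, id), code)
}

# ---- internal image helpers -----------------------------------------------

# images are H x W x 3 arrays, values in [0, 1], row-major, origin top-left
check_image <- function(img, name = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    ff_stop(name, " must be an H x W x 3 array", class = "ff_argument_error")
  invisible(img)
}
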