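#' @keywords internal
"_PACKAGE"

# Run expr with a local, restored RNG state so no function touches global
# reproducibility. All exported stochastic operations take an explicit seed.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# round-half-up: round(0.5) in R is banker's rounding; mask counts need the
# exact round(ratio * n) contract with halves going up.
round_half_up <- function(x) floor(x + 0.5)

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- parameter-tree helpers -------------------------------------------------
# Model parameters are nested named lists of numeric arrays. These walk two
# trees with identical shape, used by the optimizer and the momentum update.

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(el) tree_map(f, el))
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    stop_if_not(is.list(b) && length(a) == length(b), "parameter trees mismatched")
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    if (is.list(b) || length(a) != length(b)) stop("parameter trees mismatched", call. = FALSE)
    f(a, b)
  }
}

tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

tree_sum <- function(f, a) {
  if (is.list(a)) sum(vapply(a, function(el) tree_sum(f, el), numeric(1))) else f(a)
}
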