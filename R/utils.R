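# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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

# Derive a child seed from a parent seed and a stream label, staying
# well inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear voxel index (column-major, like R arrays) -> integer matrix of
# (i, j, k) coordinates and back.
vox_coords <- function(idx, dim3) {
  arrayInd(idx, .dim = dim3)
}

stop_npda <- function(msg, class) {
  stop(structure(
    class = c(class, "npda_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
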