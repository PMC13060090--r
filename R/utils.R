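# Seed handling: set a temporary seed and restore the caller's RNG state,
# so seeded helpers do not perturb the global stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Draw n sub-seeds from a master seed (each < 2^31), leaving the caller's
# RNG state untouched. Used to give every Monte-Carlo iteration / shuffle
# its own substream so results do not depend on execution order.
spawn_seeds <- function(master, n) {
  old <- local_seed(master)
  on.exit(restore_seed(old))
  sample.int(.Machine$integer.max, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
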