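# Seed hygiene: set the RNG inside a function without clobbering the caller's
# stream; every stochastic routine takes an explicit seed and restores state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# log-spaced grid
lseq <- function(from, to, length.out) {
  10^seq(log10(from), log10(to), length.out = length.out)
}
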