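#' Derive a reproducible sub-stream seed
#'
#' Hashes an integer master seed together with an arbitrary sequence of
#' string/numeric labels into a seed suitable for [set.seed()]. Every source
#' of randomness in the simulator (connectivity rows, Poisson sources,
#' initial membrane voltages, ...) draws from its own sub-stream keyed this
#' way, so that realized randomness is a pure function of (master seed,
#' stream labels) and is unaffected by how the network is partitioned into
#' virtual cores.
#'
#' @param seed Integer master seed.
#' @param ... Labels (character or numeric scalars) identifying the stream,
#'   e.g. a projection name and a presynaptic neuron id.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stream_seed(42, "proj-ee", 17)
stream_seed <- function(seed, ...) {
  m <- 2147483629 # prime < 2^31
  h <- as.numeric(seed) %% m
  for (lab in list(...)) {
    codes <- if (is.character(lab)) {
      utf8ToInt(lab)
    } else {
      # mix numerics digit-wise so 12 and 1,2 differ from each other
      c(1e6, utf8ToInt(format(lab, scientific = FALSE)))
    }
    h <- (h * 31 + 7) %% m
    for (k in codes) h <- (h * 131 + k) %% m
  }
  as.integer(h)
}

# Evaluate expr with the global RNG temporarily seeded from a sub-stream,
# restoring the caller's RNG state afterwards.
with_stream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, ...))
  expr
}
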