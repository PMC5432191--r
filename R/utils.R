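# Set the RNG seed for the calling function, restoring the caller's RNG
# state when that function exits, so seeded operations are reproducible
# without perturbing the session's random stream.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible())
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    withr::defer(assign(".Random.seed", old, envir = globalenv()),
                 envir = envir)
  } else {
    withr::defer(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                 envir = envir)
  }
  set.seed(seed)
  invisible()
}
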