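# Deterministic per-task RNG streams.
#
# All repeated randomization in the package (bootstrap replicates, simulation
# cycles, per-patient sampling) draws from L'Ecuyer-CMRG streams derived from
# a single integer seed.  Stream k is obtained by advancing the stream
# sequence k times, so results are independent of execution order and of the
# number of parallel workers.

rng_streams <- function(seed, k) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "L'Ecuyer-CMRG")
  streams <- vector("list", k)
  s <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(k)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

with_rng_stream <- function(stream, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  assign(".Random.seed", stream, envir = globalenv())
  expr
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# run fun over 1..k, optionally on several workers; per-index RNG streams
# make the result identical for any worker count
stream_lapply <- function(k, seed, threads, fun) {
  streams <- rng_streams(seed, k)
  worker <- function(i) with_rng_stream(streams[[i]], fun(i))
  if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(k), worker, mc.cores = threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(k), worker)
  }
}
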