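# Internal helpers shared across modules.

# Deterministic per-sensor substreams: one master seed yields a fixed block
# of child seeds per named stream, so results are identical however the
# sensors are chunked or ordered.
substream_seeds <- function(master_seed, n, stream = c("spikes", "noise", "misc", "assembly")) {
  stream <- match.arg(stream)
  block <- match(stream, c("spikes", "noise", "misc", "assembly"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed))
  all <- sample.int(2147483646L, 4L * n)
  all[seq.int((block - 1L) * n + 1L, block * n)]
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` under a local RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

check_proportion <- function(x, name) {
  stopifnot_scalar(x, name)
  if (x < 0 || x > 1) {
    stop(sprintf("'%s' must lie in [0, 1], got %g", name, x), call. = FALSE)
  }
  invisible(x)
}

# 32-bit rolling hash of a character string; used to fingerprint pipeline
# configurations in logs and output headers without extra dependencies.
config_hash32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

sample_skewness <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}
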