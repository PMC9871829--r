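# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Centred moving average with circular (closed-loop) or reflecting edges.
moving_average <- function(x, window, circular = FALSE) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L) return(x)
  k <- rep(1 / window, window)
  if (circular) {
    as.numeric(stats::filter(x, k, sides = 2, circular = TRUE))
  } else {
    # point-symmetric padding: keeps the endpoints unbiased for a locally
    # linear signal (plain reflection would drag them inward)
    h <- (window - 1L) / 2L
    n <- length(x)
    xp <- c(2 * x[1] - rev(x[seq_len(h) + 1L]), x, 2 * x[n] - x[n - seq_len(h)])
    as.numeric(stats::filter(xp, k, sides = 2))[h + seq_along(x)]
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
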