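# internal helpers

# evaluate `expr` under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

cache_get <- function(key, compute) {
  if (!is.null(.icto_cache[[key]])) return(.icto_cache[[key]])
  val <- compute()
  assign(key, val, envir = .icto_cache)
  val
}

# total length of the union of intervals given as a 2-column matrix [start, end)
interval_union_length <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(0)
  o <- order(iv[, 1])
  s <- iv[o, 1]; e <- iv[o, 2]
  tot <- 0; cur_s <- s[1]; cur_e <- e[1]
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] > cur_e) {
        tot <- tot + (cur_e - cur_s)
        cur_s <- s[i]; cur_e <- e[i]
      } else if (e[i] > cur_e) cur_e <- e[i]
    }
  }
  tot + (cur_e - cur_s)
}

# merge overlapping intervals, returning the disjoint sorted union
interval_union <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(matrix(numeric(0), ncol = 2))
  o <- order(iv[, 1])
  s <- iv[o, 1]; e <- iv[o, 2]
  out_s <- s[1]; out_e <- e[1]
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      k <- length(out_s)
      if (s[i] > out_e[k]) {
        out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i])
      } else if (e[i] > out_e[k]) out_e[k] <- e[i]
    }
  }
  cbind(start = out_s, end = out_e)
}

# centred running mean over an odd window; edges filled with adjacent values
running_mean <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  cs <- cumsum(c(0, x))
  h <- (w - 1L) %/% 2L
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# indices of strict-left / weak-right local maxima
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
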