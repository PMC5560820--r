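# shared helpers for the test suite

star5 <- function() igraph::make_star(5, mode = "undirected", center = 1)

# fake simulation object wrapping a hand-built trace, for exercising the
# spike-epoch machinery with explicit thresholds and windows
fake_sim <- function(x, dt_out, model = "wm") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  structure(list(output = x, dt_out = dt_out,
                 duration = ncol(x) * dt_out, model = model,
                 params = if (model == "wm") wm_params() else cm_params(),
                 seed = 0, node_ids = seq_len(nrow(x))),
            class = "ictosim")
}

# brute-force weighted rich-club coefficient (independent of the package
# implementation): explicit club enumeration and edge sorting
phi_oracle <- function(W, k) {
  n <- nrow(W)
  deg <- numeric(n)
  for (i in 1:n) for (j in 1:n) if (i != j && W[i, j] != 0)
    deg[i] <- deg[i] + 1
  club <- which(deg > k)
  if (length(club) < 2) return(NA_real_)
  wsum <- 0; ecnt <- 0
  for (a in seq_along(club)) for (b in seq_along(club)) {
    i <- club[a]; j <- club[b]
    if (i < j && W[i, j] != 0) { wsum <- wsum + W[i, j]; ecnt <- ecnt + 1 }
  }
  if (ecnt == 0) return(NA_real_)
  all_w <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) if (W[i, j] != 0)
    all_w <- c(all_w, W[i, j])
  all_w <- sort(all_w, decreasing = TRUE)
  wsum / sum(all_w[1:ecnt])
}

# independent union-length oracle by fine discretization
union_length_oracle <- function(iv, lo, hi, m = 20000) {
  grid <- seq(lo, hi, length.out = m)
  covered <- rep(FALSE, m)
  for (r in seq_len(nrow(iv)))
    covered <- covered | (grid >= iv[r, 1] & grid < iv[r, 2])
  mean(covered) * (hi - lo)
}

# rank-based AUC for separating two score sets (positives vs negatives)
auc_score <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
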