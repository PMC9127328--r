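# Shared fixtures, built in code.

# noiseless Gaussian spot image; center in 0-based (row, col) pixel coords
gauss_spot_image <- function(n = 64, center = c(31.5, 31.5), amp = 100,
                             sigma_px = 1.5, background = 0,
                             pixel_size_nm = 25) {
  px <- background + outer(
    seq_len(n) - 1, seq_len(n) - 1,
    function(r, c) amp * exp(-((r - center[1])^2 + (c - center[2])^2) /
                               (2 * sigma_px^2)))
  micrograph(px, pixel_size_nm)
}

# maximum-cardinality bipartite matching of true vs detected positions
# within a radius (augmenting-path algorithm); returns the match count
match_count <- function(truth, detected, radius) {
  if (nrow(truth) == 0L || nrow(detected) == 0L) return(0L)
  d2 <- outer(truth[, 1], detected[, 1], "-")^2 +
    outer(truth[, 2], detected[, 2], "-")^2
  adj <- d2 <= radius^2
  matched <- rep(0L, nrow(detected))
  seen <- NULL
  aug <- function(u) {
    for (v in which(adj[u, ])) if (!seen[v]) {
      seen[v] <<- TRUE
      if (matched[v] == 0L || aug(matched[v])) {
        matched[v] <<- u
        return(TRUE)
      }
    }
    FALSE
  }
  n <- 0L
  for (u in seq_len(nrow(truth))) {
    seen <- rep(FALSE, nrow(detected))
    if (aug(u)) n <- n + 1L
  }
  n
}

# membrane ROI covering the emitter placement region of a simulated sheet
sim_interior_roi <- function(sim) {
  m <- ceiling(sim$truth$margin_px)
  d <- dim(sim$img_a$pixels)
  roi_rect(m, m, d[1] - 2 * m, d[2] - 2 * m, "membrane")
}

# brute-force nearest-neighbour oracle: plain per-query loop
nn_oracle <- function(q, t) {
  vapply(seq_len(nrow(q)), function(i)
    sqrt(min((q[i, 1] - t[, 1])^2 + (q[i, 2] - t[, 2])^2)), numeric(1))
}
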