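# Independent oracles used across tests. These deliberately share no code
# with the package implementations they check.

# Topological charge of every 2x2 plaquette of a phase field: the sum of
# wrapped differences around the 4-pixel loop is +/- 2*pi at a singularity
# and 0 elsewhere. Returns the plaquette centers (row + 0.5, col + 0.5).
oracle_plaquette_charges <- function(phase) {
  wrap <- function(x) atan2(sin(x), cos(x))
  H <- nrow(phase); W <- ncol(phase)
  out <- NULL
  for (r in seq_len(H - 1L)) for (c in seq_len(W - 1L)) {
    s <- wrap(phase[r, c + 1L] - phase[r, c]) +
      wrap(phase[r + 1L, c + 1L] - phase[r, c + 1L]) +
      wrap(phase[r + 1L, c] - phase[r + 1L, c + 1L]) +
      wrap(phase[r, c] - phase[r + 1L, c])
    q <- round(s / (2 * pi))
    if (q != 0)
      out <- rbind(out, data.frame(row = r + 0.5, col = c + 0.5,
                                   charge = q))
  }
  if (is.null(out))
    out <- data.frame(row = numeric(), col = numeric(), charge = integer())
  out
}

# Phase field with planted vortices of given charges, plus an optional
# uniform ramp; wrapped to (-pi, pi].
make_vortex_field <- function(H, W, centers, ramp = 0) {
  phase <- matrix(ramp, H, W) * matrix(seq_len(W), H, W, byrow = TRUE)
  if (nrow(centers) > 0) {
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (i in seq_len(nrow(centers)))
      phase <- phase + centers$charge[i] *
        atan2(rr - centers$row[i], cc - centers$col[i])
  }
  atan2(sin(phase), cos(phase))
}

# Random vortex configuration: n vortices inside the margin, pairwise
# separated by at least min_sep.
random_vortices <- function(n, H, W, margin = 12, min_sep = 14) {
  out <- data.frame(row = numeric(), col = numeric(), charge = integer())
  guard <- 0
  while (nrow(out) < n && guard < 500) {
    guard <- guard + 1
    r <- runif(1, margin, H - margin)
    c <- runif(1, margin, W - margin)
    if (nrow(out) == 0 ||
        min(sqrt((out$row - r)^2 + (out$col - c)^2)) >= min_sep)
      out <- rbind(out, data.frame(row = r, col = c,
                                   charge = sample(c(-1L, 1L), 1L)))
  }
  out
}

# Brute-force sliding-window min/max at every sample (centered, truncated)
oracle_window_minmax <- function(x, window) {
  n <- length(x)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  t(vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - half_lo):min(n, i + half_hi)]
    c(min(w), max(w))
  }, c(0, 0)))
}
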