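# Short daytime window so raw-stream fixtures stay small (2 min/day at 25 Hz).
short_day_config <- function(...) {
  filter_config(day_start = "08:00", day_end = "08:02", ...)
}

linear_arch <- function(i0 = 1, s = 0.5) {
  trajectory_archetype("upward_linear", i0 = i0, s = s)
}

sshape_arch <- function(L0 = 1, L1 = 10, t0 = 7, k = 1) {
  trajectory_archetype("s_shape", L0 = L0, L1 = L1, t0 = t0, k = k)
}

# Independent entropy oracle for SU, computed straight from a joint count table.
su_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  hx <- -sum(ifelse(rowSums(p) > 0, rowSums(p) * log2(rowSums(p)), 0))
  hy <- -sum(ifelse(colSums(p) > 0, colSums(p) * log2(colSums(p)), 0))
  hxy <- -sum(ifelse(p > 0, p * log2(p), 0))
  if (hx + hy == 0) return(0)
  2 * (hx + hy - hxy) / (hx + hy)
}

# Expand a joint count table into paired label vectors.
counts_to_vectors <- function(counts) {
  idx <- which(counts > 0, arr.ind = TRUE)
  x <- rep(idx[, 1], counts[counts > 0])
  y <- rep(idx[, 2], counts[counts > 0])
  list(x = x, y = y)
}
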