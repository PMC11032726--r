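# Small deterministic trajectories and independent oracles used across tests.

# straight 1-D unit-step line
line_traj <- function(n = 32) trajectory(0:(n - 1), dt = 1)

# 2-D diagonal unit-variance line (constant-modulus steps)
diag_traj <- function(n = 32) trajectory(cbind(0:(n - 1), 0:(n - 1)), dt = 1)

# L-shaped path (0,0) -> (1,0) -> (1,1)
l_path <- function() trajectory(rbind(c(0, 0), c(1, 0), c(1, 1)), dt = 1)

# square staple (0,0) -> (1,0) -> (1,1) -> (0,1)
staple_path <- function() {
  trajectory(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), dt = 1)
}

# brute-force O(N^2) time-averaged MSD: the independent oracle
msd_brute <- function(pos, n_max) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 1)
  n <- nrow(pos)
  vapply(seq_len(n_max), function(lag) {
    acc <- 0
    for (i in 1:(n - lag)) acc <- acc + sum((pos[i + lag, ] - pos[i, ])^2)
    acc / (n - lag)
  }, numeric(1))
}

# log-log regression oracle independent of anomalous_exponent()
loglog_slope <- function(lags, values) {
  unname(stats::coef(stats::lm(log(values) ~ log(lags)))[2])
}

write_lammps_fixture <- function(path, frames) {
  # frames: list of list(timestep=, keywords=, rows=list(vec,...))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines("---", con)
    writeLines(sprintf("timestep: %d", f$timestep), con)
    writeLines(sprintf("keywords: [%s]", paste(f$keywords, collapse = ", ")), con)
    writeLines("data:", con)
    for (r in f$rows)
      writeLines(sprintf("  - [%s]", paste(r, collapse = ", ")), con)
    writeLines("...", con)
  }
}
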