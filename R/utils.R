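# Internal helpers: angles, quaternions, reproducible RNG streams.

# wrap angles to (-pi, pi]
wrap_angle <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

quat_normalize <- function(q) {
  nrm <- sqrt(sum(q^2))
  if (nrm < 1e-12) return(c(1, 0, 0, 0))
  q / nrm
}

# rotation matrix from unit quaternion (w, x, y, z)
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

# uniform random rotation via normalized 4-Gaussian
quat_random <- function() {
  quat_normalize(stats::rnorm(4))
}

# Rodrigues rotation matrix about unit axis
rotation_matrix_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); v <- 1 - c_
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux * ux * v,      ux * uy * v - uz * s_, ux * uz * v + uy * s_,
    uy * ux * v + uz * s_, c_ + uy * uy * v,      uy * uz * v - ux * s_,
    uz * ux * v - uy * s_, uz * uy * v + ux * s_, c_ + uz * uz * v
  ), nrow = 3, byrow = TRUE)
}

# ---- RNG stream bookkeeping ---------------------------------------------
# Each island owns an independent stream (a saved .Random.seed) derived from
# the master seed and the island id, so trajectories do not depend on the
# order in which the scheduler happens to run the islands.

rng_snapshot <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

rng_restore <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
}

with_preserved_rng <- function(code) {
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  force(code)
}

with_seed <- function(seed, code) {
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  set.seed(seed)
  force(code)
}

# deterministic substream seed, kept below 2^31
derive_seed <- function(master_seed, k) {
  as.integer(((as.double(master_seed) %% 1000003) * 1009 + k * 97 + 11) %% 2147483629)
}

stream_new <- function(seed) {
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  set.seed(seed)
  rng_snapshot()
}

# run `fn()` under `stream`, return list(value, stream) with the advanced state
stream_eval <- function(stream, fn) {
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  rng_restore(stream)
  value <- fn()
  list(value = value, stream = rng_snapshot())
}
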