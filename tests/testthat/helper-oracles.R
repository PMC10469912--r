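# Shared generators and independent oracles.

# random non-degenerate configuration
rand_config <- function(p = 41, scale = 50) {
  matrix(stats::rnorm(2 * p, 0, scale), p, 2)
}

# random similarity transform (rotation + scale + translation, det +1)
rand_similarity <- function(points) {
  th <- stats::runif(1, 0, 2 * pi)
  s <- stats::runif(1, 0.2, 5)
  r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(s * points %*% r, 2, stats::rnorm(2, 0, 100), `+`)
}

# independent closed-form full-Procrustes oracle via complex least squares:
# both configurations centered and scaled to unit norm, the optimal
# rotation+scale is b = <z, conj(w)>, and the residual norm is sqrt(1 - |b|^2)
complex_procrustes_distance <- function(reference, target) {
  z <- complex(real = reference[, 1], imaginary = reference[, 2])
  w <- complex(real = target[, 1], imaginary = target[, 2])
  z <- z - mean(z); w <- w - mean(w)
  z <- z / sqrt(sum(Mod(z)^2)); w <- w / sqrt(sum(Mod(w)^2))
  b <- sum(z * Conj(w))
  sqrt(max(0, 1 - Mod(b)^2))
}

# direct dense TPS solve: bending energy of mapping `ref` onto `ref + disp`
# via the full interpolation system, independent of bending_energy_matrix()
tps_energy_direct <- function(ref, disp) {
  p <- nrow(ref)
  d2 <- as.matrix(dist(ref))^2
  k <- ifelse(d2 > 0, d2 * log(d2), 0)
  q <- cbind(1, ref)
  l <- rbind(cbind(k, q), cbind(t(q), matrix(0, 3, 3)))
  energy <- 0
  for (dim in 1:2) {
    rhs <- c(ref[, dim] + disp[, dim], 0, 0, 0)
    coefs <- solve(l, rhs)
    w <- coefs[seq_len(p)]
    energy <- energy + drop(crossprod(w, k %*% w))
  }
  energy
}

# small simulated cohort in right-frame coordinates, for morphometric tests
sim_configs <- function(seed, n_control = 6, n_mfdm = 6) {
  co <- simulate_cohort(simulation_config(
    group_sizes = c(control = n_control, MFDM = n_mfdm), seed = seed))
  lapply(co$landmarks[!vapply(co$landmarks, is.null, TRUE)],
         function(l) reflect_to_reference_side(l)$points)
}

# one landmarked ear
one_ear <- function(seed = 1, side = "right") {
  co <- simulate_cohort(simulation_config(group_sizes = c(control = 4),
                                          seed = seed))
  ok <- which(!vapply(co$landmarks, is.null, TRUE) & co$side == side)
  co$landmarks[[ok[1]]]
}

round_hu <- earmorph::round_half_up
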