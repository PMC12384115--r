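# Independent oracles used by the tests. These deliberately re-derive
# quantities through different code paths than the package implementation.

# Literal, independent transcription of the extrapolated-boundary dipole
# reflectance (written out long-hand, no shared code with the package).
reference_reflectance <- function(mu_a, mu_s_prime, rho, A = 2.95) {
  mu_t <- mu_a + mu_s_prime
  D <- 1 / (3 * mu_t)
  mu_eff <- sqrt(mu_a / D)
  z0 <- 1 / mu_t
  zb <- 2 * A * D
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  term1 <- z0 * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / (r1 * r1)
  term2 <- (z0 + 2 * zb) * (mu_eff + 1 / r2) * exp(-mu_eff * r2) / (r2 * r2)
  (term1 + term2) / (4 * pi)
}

# Monte-Carlo photon random walk in a semi-infinite medium with an
# index-matched surface (compare against the formula with A = 1).
# Isotropic scattering at rate mu_s_prime (similarity relation), absorption
# handled by path-length weighting. Returns, per batch, the weight collected
# in an annulus around each target radius, normalised per unit area.
mc_reflectance_rings <- function(mu_a, mu_s_prime, rho_targets,
                                 n_photons = 1e5, ring_width = 3,
                                 n_batches = 10, seed = 1) {
  set.seed(seed)
  per_batch <- ceiling(n_photons / n_batches)
  l_max <- 15 / mu_a  # weight below exp(-15): negligible
  areas <- pi * ((rho_targets + ring_width / 2)^2 -
                   (rho_targets - ring_width / 2)^2)
  out <- matrix(0, n_batches, length(rho_targets))
  for (b in seq_len(n_batches)) {
    np <- per_batch
    x <- numeric(np); y <- numeric(np)
    z <- rexp(np, mu_s_prime)  # first interaction straight down
    L <- z
    alive <- rep(TRUE, np)
    wsum <- numeric(length(rho_targets))
    while (any(alive)) {
      n_a <- sum(alive)
      # isotropic direction
      cz <- runif(n_a, -1, 1)
      phi <- runif(n_a, 0, 2 * pi)
      st <- sqrt(1 - cz^2)
      s <- rexp(n_a, mu_s_prime)
      dx <- s * st * cos(phi); dy <- s * st * sin(phi); dz <- s * cz
      zi <- z[alive]
      znew <- zi + dz
      exits <- znew < 0
      if (any(exits)) {
        frac <- zi[exits] / (zi[exits] - znew[exits])
        ex <- x[alive][exits] + dx[exits] * frac
        ey <- y[alive][exits] + dy[exits] * frac
        el <- L[alive][exits] + s[exits] * frac
        r <- sqrt(ex^2 + ey^2)
        w <- exp(-mu_a * el)
        for (k in seq_along(rho_targets)) {
          in_ring <- abs(r - rho_targets[k]) < ring_width / 2
          wsum[k] <- wsum[k] + sum(w[in_ring])
        }
      }
      keep <- !exits
      idx <- which(alive)
      x[idx] <- x[idx] + dx; y[idx] <- y[idx] + dy; z[idx] <- znew
      L[idx] <- L[idx] + s
      alive[idx[!keep]] <- FALSE
      alive[idx[L[idx] > l_max]] <- FALSE
    }
    out[b, ] <- wsum / (areas * np)
  }
  out
}

# Exact one-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the shifted differences (zeros dropped, average ranks).
enum_signed_rank_p <- function(d, mu = 0, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  x <- d - mu
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(0.5)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  if (alternative == "greater") mean(w_all >= w_obs) else mean(w_all <= w_obs)
}

enum_wilcox_tost_p <- function(d, delta) {
  max(
    enum_signed_rank_p(d, mu = -delta, alternative = "greater"),
    enum_signed_rank_p(d, mu = delta, alternative = "less")
  )
}

# Kendall tau by brute-force pair enumeration (no ties expected).
enum_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  (conc - disc) / (n * (n - 1) / 2)
}

# Canonical single-trial generator parameters used across tests.
test_params <- function(...) {
  p <- tibble::tibble(
    baseline_hbt_uM = 60, baseline_sto2_pct = 70,
    bh_max_pct_change_hbt = 3.5, bh_max_pct_change_sto2 = 1.2,
    db_mean_pkpk_hbt = 1.6, db_mean_pkpk_sto2 = 0.3,
    db_mean_osc_time_hbt = 6.5, db_mean_osc_time_sto2 = 3.3,
    hbt_response_delay_s = 2
  )
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

# Noiseless truth -> recording -> reconstruction for one trial.
noiseless_trial <- function(params = test_params(), seed = 1) {
  truth <- generate_truth(params, noise = silent_noise_model(), seed = seed)
  rec <- truth_to_recording(truth, noise = silent_noise_model(), seed = seed + 1)
  trace <- reconstruct_trial(rec)
  list(truth = truth, recording = rec, trace = trace)
}

# correlated paired draws used by the equivalence power checks
draw_paired_arms <- function(n, mean_x, mean_y, sd_x, sd_y, correlation) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  list(
    x = mean_x + sd_x * z1,
    y = mean_y + sd_y * (correlation * z1 + sqrt(1 - correlation^2) * z2)
  )
}
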