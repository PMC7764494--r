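# in-code fixtures shared across test files

# trajectory with explicitly given per-frame z positions for one or more
# particles; zmat is frames x particles
traj_from_z <- function(zmat, species = "NA", times = NULL, box = NULL,
                        x = 0, y = 0, charge = NULL) {
  zmat <- as.matrix(zmat)
  nf <- nrow(zmat); np <- ncol(zmat)
  if (is.null(times)) times <- seq_len(nf) - 1
  species <- rep_len(species, np)
  d <- data.frame(
    time = rep(times, each = np),
    id = rep(seq_len(np), nf),
    species = rep(species, nf),
    charge = if (is.null(charge)) NA_real_ else rep(rep_len(charge, np), nf),
    x = rep_len(x, nf * np), y = rep_len(y, nf * np),
    z = as.vector(t(zmat))
  )
  ion_trajectory(d, box = box)
}

# static single-frame arrangement from explicit coordinates
frame_from_particles <- function(species, x, y, z, charge = NULL) {
  d <- data.frame(time = 0, id = seq_along(species), species = species,
                  charge = if (is.null(charge)) NA_real_ else charge,
                  x = x, y = y, z = z)
  ion_trajectory(d)
}

# brute-force MSD over all overlapping origins (independent oracle for the
# FFT-based path)
msd_direct <- function(q, lags) {
  n <- length(q)
  vapply(lags, function(k) mean((q[(1 + k):n] - q[1:(n - k)])^2), numeric(1))
}

# fabricate a charge_transport object from a dQ series (test plumbing)
transport_from_dq <- function(dQ, dt = 1, slab = slab_region(-4.5, 16.5)) {
  structure(list(series = data.frame(time = (0:length(dQ)) * dt,
                                     dQ = c(NA, dQ), Q = c(0, cumsum(dQ))),
                 slab = slab, membership = "both_frames"),
            class = "charge_transport")
}
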