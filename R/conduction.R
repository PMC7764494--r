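#' Per-interval transported charge through a slab
#'
#' The collective-diffusion bookkeeping: for each pair of consecutive frames
#' the transported charge is `dQ = sum_i e_i dz_i / Lz`, summed over the
#' ions inside the slab `[z1, z2]`. The cumulative series
#' `Q(t) = sum_{t_i < t} dQ(t_i)` behaves, at equilibrium, as an unbiased
#' random walk whose diffusion coefficient sets the channel conductance.
#'
#' Two slab-membership rules are offered. `"both_frames"` (default, the
#' literal reading of the slab condition) includes an ion only when its z is
#' inside the closed interval at both frames of the pair, and uses the full
#' displacement. `"clip"` credits every ion with the portion of its path
#' inside the slab: `dQ_i = e_i (clamp(z') - clamp(z)) / Lz` with positions
#' clamped to `[z1, z2]`, the fractional-transport variant. Both rules give
#' exactly `e_i` for an ion carried from `z1` to `z2`.
#'
#' When the trajectory carries a periodic box, per-interval displacements
#' are taken as minimum-image steps and slab membership is evaluated on the
#' in-box coordinates (the slab must lie inside the box and away from its
#' boundary). Without a box the z coordinates must already be continuous.
#'
#' @param traj an [ion_trajectory()] with >= 2 frames.
#' @param slab a [slab_region()].
#' @param membership `"both_frames"` or `"clip"`.
#' @return a `charge_transport` object: data frame `series` with `time`
#'   (ps; frame times), `dQ` (e; `NA` for the first frame) and cumulative
#'   `Q` (e; `Q[1] = 0`), plus the slab and the rule used.
#' @export
charge_increments <- function(traj, slab = slab_region(),
                              membership = c("both_frames", "clip")) {
  stopifnot(inherits(traj, "ion_trajectory"), inherits(slab, "slab_region"))
  membership <- match.arg(membership)
  if (traj$n_frames < 2L) stop("need at least 2 frames")
  z <- traj_coord_matrix(traj, "z")
  nf <- traj$n_frames
  e <- matrix(traj$charges, nf - 1L, traj$n_particles, byrow = TRUE)
  z0 <- z[-nf, , drop = FALSE]
  z1 <- z[-1, , drop = FALSE]
  dz <- z1 - z0
  if (!is.null(traj$box)) {
    Lbox <- traj$box[3]
    dz <- dz - Lbox * round(dz / Lbox)  # minimum-image step
  }
  if (membership == "both_frames") {
    inside <- z0 >= slab$z1 & z0 <= slab$z2 & z1 >= slab$z1 & z1 <= slab$z2
    contrib <- ifelse(inside, e * dz / slab$Lz, 0)
  } else {
    c0 <- pmin(pmax(z0, slab$z1), slab$z2)
    c1 <- pmin(pmax(z0 + dz, slab$z1), slab$z2)
    contrib <- e * (c1 - c0) / slab$Lz
  }
  dQ <- rowSums(contrib)
  if (all(dQ == 0)) {
    zr <- range(z)
    if (slab$z2 < zr[1] || slab$z1 > zr[2]) {
      warning("slab does not overlap the trajectory's z-range; ",
              "all increments are zero")
    }
  }
  structure(list(series = data.frame(time = traj$times,
                                     dQ = c(NA_real_, dQ),
                                     Q = c(0, cumsum(dQ))),
                 slab = slab, membership = membership),
            class = "charge_transport")
}

# exact O(n log n) MSD of a scalar series via FFT autocorrelation
.msd_fft <- function(q, lags) {
  n <- length(q)
  # autocorrelation sum S2(k) = sum_i q[i] q[i+k] by zero-padded FFT
  npad <- 2^ceiling(log2(2 * n))
  fq <- stats::fft(c(q, rep(0, npad - n)))
  ac <- Re(stats::fft(fq * Conj(fq), inverse = TRUE)) / npad
  ac <- ac[seq_len(n)]
  # S1 recursion: D[i] = q[i]^2; SS(k) = sum_{i=1}^{n-k}(D[i] + D[i+k])
  d2 <- q^2
  ss0 <- 2 * sum(d2)
  csum_head <- cumsum(d2)                 # sum of first k terms
  csum_tail <- cumsum(rev(d2))            # sum of last k terms
  vapply(lags, function(k) {
    ss <- ss0 - csum_head[k] - csum_tail[k]
    (ss - 2 * ac[k + 1]) / (n - k)
  }, numeric(1))
}

#' Mean-square displacement of the transported charge
#'
#' `MSD(tau)` is the average over all (overlapping) time origins of
#' `(Q(t0 + tau) - Q(t0))^2`, evaluated at every frame lag up to
#' `max_lag_fraction` of the series length. For a diffusive `Q(t)` the MSD
#' grows linearly, `MSD ~ 2 DQ tau + const`; the slope is fitted by
#' [fit_dq()]. Computed exactly via an FFT autocorrelation
#' (O(n log n)), identical to the direct double loop.
#'
#' @param transport a [charge_increments()] result.
#' @param max_lag_fraction largest lag as a fraction of the series length,
#'   in (0, 1] (default 0.1).
#' @return a `charge_msd`: data frame `msd` with `lag` (ps), `lag_frames`,
#'   `msd` (e^2), `n_origins`.
#' @export
charge_msd <- function(transport, max_lag_fraction = 0.1) {
  stopifnot(inherits(transport, "charge_transport"))
  if (!is.numeric(max_lag_fraction) || max_lag_fraction <= 0 ||
      max_lag_fraction > 1) {
    stop("max_lag_fraction must be in (0, 1]")
  }
  q <- transport$series$Q
  q <- q - mean(q)  # MSD is shift-invariant; centring improves conditioning
  n <- length(q)
  if (n - 1L < 10L) stop("need at least 10 intervals for an MSD")
  max_lag <- max(1L, floor((n - 1L) * max_lag_fraction))
  lags <- seq_len(max_lag)
  msd <- .msd_fft(q, lags)
  msd <- pmax(msd, 0)  # guard tiny negative round-off
  dt <- mean(diff(transport$series$time))
  structure(list(msd = data.frame(lag = lags * dt, lag_frames = lags,
                                  msd = msd, n_origins = n - lags),
                 dt = dt),
            class = "charge_msd")
}

#' Fit the charge diffusion coefficient DQ
#'
#' Ordinary least squares of `MSD(tau)` against `tau` over a window of
#' lags, by default the 10%-50% band of the available lags (short lags are
#' dominated by the intercept, long lags by origin-correlation noise).
#' `DQ` is half the slope; the intercept and r-squared are reported. A
#' negative fitted slope signals insufficient sampling and is an error,
#' never silently clamped.
#'
#' @param msd a [charge_msd()] result.
#' @param window length-2 fractions of the maximum lag, default
#'   `c(0.1, 0.5)`.
#' @return a `dq_fit`: `DQ` (e^2/ps), `intercept` (e^2), `r_squared`,
#'   `window` (ps), `n_points`.
#' @export
fit_dq <- function(msd, window = c(0.1, 0.5)) {
  stopifnot(inherits(msd, "charge_msd"))
  m <- msd$msd
  max_lag <- max(m$lag)
  sel <- m$lag >= window[1] * max_lag & m$lag <= window[2] * max_lag
  if (sum(sel) < 5L) stop("fewer than 5 lag points in the fit window")
  fit <- stats::lm(msd ~ lag, data = m[sel, ])
  slope <- unname(stats::coef(fit)["lag"])
  if (slope < 0) {
    stop("negative MSD slope: insufficient sampling to estimate DQ")
  }
  ss_tot <- sum((m$msd[sel] - mean(m$msd[sel]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NaN
  structure(list(DQ = slope / 2,
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = r2,
                 window = range(m$lag[sel]),
                 n_points = sum(sel)),
            class = "dq_fit")
}

#' @export
print.dq_fit <- function(x, ...) {
  cat(sprintf("dq_fit: DQ = %.4g e^2/ps (intercept %.4g e^2, r^2 = %.3f, %d lags)\n",
              x$DQ, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Linear-response current-voltage prediction
#'
#' Converts a charge diffusion coefficient into a conductance
#' `G = DQ e^2 / (kB T)` (pS) and evaluates the linear IV relation
#' `I = G V` at the requested voltages. Valid in the linear-response regime,
#' i.e. for voltages small enough that the equilibrium fluctuations govern
#' the response.
#'
#' @param DQ charge diffusion coefficient, e^2/ps.
#' @param T temperature, kelvin.
#' @param voltages voltages, mV.
#' @return an `iv_prediction`: `G` (pS), `T`, and data frame `points` with
#'   `V_mV` and `I_pA`.
#' @examples
#' predict_iv(conductance_to_dq(23.06, 300), 300, -20)  # I = -0.4612 pA
#' @export
predict_iv <- function(DQ, T = 300, voltages = seq(-40, 40, by = 10)) {
  G <- dq_to_conductance(DQ, T)
  structure(list(G = G, T = T,
                 points = data.frame(V_mV = voltages,
                                     I_pA = G * voltages * 1e-3)),
            class = "iv_prediction")
}

#' @export
print.iv_prediction <- function(x, ...) {
  cat(sprintf("iv_prediction: G = %.4g pS at %g K\n", x$G, x$T))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Equilibrium-trajectory conductance pipeline
#'
#' Composes [charge_increments()], [charge_msd()], [fit_dq()] and
#' [predict_iv()]. Deterministic given the trajectory and options; all
#' intermediates are returned.
#'
#' @param traj an [ion_trajectory()].
#' @param slab a [slab_region()].
#' @param T temperature, kelvin.
#' @param membership slab-membership rule, see [charge_increments()].
#' @param max_lag_fraction,window MSD and fit options.
#' @param voltages voltages for the IV table, mV.
#' @return list with `transport`, `msd`, `fit`, `iv` and scalar `G` (pS).
#' @export
conductance_pipeline <- function(traj, slab = slab_region(), T = 300,
                                 membership = "both_frames",
                                 max_lag_fraction = 0.1,
                                 window = c(0.1, 0.5),
                                 voltages = seq(-40, 40, by = 10)) {
  transport <- charge_increments(traj, slab, membership)
  msd <- charge_msd(transport, max_lag_fraction)
  fit <- fit_dq(msd, window)
  iv <- predict_iv(fit$DQ, T, voltages)
  list(transport = transport, msd = msd, fit = fit, iv = iv, G = iv$G)
}
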