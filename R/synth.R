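#' One-dimensional potentials for the Brownian-dynamics generator
#'
#' Constructors for the axial potentials U(z) (kcal/mol, z in angstrom) that
#' [simulate_ions()] samples. Each returns a `potential_spec` carrying the
#' energy `U(z)` and its derivative `dU(z)`.
#'
#' * `potential_flat()`: U = 0 everywhere.
#' * `potential_harmonic(k, z0)`: U = k/2 (z - z0)^2; `k` in
#'   kcal mol^-1 A^-2.
#' * `potential_double_well(barrier, half_sep, center)`: quartic
#'   U = barrier ((z - center)^2 / half_sep^2 - 1)^2 with minima at
#'   center +/- half_sep and a `barrier`-high maximum between them.
#' * `potential_piecewise_linear(knots)`: linear interpolation through
#'   `knots`, a data frame / matrix with columns `z` (strictly increasing)
#'   and `U`; constant extrapolation outside the knot range.
#'
#' @param k harmonic force constant, kcal mol^-1 A^-2.
#' @param z0,center location parameters, angstrom.
#' @param barrier barrier height, kcal/mol.
#' @param half_sep half-separation of the two minima, angstrom.
#' @param knots two-column (z, U) table, z strictly increasing.
#' @return a `potential_spec` object.
#' @name potentials
NULL

new_potential <- function(kind, U, dU, params = list()) {
  structure(list(kind = kind, U = U, dU = dU, params = params),
            class = "potential_spec")
}

#' @rdname potentials
#' @export
potential_flat <- function() {
  new_potential("flat", function(z) rep(0, length(z)),
                function(z) rep(0, length(z)))
}

#' @rdname potentials
#' @export
potential_harmonic <- function(k, z0 = 0) {
  stopifnot(is.numeric(k), k > 0, is.finite(z0))
  new_potential("harmonic",
                function(z) 0.5 * k * (z - z0)^2,
                function(z) k * (z - z0),
                list(k = k, z0 = z0))
}

#' @rdname potentials
#' @export
potential_double_well <- function(barrier, half_sep, center = 0) {
  stopifnot(barrier > 0, half_sep > 0)
  a2 <- half_sep^2
  new_potential("double_well",
                function(z) barrier * ((z - center)^2 / a2 - 1)^2,
                function(z) {
                  u <- (z - center)
                  4 * barrier * u * (u^2 / a2 - 1) / a2
                },
                list(barrier = barrier, half_sep = half_sep, center = center))
}

#' @rdname potentials
#' @export
potential_piecewise_linear <- function(knots) {
  knots <- as.data.frame(knots)
  if (!all(c("z", "U") %in% names(knots))) {
    names(knots)[1:2] <- c("z", "U")
  }
  if (nrow(knots) < 2L) stop("piecewise-linear potential needs >= 2 knots")
  if (any(diff(knots$z) <= 0)) stop("knot z values must be strictly increasing")
  if (any(!is.finite(knots$U))) stop("knot energies must be finite")
  zk <- knots$z; Uk <- knots$U
  slopes <- diff(Uk) / diff(zk)
  Ufun <- function(z) {
    stats::approx(zk, Uk, xout = z, rule = 2)$y
  }
  dUfun <- function(z) {
    i <- findInterval(z, zk, rightmost.closed = TRUE)
    s <- rep(0, length(z))
    inside <- i >= 1L & i <= length(slopes)
    s[inside] <- slopes[i[inside]]
    s[z < zk[1] | z > zk[length(zk)]] <- 0  # constant extrapolation
    s
  }
  new_potential("piecewise_linear", Ufun, dUfun, list(knots = knots))
}

#' Configuration of a multi-ion Brownian-dynamics run
#'
#' Overdamped Langevin dynamics along the pore axis: each ion moves by
#' Euler-Maruyama steps
#' `z <- z - (D / kB T) U'(z) dt + sqrt(2 D dt) eta` with `eta` standard
#' normal, plus an optional short-ranged pairwise repulsion (amplitude `A`
#' exp(-|zi - zj| / `range`)) so multi-ion bound configurations can be
#' staged. x and y are cosmetic jitter, uniform in a disc of
#' `lateral_extent`; all physics is axial.
#'
#' @param potential a `potential_spec` from [potentials].
#' @param D per-species diffusion coefficient, A^2/ps: a single number or a
#'   named vector by species.
#' @param T temperature, kelvin.
#' @param dt time step, ps.
#' @param n_steps number of integration steps (>= 1).
#' @param save_stride save every `save_stride`-th step (step 0 always saved).
#' @param seed integer RNG seed; mandatory for reproducibility.
#' @param domain length-2 z-interval (angstrom) with boundary handling
#'   `boundary` = `"reflecting"` or `"periodic"`.
#' @param ions named integer vector: species -> ion count, e.g.
#'   `c("NA" = 4)`.
#' @param boundary boundary condition on `domain`.
#' @param pair_repulsion optional `list(amplitude =, range =)`
#'   (kcal/mol, angstrom) screened-Coulomb-like axial repulsion.
#' @param lateral_extent radius of the x,y jitter disc, angstrom.
#' @param charges optional extra species->charge registry entries.
#' @return a `langevin_config` object.
#' @export
langevin_config <- function(potential, D, T = 300, dt = 0.01,
                            n_steps = 1000L, save_stride = 1L, seed,
                            domain = c(-20, 20),
                            ions = c("NA" = 1),
                            boundary = c("reflecting", "periodic"),
                            pair_repulsion = NULL,
                            lateral_extent = 0,
                            charges = NULL) {
  boundary <- match.arg(boundary)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(inherits(potential, "potential_spec"))
  if (any(!is.finite(D)) || any(D <= 0)) stop("D must be positive (A^2/ps)")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive (ps)")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (save_stride < 1) stop("save_stride must be >= 1")
  if (length(domain) != 2L || domain[1] >= domain[2]) {
    stop("domain must be an increasing z-interval")
  }
  if (is.null(names(ions)) || any(ions < 1)) {
    stop("ions must be a named vector of positive counts")
  }
  if (!is.null(pair_repulsion)) {
    stopifnot(is.list(pair_repulsion),
              all(c("amplitude", "range") %in% names(pair_repulsion)),
              pair_repulsion$range > 0)
  }
  structure(list(potential = potential, D = D, T = T, dt = dt,
                 n_steps = as.integer(n_steps),
                 save_stride = as.integer(save_stride),
                 seed = as.integer(seed), domain = domain, ions = ions,
                 boundary = boundary, pair_repulsion = pair_repulsion,
                 lateral_extent = lateral_extent, charges = charges),
            class = "langevin_config")
}

# reflect positions into [lo, hi] (repeatedly, for large excursions)
.reflect <- function(z, lo, hi) {
  L <- hi - lo
  out <- (z - lo) %% (2 * L)
  out <- ifelse(out > L, 2 * L - out, out)
  out + lo
}

#' Simulate ions by overdamped Langevin dynamics
#'
#' Runs the Brownian-dynamics integrator described in [langevin_config()]
#' and returns the saved frames as an [ion_trajectory()]. Bitwise
#' reproducible for a fixed seed; extending `n_steps` leaves the already
#' saved prefix unchanged. The configured seed is recorded in the trajectory
#' comments.
#'
#' Errors with a stability diagnosis when the deterministic drift per step
#' exceeds a tenth of the domain anywhere on it (dt too large for the
#' potential).
#'
#' @param config a [langevin_config()].
#' @return an [ion_trajectory()]. For `boundary = "periodic"` the trajectory
#'   carries a box whose z-length is the domain length, so
#'   [unwrap_axial()] applies.
#' @export
simulate_ions <- function(config) {
  stopifnot(inherits(config, "langevin_config"))
  pot <- config$potential
  kT <- thermal_energy(config$T)
  lo <- config$domain[1]; hi <- config$domain[2]
  Ldom <- hi - lo

  species <- rep(names(config$ions), times = config$ions)
  n_ions <- length(species)
  Dvec <- if (length(config$D) == 1L && is.null(names(config$D))) {
    rep(as.numeric(config$D), n_ions)
  } else {
    if (!all(species %in% names(config$D))) {
      stop("D must name every simulated species")
    }
    as.numeric(config$D[species])
  }

  # stability: max deterministic drift per step < domain/10
  zgrid <- seq(lo, hi, length.out = 2001L)
  max_drift <- max(abs(pot$dU(zgrid))) * max(Dvec) / kT * config$dt
  if (max_drift > Ldom / 10) {
    stop(sprintf(paste0("unstable integration: max drift per step %.3g A ",
                        "exceeds domain/10 = %.3g A; reduce dt"),
                 max_drift, Ldom / 10))
  }

  rep_on <- !is.null(config$pair_repulsion) && n_ions > 1L
  if (rep_on) {
    A <- config$pair_repulsion$amplitude
    lam <- config$pair_repulsion$range
  }

  set.seed(config$seed)
  z <- stats::runif(n_ions, lo, hi)
  n_saved <- config$n_steps %/% config$save_stride + 1L
  Z <- matrix(NA_real_, n_saved, n_ions)
  X <- matrix(0, n_saved, n_ions)
  Y <- matrix(0, n_saved, n_ions)
  jitter_xy <- function() {
    if (config$lateral_extent <= 0) return(cbind(rep(0, n_ions), 0))
    r <- config$lateral_extent * sqrt(stats::runif(n_ions))
    th <- stats::runif(n_ions, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  }
  Z[1, ] <- z
  xy <- jitter_xy(); X[1, ] <- xy[, 1]; Y[1, ] <- xy[, 2]

  sig <- sqrt(2 * Dvec * config$dt)
  mob_dt <- Dvec / kT * config$dt
  k_save <- 1L
  for (step in seq_len(config$n_steps)) {
    force <- -pot$dU(z)
    if (rep_on) {
      dzm <- outer(z, z, "-")                   # zi - zj
      f_pair <- (A / lam) * sign(dzm) * exp(-abs(dzm) / lam)
      diag(f_pair) <- 0
      force <- force + rowSums(f_pair)
    }
    z <- z + mob_dt * force + sig * stats::rnorm(n_ions)
    if (config$boundary == "reflecting") {
      z <- .reflect(z, lo, hi)
    } else {
      z <- lo + (z - lo) %% Ldom
    }
    if (step %% config$save_stride == 0L) {
      k_save <- k_save + 1L
      Z[k_save, ] <- z
      xy <- jitter_xy(); X[k_save, ] <- xy[, 1]; Y[k_save, ] <- xy[, 2]
    }
  }

  times <- (0:(n_saved - 1L)) * config$save_stride * config$dt
  d <- data.frame(
    time = rep(times, each = n_ions),
    id = rep(seq_len(n_ions), times = n_saved),
    species = rep(species, times = n_saved),
    charge = NA_real_,
    x = as.vector(t(X)), y = as.vector(t(Y)), z = as.vector(t(Z)),
    stringsAsFactors = FALSE
  )
  box <- if (config$boundary == "periodic") {
    c(2 * max(config$lateral_extent, 1), 2 * max(config$lateral_extent, 1),
      Ldom)
  } else NULL
  ion_trajectory(d, box = box, charges = config$charges,
                 comment = c(
                   sprintf("ionperm simulate seed=%d", config$seed),
                   sprintf("potential=%s dt=%g D=%s T=%g boundary=%s",
                           pot$kind, config$dt,
                           paste(format(config$D), collapse = ","),
                           config$T, config$boundary)))
}

#' Build a labeled coordination-shell frame
#'
#' Places a central ion at (0, 0, `z`) and each shell partner at exactly its
#' stated distance from the ion, in a seeded random direction. Partners
#' closer than 0.5 angstrom to an already placed partner are re-drawn; after
#' 200 failed attempts placement errors out.
#'
#' @param ion_species species label of the central ion (e.g. `"NA"`, `"CA"`).
#' @param shells data frame with columns `species`, `count`, `distance`
#'   (angstrom): one row per shell. May have zero rows (ion only).
#' @param z axial position of the ion, angstrom.
#' @param seed integer RNG seed.
#' @param time frame time stamp, ps.
#' @param charges optional extra species->charge entries.
#' @return a one-frame [ion_trajectory()]; the ion has id 1.
#' @export
make_coordination_fixture <- function(ion_species, shells = NULL, z = 0,
                                      seed = 1, time = 0, charges = NULL) {
  if (is.null(shells)) {
    shells <- data.frame(species = character(), count = integer(),
                         distance = numeric())
  }
  shells <- as.data.frame(shells)
  stopifnot(all(c("species", "count", "distance") %in% names(shells)))
  if (any(shells$distance <= 0)) stop("shell distances must be positive")
  if (any(shells$count < 0)) stop("shell counts must be non-negative")

  set.seed(seed)
  pos <- matrix(c(0, 0, z), nrow = 1)
  sp <- ion_species
  for (i in seq_len(nrow(shells))) {
    for (j in seq_len(shells$count[i])) {
      ok <- FALSE
      for (attempt in seq_len(200L)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        p <- c(0, 0, z) + shells$distance[i] * u
        others <- pos[-1, , drop = FALSE]
        if (nrow(others) == 0L ||
            min(sqrt(rowSums(sweep(others, 2, p)^2))) >= 0.5) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        stop("could not place shell partner without overlap (< 0.5 A) after ",
             "200 attempts")
      }
      pos <- rbind(pos, p)
      sp <- c(sp, shells$species[i])
    }
  }
  d <- data.frame(time = time, id = seq_len(nrow(pos)), species = sp,
                  charge = NA_real_,
                  x = pos[, 1], y = pos[, 2], z = pos[, 3],
                  stringsAsFactors = FALSE)
  ion_trajectory(d, charges = charges,
                 comment = sprintf("coordination fixture seed=%d", seed))
}
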