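#' Axial ion density profile
#'
#' Time-averaged number density of one ion species in uniform z-bins,
#' restricted to a cylinder of radius `radial_cutoff` around the pore axis
#' (x = y = 0). For each frame, ions of the species with lateral distance
#' `sqrt(x^2 + y^2) <= radial_cutoff` are histogrammed by z; the per-bin
#' density is the mean count divided by the bin volume
#' `pi radial_cutoff^2 bin_width` (A^-3).
#'
#' @param traj an [ion_trajectory()].
#' @param species species label to count (e.g. `"NA"`, `"CA"`).
#' @param bin_width bin thickness, angstrom (default 0.5).
#' @param radial_cutoff cylinder radius, angstrom (default 8).
#' @param z_range length-2 interval covered by the bins; defaults to the
#'   species' z-extent, expanded to a whole number of bins aligned at z = 0.
#' @return a `density_profile` object: data frame `profile` with
#'   `bin_center`, `count` (mean ions per frame), `rho` (A^-3), `visited`
#'   plus fields `bin_edges`, `species`, `radial_cutoff`, `n_frames`.
#' @export
axial_density <- function(traj, species, bin_width = 0.5, radial_cutoff = 8,
                          z_range = NULL) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (bin_width <= 0) stop("bin_width must be positive")
  if (radial_cutoff <= 0) stop("radial_cutoff must be positive")
  d <- traj$data
  sel <- d$species == species
  if (!any(sel)) {
    warning("no particles of species '", species, "' in trajectory; ",
            "returning an all-zero profile")
  }
  if (is.null(z_range)) {
    zr <- if (any(sel)) range(d$z[sel]) else c(0, bin_width)
    z_range <- c(floor(zr[1] / bin_width), ceiling(zr[2] / bin_width) +
                   (zr[2] %% bin_width == 0)) * bin_width
  }
  if (z_range[1] >= z_range[2]) stop("z_range must be increasing")
  edges <- seq(z_range[1], z_range[2], by = bin_width)
  if (edges[length(edges)] < z_range[2]) {
    edges <- c(edges, edges[length(edges)] + bin_width)
  }
  n_bins <- length(edges) - 1L

  keep <- sel & sqrt(d$x^2 + d$y^2) <= radial_cutoff &
    d$z >= edges[1] & d$z < edges[length(edges)]
  idx <- findInterval(d$z[keep], edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  mean_count <- counts / traj$n_frames
  vol <- pi * radial_cutoff^2 * bin_width
  structure(list(
    profile = data.frame(
      bin_center = (edges[-1] + edges[-length(edges)]) / 2,
      count = mean_count,
      rho = mean_count / vol,
      visited = counts > 0
    ),
    bin_edges = edges, species = species, bin_width = bin_width,
    radial_cutoff = radial_cutoff, n_frames = traj$n_frames
  ), class = "density_profile")
}

#' Bulk reference density
#'
#' Time-averaged number density of a species in one or more bulk z-slabs,
#' using the full box cross-section: `rho_b` = mean ion count in the region
#' divided by `box_x box_y` times the summed slab thickness.
#'
#' @param traj an [ion_trajectory()].
#' @param species species label.
#' @param bulk_region a length-2 interval or a list of such intervals
#'   (angstrom), disjoint from the channel region.
#' @param box length-3 box vector; defaults to the trajectory's box.
#' @return a `bulk_reference` with `rho_b` (A^-3), the region and the count.
#' @export
bulk_density <- function(traj, species, bulk_region, box = traj$box) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (is.null(box)) stop("bulk_density needs box dimensions")
  if (!is.list(bulk_region)) bulk_region <- list(bulk_region)
  thick <- vapply(bulk_region, function(r) r[2] - r[1], numeric(1))
  if (any(thick <= 0)) stop("bulk region of non-positive thickness")
  d <- traj$data
  sel <- d$species == species
  inside <- rep(FALSE, nrow(d))
  for (r in bulk_region) inside <- inside | (d$z >= r[1] & d$z <= r[2])
  n_in <- sum(sel & inside)
  if (n_in == 0L) {
    stop("no '", species, "' ion ever visits the bulk region; ",
         "no density reference available")
  }
  vol <- box[1] * box[2] * sum(thick)
  structure(list(rho_b = n_in / traj$n_frames / vol,
                 bulk_region = bulk_region, species = species,
                 mean_count = n_in / traj$n_frames, volume = vol),
            class = "bulk_reference")
}

#' Potential of mean force by Boltzmann inversion of the axial density
#'
#' Computes `F(z) = -kB T ln(rho(z) / rho_b)` per bin (natural logarithm;
#' kcal/mol). Bins never visited by the ions (`rho = 0`) are assigned
#' `F = 0` exactly, so the logarithm never diverges; the `visited` flag kept
#' alongside distinguishes these convention-zero bins from genuinely
#' zero-free-energy bins.
#'
#' @param profile a [axial_density()] result.
#' @param bulk a [bulk_density()] result, or a single positive number taken
#'   as `rho_b` (A^-3).
#' @param T temperature, kelvin.
#' @return a `pmf_profile`: data frame `profile` with `bin_center`,
#'   `F` (kcal/mol), `visited`, plus `T` and `rho_b`.
#' @export
pmf_from_density <- function(profile, bulk, T = 300) {
  stopifnot(inherits(profile, "density_profile"))
  rho_b <- if (inherits(bulk, "bulk_reference")) bulk$rho_b else as.numeric(bulk)
  if (!is.finite(rho_b) || rho_b <= 0) stop("rho_b must be positive")
  kT <- thermal_energy(T)  # validates T
  F <- ifelse(profile$profile$rho > 0,
              -kT * log(profile$profile$rho / rho_b), 0)
  structure(list(
    profile = data.frame(bin_center = profile$profile$bin_center, F = F,
                         visited = profile$profile$visited),
    T = T, rho_b = rho_b, species = profile$species,
    bin_width = profile$bin_width
  ), class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  v <- x$profile$visited
  cat(sprintf("pmf_profile (%s): %d bins (%d visited), T = %g K\n",
              x$species, nrow(x$profile), sum(v), x$T))
  if (any(v)) {
    i <- which.min(ifelse(v, x$profile$F, Inf))
    cat(sprintf("  min F = %.3f kcal/mol at z = %g A\n",
                x$profile$F[i], x$profile$bin_center[i]))
  }
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  p <- x$profile[x$profile$visited, ]
  graphics::plot(p$bin_center, p$F, type = "l",
                 xlab = "z (Å)", ylab = "F (kcal/mol)", ...)
  invisible(x)
}

#' Depth of a free-energy well
#'
#' Locates the minimum of the PMF over visited bins within a z-interval and
#' reports its depth as a positive number, both in kcal/mol and in units of
#' kB T at the profile's temperature.
#'
#' @param pmf a [pmf_from_density()] result.
#' @param region length-2 z-interval to search, angstrom; defaults to the
#'   full profile.
#' @return list with `depth_kcal`, `depth_kBT`, `z_min`.
#' @export
well_depth <- function(pmf, region = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"))
  p <- pmf$profile
  if (is.null(region)) region <- range(p$bin_center)
  in_reg <- p$visited & p$bin_center >= region[1] & p$bin_center <= region[2]
  if (!any(in_reg)) stop("no visited bins in the requested region")
  i <- which(in_reg)[which.min(p$F[in_reg])]
  depth <- -min(p$F[in_reg])
  list(depth_kcal = depth,
       depth_kBT = depth / thermal_energy(pmf$T),
       z_min = p$bin_center[i])
}
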