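#' Distance cutoffs for coordination counting
#'
#' Cutoff scheme for identifying coordination partners of an ion: one
#' cutoff for ion-oxygen contacts (water, acidic side-chain and other
#' protein oxygens alike) and one for ion-chloride contacts. The field's
#' working values are 3.2 angstrom for sodium-oxygen and 3.5 angstrom for
#' calcium-oxygen and for any ion-chloride contact; `cutoff_scheme_for()`
#' returns those per-species defaults.
#'
#' @param oxygen ion-oxygen cutoff, angstrom.
#' @param chloride ion-chloride cutoff, angstrom.
#' @return a `cutoff_scheme` object.
#' @export
cutoff_scheme <- function(oxygen, chloride = 3.5) {
  if (oxygen <= 0 || chloride <= 0) stop("cutoffs must be positive")
  structure(list(oxygen = oxygen, chloride = chloride),
            class = "cutoff_scheme")
}

#' @rdname cutoff_scheme
#' @param species ion species label (`"NA"` or `"CA"`).
#' @export
cutoff_scheme_for <- function(species) {
  switch(species,
    "NA" = cutoff_scheme(oxygen = 3.2, chloride = 3.5),
    "CA" = cutoff_scheme(oxygen = 3.5, chloride = 3.5),
    stop("no default cutoff scheme for species '", species,
         "'; build one with cutoff_scheme()")
  )
}

#' Per-frame occupancy of a slab region
#'
#' Counts, in every frame, the ions of a target species whose z lies in the
#' closed interval `[z1, z2]` of a [slab_region()].
#'
#' @param traj an [ion_trajectory()].
#' @param species species label to count.
#' @param region a [slab_region()].
#' @return an `occupancy_trace`: data frame with `time` (ps) and integer
#'   `count`.
#' @export
occupancy_trace <- function(traj, species, region = slab_region()) {
  stopifnot(inherits(traj, "ion_trajectory"), inherits(region, "slab_region"))
  d <- traj$data
  inside <- d$species == species & d$z >= region$z1 & d$z <= region$z2
  fidx <- match(d$time, traj$times)
  counts <- tabulate(fidx[inside], nbins = traj$n_frames)
  structure(list(trace = data.frame(time = traj$times,
                                    count = as.integer(counts)),
                 species = species, region = region),
            class = "occupancy_trace")
}

#' Summary statistics of an occupancy trace
#'
#' @param trace an [occupancy_trace()].
#' @return list with `mean`, `histogram` (named vector of frame counts per
#'   occupancy value, summing to the number of frames) and `dwell` (data
#'   frame of the longest uninterrupted run per occupancy value, in frames
#'   and ps; the ps duration uses the mean frame interval).
#' @export
occupancy_stats <- function(trace) {
  stopifnot(inherits(trace, "occupancy_trace"))
  cnt <- trace$trace$count
  if (length(cnt) == 0L) stop("empty occupancy trace")
  r <- rle(cnt)
  vals <- sort(unique(cnt))
  longest <- vapply(vals, function(v) max(r$lengths[r$values == v]),
                    integer(1))
  dt <- if (length(trace$trace$time) > 1L) mean(diff(trace$trace$time)) else 0
  h <- table(factor(cnt, levels = vals))
  list(mean = mean(cnt),
       histogram = stats::setNames(as.integer(h), vals),
       dwell = data.frame(count = vals, frames = longest,
                          ps = longest * dt))
}

# category map from species label to coordination-partner class
.partner_category <- c(OW = "water_O", OD = "acidic_O", OP = "other_protein_O",
                       CL = "chloride")

#' Axially binned coordination-number profile
#'
#' For every frame and every ion of the target species, counts coordination
#' partners within the cutoff distances (minimum-image distances when the
#' trajectory has a box), classified by the partner's species label:
#' `OW` water oxygens, `OD` acidic side-chain oxygens, `OP` other protein
#' oxygens (the three summing to `total_O`), and `CL` chlorides. Each sample
#' is assigned to the axial bin containing the ion's z; per-bin means are
#' taken over the samples that landed in the bin, and bins with zero samples
#' are flagged and carry `NA` means. Distance comparison is `<= cutoff`.
#'
#' Other ionic species (registered charged species such as `NA` or `CA`)
#' are ignored as partners; any other label is an error.
#'
#' @param traj an [ion_trajectory()].
#' @param species central-ion species label.
#' @param cutoffs a [cutoff_scheme()]; defaults to
#'   [cutoff_scheme_for()]`(species)`.
#' @param bin_width axial bin thickness, angstrom (default 2.0).
#' @param z_range length-2 interval for binning; defaults to the ions'
#'   z-extent expanded to whole bins aligned at z = 0.
#' @return a `coordination_profile`: data frame `profile` with `bin_center`,
#'   `n_samples`, mean `water_O`, `acidic_O`, `other_protein_O`, `total_O`,
#'   `chloride`, and `visited`.
#' @export
coordination_profile <- function(traj, species, cutoffs = NULL,
                                 bin_width = 2.0, z_range = NULL) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (is.null(cutoffs)) cutoffs <- cutoff_scheme_for(species)
  stopifnot(inherits(cutoffs, "cutoff_scheme"))
  d <- traj$data
  is_ion <- d$species == species

  partner_sp <- unique(d$species[!is_ion])
  unknown <- setdiff(partner_sp, c(names(.partner_category), "NA", "CA"))
  if (length(unknown) > 0) {
    stop("unknown coordination-partner species label(s): ",
         paste(unknown, collapse = ", "))
  }

  if (is.null(z_range)) {
    zr <- range(d$z[is_ion])
    z_range <- c(floor(zr[1] / bin_width) * bin_width,
                 ceiling(zr[2] / bin_width) * bin_width)
    if (z_range[2] <= z_range[1]) z_range[2] <- z_range[1] + bin_width
  }
  edges <- seq(z_range[1], z_range[2], by = bin_width)
  if (edges[length(edges)] < z_range[2]) {
    edges <- c(edges, edges[length(edges)] + bin_width)
  }
  n_bins <- length(edges) - 1L
  cats <- c("water_O", "acidic_O", "other_protein_O", "chloride")
  sums <- matrix(0, n_bins, length(cats), dimnames = list(NULL, cats))
  n_samples <- integer(n_bins)

  box <- traj$box
  mi <- function(delta, L) if (is.null(box)) delta else delta - L * round(delta / L)

  frames_idx <- match(d$time, traj$times)
  for (f in seq_len(traj$n_frames)) {
    fr <- d[frames_idx == f, , drop = FALSE]
    ions <- fr[fr$species == species, , drop = FALSE]
    if (nrow(ions) == 0L) next
    partners <- fr[fr$species %in% names(.partner_category), , drop = FALSE]
    for (i in seq_len(nrow(ions))) {
      zi <- ions$z[i]
      if (zi < edges[1] || zi >= edges[n_bins + 1L]) next
      b <- findInterval(zi, edges, rightmost.closed = TRUE)
      n_samples[b] <- n_samples[b] + 1L
      if (nrow(partners) > 0L) {
        dx <- partners$x - ions$x[i]
        dy <- partners$y - ions$y[i]
        dz <- partners$z - zi
        if (!is.null(box)) {
          dx <- mi(dx, box[1]); dy <- mi(dy, box[2]); dz <- mi(dz, box[3])
        }
        dist <- sqrt(dx^2 + dy^2 + dz^2)
        cut <- ifelse(partners$species == "CL", cutoffs$chloride,
                      cutoffs$oxygen)
        hit <- partners$species[dist <= cut]
        if (length(hit) > 0L) {
          tb <- table(.partner_category[hit])
          sums[b, names(tb)] <- sums[b, names(tb)] + as.integer(tb)
        }
      }
    }
  }

  means <- sums / ifelse(n_samples > 0, n_samples, NA_real_)
  prof <- data.frame(
    bin_center = (edges[-1] + edges[-length(edges)]) / 2,
    n_samples = n_samples,
    water_O = means[, "water_O"],
    acidic_O = means[, "acidic_O"],
    other_protein_O = means[, "other_protein_O"],
    chloride = means[, "chloride"]
  )
  prof$total_O <- prof$water_O + prof$acidic_O + prof$other_protein_O
  prof$visited <- n_samples > 0
  structure(list(profile = prof, species = species, cutoffs = cutoffs,
                 bin_edges = edges, bin_width = bin_width),
            class = "coordination_profile")
}

#' @export
plot.coordination_profile <- function(x, ...) {
  p <- x$profile[x$profile$visited, ]
  graphics::matplot(p$bin_center,
                    p[, c("water_O", "acidic_O", "other_protein_O",
                          "total_O", "chloride")],
                    type = "l", lty = 1,
                    col = c("blue", "green3", "red", "black", "magenta"),
                    xlab = "z (Å)", ylab = "mean coordination number", ...)
  graphics::legend("topright",
                   legend = c("water O", "acidic O", "other protein O",
                              "total O", "chloride"),
                   col = c("blue", "green3", "red", "black", "magenta"),
                   lty = 1, bty = "n")
  invisible(x)
}
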