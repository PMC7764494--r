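#' Construct an ion trajectory
#'
#' An `ion_trajectory` holds time-ordered frames of labeled charged particles.
#' Internally it is a long data frame with columns `time` (ps), `id`
#' (integer particle label), `species` (character), `charge` (e) and
#' `x`, `y`, `z` (angstrom), sorted by time and, within a frame, by id.
#' The particle roster (set of ids, with their species and charges) must be
#' identical in every frame, and frame times must be strictly increasing.
#'
#' @param data data frame with columns `time`, `id`, `species`, `charge`,
#'   `x`, `y`, `z`. A missing or `NA` charge is filled from the species
#'   registry; a species absent from the registry with no explicit charge is
#'   an error (never a silent zero).
#' @param box optional numeric length-3 vector of orthorhombic periodic box
#'   lengths (angstrom), or `NULL` for no periodicity.
#' @param charges optional extra species->charge entries passed to
#'   [species_charges()].
#' @param comment optional character vector of comment lines (stored, and
#'   written as '#' lines by [write_trajectory()]).
#' @return an object of class `ion_trajectory`.
#' @export
ion_trajectory <- function(data, box = NULL, charges = NULL, comment = NULL) {
  required <- c("time", "id", "species", "x", "y", "z")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("trajectory data is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$species <- as.character(data$species)
  if (nrow(data) == 0L) stop("trajectory must contain at least one frame")

  reg <- species_charges(charges)
  if (!"charge" %in% names(data)) data$charge <- NA_real_
  need <- is.na(data$charge)
  if (any(need)) {
    known <- data$species[need] %in% names(reg)
    if (any(!known)) {
      stop("no charge given and species not in registry: ",
           paste(unique(data$species[need][!known]), collapse = ", "))
    }
    data$charge[need] <- reg[data$species[need]]
  }
  if (any(!is.finite(data$charge))) stop("all particle charges must be finite")

  data <- data[order(data$time, data$id), , drop = FALSE]
  rownames(data) <- NULL
  times <- unique(data$time)
  if (any(diff(order(match(data$time, times))) < 0)) {
    stop("internal ordering failure")  # defensive; order() above prevents this
  }
  n_frames <- length(times)

  # roster consistency: identical id/species/charge in every frame
  n_per_frame <- tabulate(match(data$time, times))
  if (length(unique(n_per_frame)) != 1L) {
    stop("particle roster differs between frames (unequal particle counts)")
  }
  n_part <- n_per_frame[1]
  ids0 <- data$id[seq_len(n_part)]
  if (anyDuplicated(ids0)) stop("particle ids must be unique within a frame")
  idmat <- matrix(data$id, nrow = n_part)
  if (any(idmat != ids0)) {
    stop("particle roster differs between frames (mismatched ids)")
  }
  spec0 <- data$species[seq_len(n_part)]
  if (any(matrix(data$species, nrow = n_part) != spec0)) {
    stop("particle species labels differ between frames for the same id")
  }
  chg0 <- data$charge[seq_len(n_part)]
  if (any(matrix(data$charge, nrow = n_part) != chg0)) {
    stop("particle charges differ between frames for the same id")
  }

  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be a length-3 vector of positive lengths (angstrom)")
    }
  }
  structure(
    list(data = data, times = times, box = box,
         ids = ids0, species = spec0, charges = chg0,
         n_frames = n_frames, n_particles = n_part,
         comment = comment),
    class = "ion_trajectory"
  )
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf("ion_trajectory: %d frames x %d particles, t = %g..%g ps\n",
              x$n_frames, x$n_particles, x$times[1], x$times[x$n_frames]))
  tab <- table(x$species)
  cat("  species:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
      "\n")
  if (!is.null(x$box)) {
    cat(sprintf("  box: %g x %g x %g A\n", x$box[1], x$box[2], x$box[3]))
  }
  invisible(x)
}

# frames x particles matrix of one coordinate (columns follow x$ids order)
traj_coord_matrix <- function(traj, coord = "z") {
  matrix(traj$data[[coord]], nrow = traj$n_frames,
         ncol = traj$n_particles, byrow = TRUE)
}

#' Read a columnar plain-text trajectory
#'
#' The canonical interchange format is UTF-8 text with '#'-prefixed comment
#' lines, a header row `time id species charge x y z`, whitespace-delimited
#' values, one row per particle per frame, frames contiguous and time-sorted.
#' A box, when present, is recorded in a comment line
#' `# box <Lx> <Ly> <Lz>`.
#'
#' @param path file path.
#' @param charges optional extra species->charge entries.
#' @return an [ion_trajectory()].
#' @export
read_trajectory <- function(path, charges = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(trimws(lines), "#")
  comments <- sub("^\\s*#\\s?", "", lines[is_comment])

  box <- NULL
  box_line <- grep("^box\\s", comments, value = TRUE)
  if (length(box_line) >= 1L) {
    box <- as.numeric(strsplit(trimws(box_line[1]), "\\s+")[[1]][-1])
  }

  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("trajectory file has no data rows: ", path)
  header <- strsplit(trimws(body[1]), "\\s+")[[1]]
  required <- c("time", "id", "species", "charge", "x", "y", "z")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    stop("trajectory header is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  fields <- strsplit(trimws(body[-1]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    stop("malformed data row (expected ", length(header), " fields) at line ",
         which(nf != length(header))[1])
  }
  m <- do.call(rbind, fields)
  colnames(m) <- header
  d <- data.frame(
    time = as.numeric(m[, "time"]),
    id = as.integer(m[, "id"]),
    species = as.character(m[, "species"]),
    charge = suppressWarnings(as.numeric(m[, "charge"])),
    x = as.numeric(m[, "x"]), y = as.numeric(m[, "y"]),
    z = as.numeric(m[, "z"]),
    stringsAsFactors = FALSE
  )
  # "NA" in the charge column means: fall back to species registry
  if (any(!is.finite(d$time))) stop("non-numeric time value in ", path)

  # frames delimited by change in time value; times must strictly increase
  rle_t <- rle(d$time)$values
  if (any(diff(rle_t) <= 0)) {
    bad <- which(diff(rle_t) <= 0)[1] + 1L
    stop("frame times not strictly increasing at frame index ", bad,
         " (time ", rle_t[bad], ")")
  }
  ion_trajectory(d, box = box, charges = charges,
                 comment = if (length(comments)) comments else NULL)
}

#' Write a trajectory to the columnar plain-text format
#'
#' Values are written with 12 significant digits so a read/write round trip
#' reproduces the trajectory to numerical identity for desk-scale data.
#'
#' @param traj an [ion_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ion_trajectory"))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  if (!is.null(traj$comment)) {
    writeLines(paste("#", traj$comment), con)
  }
  if (!is.null(traj$box)) {
    writeLines(sprintf("# box %.12g %.12g %.12g",
                       traj$box[1], traj$box[2], traj$box[3]), con)
  }
  writeLines("time id species charge x y z", con)
  d <- traj$data
  writeLines(sprintf("%.12g %d %s %.12g %.12g %.12g %.12g",
                     d$time, d$id, d$species, d$charge, d$x, d$y, d$z), con)
  invisible(path)
}

#' Unwrap axial (z) coordinates across periodic boundaries
#'
#' Rebuilds each particle's z coordinate as a continuous series: the step
#' between consecutive frames is taken as the minimum-image displacement
#' (true per-step displacements are assumed smaller than half the box
#' z-length), accumulated from the particle's initial position. x and y are
#' left untouched; they matter only for within-frame distances.
#' Idempotent on trajectories that never cross the boundary.
#'
#' @param traj an [ion_trajectory()] with a box.
#' @return an [ion_trajectory()] with continuous z.
#' @export
unwrap_axial <- function(traj) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (is.null(traj$box)) {
    stop("unwrap_axial requires a periodic box (box z-length)")
  }
  Lz <- traj$box[3]
  z <- traj_coord_matrix(traj, "z")
  nf <- traj$n_frames
  if (nf > 1L) {
    dz <- z[-1, , drop = FALSE] - z[-nf, , drop = FALSE]
    dz <- dz - Lz * round(dz / Lz)  # minimum image per step
    cs <- matrix(0, nf, traj$n_particles)
    cs[-1, ] <- apply(dz, 2, cumsum)
    z <- matrix(z[1, ], nf, traj$n_particles, byrow = TRUE) + cs
  }
  out <- traj
  out$data$z <- as.vector(t(z))
  out
}
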