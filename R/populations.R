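#' Monomer species for tetramer assembly
#'
#' A channel monomer identified by the amino-acid motif of its
#' selectivity-filter (SF) ring position and the formal charge (e) that one
#' copy contributes to the ring. The built-in registry carries the NaChBac
#' variants LASWAS (0), LESWAS (-1e, wild type) and LEDWAS (-2e); any other
#' species can be constructed with an explicit charge.
#'
#' @param name monomer name.
#' @param charge per-monomer SF charge, elementary charges; looked up in
#'   the registry when omitted.
#' @return a `monomer_species` object with `name` and `charge`.
#' @export
monomer_species <- function(name, charge = NULL) {
  registry <- c(LASWAS = 0, LESWAS = -1, LEDWAS = -2, LEDWSM = -2)
  if (is.null(charge)) {
    if (!name %in% names(registry)) {
      stop("unknown monomer '", name, "'; give an explicit per-monomer charge")
    }
    charge <- registry[[name]]
  }
  if (!is.finite(charge)) stop("monomer charge must be finite")
  structure(list(name = name, charge = charge), class = "monomer_species")
}

as_monomer <- function(x) {
  if (inherits(x, "monomer_species")) x else monomer_species(x)
}

#' Binomial distribution of tetramer compositions and SF charges
#'
#' Under unbiased random assembly from a binary monomer mixture, the number
#' `n` of B-monomers in an N-mer is binomial:
#' `P(n) = C(N, n) p^n (1 - p)^(N - n)`, with `p` the fraction of species B
#' in the available monomer pool (cDNA mass ratios map directly to `p`).
#' The total SF fixed charge of a composition is
#' `Qf(n) = (N - n) qA + n qB`; compositions with equal `Qf` are aggregated
#' into the charge distribution.
#'
#' @param speciesA,speciesB [monomer_species()] objects or registry names.
#' @param p fraction of `speciesB` in the monomer pool, in `[0, 1]`.
#' @param N monomers per channel (default 4, a tetramer).
#' @return a `tetramer_distribution` with data frames `composition`
#'   (`n_B`, `prob`, `Qf`) and `charge` (`Qf`, `prob`), plus the mixture
#'   description.
#' @examples
#' # 3:1 LESWAS:LEDWAS cDNA mixture
#' td <- tetramer_distribution("LESWAS", "LEDWAS", p = 0.25)
#' subset(td$charge, Qf == -5)$prob  # 0.421875
#' @export
tetramer_distribution <- function(speciesA, speciesB, p, N = 4L) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single fraction in [0, 1]")
  }
  if (N < 1L) stop("N must be >= 1")
  A <- as_monomer(speciesA); B <- as_monomer(speciesB)
  n <- 0:N
  prob <- choose(N, n) * p^n * (1 - p)^(N - n)
  Qf <- (N - n) * A$charge + n * B$charge
  charge <- stats::aggregate(prob, by = list(Qf = Qf), FUN = sum)
  names(charge)[2] <- "prob"
  charge <- charge[order(-charge$Qf), , drop = FALSE]
  rownames(charge) <- NULL
  structure(list(
    composition = data.frame(n_B = n, prob = prob, Qf = Qf),
    charge = charge,
    speciesA = A, speciesB = B, p = p, N = as.integer(N)
  ), class = "tetramer_distribution")
}

#' Multinomial generalization to more than two monomer species
#'
#' Enumerates all ordered assignments of `N` slots to the given species
#' (each slot independent with the stated probabilities) and aggregates by
#' total SF charge. For two species this reduces exactly to
#' [tetramer_distribution()].
#'
#' @param species list of [monomer_species()] (or registry names).
#' @param probs per-slot probabilities, summing to 1.
#' @param N slots per channel.
#' @return data frame with `Qf` and `prob`.
#' @export
tetramer_charge_multinomial <- function(species, probs, N = 4L) {
  species <- lapply(species, as_monomer)
  if (length(probs) != length(species)) {
    stop("probs must match species in length")
  }
  if (abs(sum(probs) - 1) > 1e-9) stop("probs must sum to 1")
  k <- length(species)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), N))
  prob <- apply(grid, 1, function(idx) prod(probs[idx]))
  charges <- vapply(species, `[[`, numeric(1), "charge")
  Qf <- apply(grid, 1, function(idx) sum(charges[idx]))
  agg <- stats::aggregate(prob, by = list(Qf = Qf), FUN = sum)
  names(agg)[2] <- "prob"
  agg[order(-agg$Qf), , drop = FALSE]
}

#' Cumulative probability over tetramer charges
#'
#' Sums the charge distribution over `Qf <= threshold` (`"at_most"`: the
#' stated charge or more negative, i.e. that magnitude of fixed charge "and
#' greater") or `Qf >= threshold` (`"at_least"`).
#'
#' @param dist a [tetramer_distribution()].
#' @param threshold charge threshold, e.
#' @param direction `"at_most"` or `"at_least"`.
#' @return a probability.
#' @export
cumulative_charge_probability <- function(dist, threshold,
                                          direction = c("at_most",
                                                        "at_least")) {
  stopifnot(inherits(dist, "tetramer_distribution"))
  direction <- match.arg(direction)
  ch <- dist$charge
  if (direction == "at_most") sum(ch$prob[ch$Qf <= threshold])
  else sum(ch$prob[ch$Qf >= threshold])
}

# half-up rounding to `digits` decimals (round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Render a tetramer charge distribution as a percentage table
#'
#' @param dist a [tetramer_distribution()].
#' @param style `"percent_int"` (integer percentages) or `"percent_1dp"`
#'   (one decimal place); rounding is half-up.
#' @return character vector, one line per charge state, e.g. `"Qf = -5: 42%"`.
#' @export
format_tetramer_table <- function(dist, style = c("percent_int",
                                                  "percent_1dp")) {
  stopifnot(inherits(dist, "tetramer_distribution"))
  style <- match.arg(style)
  pct <- dist$charge$prob * 100
  lab <- if (style == "percent_int") {
    sprintf("%g%%", round_half_up(pct, 0))
  } else {
    sprintf("%.1f%%", round_half_up(pct, 1))
  }
  sprintf("Qf = %g: %s", dist$charge$Qf, lab)
}

#' @export
print.tetramer_distribution <- function(x, ...) {
  cat(sprintf("tetramer_distribution: %s (q = %g e) : %s (q = %g e), p_B = %g, N = %d\n",
              x$speciesA$name, x$speciesA$charge,
              x$speciesB$name, x$speciesB$charge, x$p, x$N))
  writeLines(paste(" ", format_tetramer_table(x, "percent_1dp")))
  invisible(x)
}
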