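# Metropolis-Hastings generation of non-overlapping disk ensembles
# (blood-smear phantoms).
#
# Disks are thrown uniformly into the ROI (overlaps allowed), each
# overlapping pair is charged a fixed energy Vij in units of kB*T, and
# single-particle teleport moves are accepted by the Metropolis rule
# until the total energy reaches exactly zero.  With Vij = 1000 kB*T an
# overlap is effectively forbidden, so the chain is a stochastic search
# for a valid hard-disk configuration.

#' Region of interest for phantom generation
#'
#' @param shape `"square"` or `"circle"`.
#' @param size Side length (square) or radius (circle) in micrometres.
#' @param origin Centre of the ROI in domain coordinates (um).
#' @return An `roi_spec` object with a derived `area` (um^2).
#' @export
#' @examples
#' roi_spec("circle", 50)       # the 50-um circular smear region
#' roi_spec("square", 104.8)
roi_spec <- function(shape = c("square", "circle"), size, origin = c(0, 0)) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(size), size > 0, length(origin) == 2)
  area <- if (shape == "square") size^2 else pi * size^2
  structure(list(shape = shape, size = size, origin = as.numeric(origin),
                 area = area),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> %s, size %g um, origin (%g, %g), area %.4g um^2\n",
              x$shape, x$size, x$origin[1], x$origin[2], x$area))
  invisible(x)
}

#' Packing-chain configuration
#'
#' @param n_disks Number of disks to place (>= 1).
#' @param radius Common disk radius in micrometres.
#' @param overlap_energy_unit Energy charged per overlapping pair, in
#'   units of \eqn{k_B T} (default 1000, making overlaps effectively
#'   forbidden).
#' @param max_sweeps Proposal budget as multiples of `n_disks`
#'   (default 5000 sweeps).
#' @param seed RNG seed; the chain is fully deterministic given it.
#' @return A `packing_config` object.  Implied area fractions above
#'   0.5 trigger a feasibility warning at packing time.
#' @export
packing_config <- function(n_disks, radius = 2.75, overlap_energy_unit = 1000,
                           max_sweeps = 5000, seed = 1) {
  stopifnot(n_disks >= 1, radius > 0, overlap_energy_unit > 0, max_sweeps >= 1)
  structure(list(n_disks = as.integer(n_disks), radius = radius,
                 overlap_energy_unit = overlap_energy_unit,
                 max_sweeps = as.integer(max_sweeps), seed = as.integer(seed)),
            class = "packing_config")
}

#' @export
print.packing_config <- function(x, ...) {
  cat(sprintf("<packing_config> %d disks of radius %g um, Vij=%g kBT, seed %d\n",
              x$n_disks, x$radius, x$overlap_energy_unit, x$seed))
  invisible(x)
}

#' Number of disks needed for a target area fraction
#'
#' The smallest integer N with \eqn{N \pi a^2 \ge} `fraction` x
#' area(ROI).  For the 50-um circular ROI at 40\% coverage with
#' 2.75-um disks this gives 133 cells.
#'
#' @param roi An [roi_spec()].
#' @param radius Disk radius in micrometres.
#' @param fraction Target area fraction in (0, 0.9).
#' @return Integer disk count.  Fractions above 0.55 warn that random
#'   packing may not terminate.
#' @export
#' @examples
#' n_disks_for_fraction(roi_spec("circle", 50), 2.75, 0.4)  # 133
n_disks_for_fraction <- function(roi, radius, fraction) {
  stopifnot(inherits(roi, "roi_spec"), fraction > 0, fraction < 0.9)
  if (fraction > 0.55)
    warning("area fraction ", fraction,
            " > 0.55: hard-disk random packing may not terminate")
  # tiny slack so an exact integer share is not pushed up by rounding
  as.integer(ceiling(fraction * roi$area / (pi * radius^2) - 1e-9))
}

# Pairwise overlap count; overlap is strict (tangency is legal).
overlap_pairs <- function(x, y, radius) {
  n <- length(x)
  if (n < 2) return(0L)
  d2 <- (outer(x, x, "-"))^2 + (outer(y, y, "-"))^2
  sum(d2[upper.tri(d2)] < (2 * radius)^2)
}

#' Total overlap energy of a disk configuration
#'
#' `overlap_energy_unit` times the number of unordered disk pairs whose
#' centre distance is strictly less than the sum of their radii
#' (tangent disks do not overlap).
#'
#' @param disks A list of [disk()]s.
#' @param config A [packing_config()] (supplies the pair energy).
#' @return Nonnegative energy in units of \eqn{k_B T}.
#' @export
overlap_energy <- function(disks, config) {
  disks <- as_disk_list(disks)
  n <- length(disks)
  if (n < 2) return(0)
  ctr <- t(vapply(disks, function(d) d$center, numeric(2)))
  rad <- vapply(disks, function(d) d$radius, numeric(1))
  d2 <- (outer(ctr[, 1], ctr[, 1], "-"))^2 + (outer(ctr[, 2], ctr[, 2], "-"))^2
  rsum2 <- outer(rad, rad, "+")^2
  config$overlap_energy_unit * sum((d2 < rsum2)[upper.tri(d2)])
}

#' Metropolis acceptance rule
#'
#' Accept when the energy change is negative; otherwise accept when the
#' supplied uniform draw does not exceed the Metropolis ratio
#' \eqn{e^{-\Delta E/k_B T}} (energies already in \eqn{k_B T} units, so
#' the ratio is `exp(-delta_E)`).
#'
#' @param delta_E Energy difference (new - old) in \eqn{k_B T}.
#' @param rng_draw Uniform draw in `[0, 1)`.
#' @return Logical.
#' @export
#' @examples
#' metropolis_accept(-1000, 0.99)  # downhill: always TRUE
#' metropolis_accept(0, 0.99)      # ratio 1: TRUE
#' metropolis_accept(1000, 0.5)    # e^-1000 ~ 0: FALSE
metropolis_accept <- function(delta_E, rng_draw) {
  stopifnot(rng_draw >= 0, rng_draw < 1)
  delta_E < 0 || rng_draw <= exp(-delta_E)
}

# Uniform position inside the ROI eroded by the disk radius, so disks
# sit fully inside the ROI.  Vectorised over k draws.
sample_positions <- function(roi, radius, k) {
  if (roi$shape == "square") {
    half <- roi$size / 2 - radius
    if (half <= 0) stop("disk radius exceeds the half-size of the square ROI")
    cbind(runif(k, -half, half), runif(k, -half, half))
  } else {
    rmax <- roi$size - radius
    if (rmax <= 0) stop("disk radius exceeds the radius of the circular ROI")
    r <- rmax * sqrt(runif(k))
    th <- runif(k, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  } + matrix(roi$origin, k, 2, byrow = TRUE)
}

#' Pack non-overlapping disks into an ROI by Metropolis-Hastings
#'
#' Places `config$n_disks` disks uniformly at random in the ROI
#' (overlaps allowed, continuous coordinates), then repeatedly picks a
#' disk at random, proposes a uniform random new position, and accepts
#' by [metropolis_accept()] on the incremental energy change.  The
#' chain stops as soon as the total [overlap_energy()] is exactly zero.
#'
#' @param roi An [roi_spec()].
#' @param config A [packing_config()].
#' @return A `tissue_realization`: the list of disks, the ROI, the seed,
#'   `final_energy` (0 on success), the achieved `area_fraction` and
#'   proposal/acceptance counts.  An exhausted proposal budget raises an
#'   error reporting the remaining energy and acceptance statistics.
#' @export
#' @examples
#' tr <- pack_disks(roi_spec("circle", 20),
#'                  packing_config(n_disks = 12, seed = 42))
#' tr$final_energy  # 0
pack_disks <- function(roi, config) {
  stopifnot(inherits(roi, "roi_spec"), inherits(config, "packing_config"))
  n <- config$n_disks
  a <- config$radius
  frac <- n * pi * a^2 / roi$area
  if (frac > 0.5)
    warning(sprintf("implied area fraction %.2f > 0.5: packing may be slow or infeasible",
                    frac))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  pos <- sample_positions(roi, a, n)
  # Per-disk overlap counts drive incremental energy bookkeeping.
  pair_overlaps <- function(i, xy) {
    d2 <- (pos[, 1] - xy[1])^2 + (pos[, 2] - xy[2])^2
    d2[i] <- Inf
    sum(d2 < (2 * a)^2)
  }
  energy_pairs <- overlap_pairs(pos[, 1], pos[, 2], a)
  proposals <- 0L
  accepted <- 0L
  budget <- config$max_sweeps * n
  while (energy_pairs > 0L && proposals < budget) {
    i <- sample.int(n, 1)
    new_xy <- sample_positions(roi, a, 1)[1, ]
    d_pairs <- pair_overlaps(i, new_xy) - pair_overlaps(i, pos[i, ])
    proposals <- proposals + 1L
    if (metropolis_accept(d_pairs * config$overlap_energy_unit, runif(1))) {
      pos[i, ] <- new_xy
      energy_pairs <- energy_pairs + d_pairs
      accepted <- accepted + 1L
    }
  }
  if (energy_pairs > 0L)
    stop(sprintf(paste0(
      "packing budget exhausted: %d overlapping pair(s) remain ",
      "(energy %g kBT) after %d proposals (%d accepted)"),
      energy_pairs, energy_pairs * config$overlap_energy_unit,
      proposals, accepted))

  disks <- lapply(seq_len(n), function(i) disk(pos[i, ], a))
  structure(list(disks = disks, roi = roi, seed = config$seed,
                 final_energy = 0,
                 area_fraction = frac,
                 proposals = proposals, accepted = accepted),
            class = "tissue_realization")
}

#' @export
print.tissue_realization <- function(x, ...) {
  cat(sprintf(
    "<tissue_realization> %d disks in %s ROI (size %g um), area fraction %.3f\n",
    length(x$disks), x$roi$shape, x$roi$size, x$area_fraction))
  cat(sprintf("  seed %d, %d proposals (%d accepted), final energy %g\n",
              x$seed, x$proposals, x$accepted, x$final_energy))
  invisible(x)
}

#' Read and write phantom files
#'
#' Phantoms are exchanged as a CSV of disk centres and radii (columns
#' `x_um`, `y_um`, `radius_um`) plus a JSON sidecar recording the ROI
#' shape and size, the seed and the achieved area fraction.
#'
#' @param realization A `tissue_realization` from [pack_disks()].
#' @param path CSV file path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_phantom()` returns `path` invisibly;
#'   `read_phantom()` returns a `tissue_realization` (with `NA`
#'   proposal counts when only files are available).
#' @export
write_phantom <- function(realization, path) {
  stopifnot(inherits(realization, "tissue_realization"))
  df <- data.frame(
    x_um = vapply(realization$disks, function(d) d$center[1], numeric(1)),
    y_um = vapply(realization$disks, function(d) d$center[2], numeric(1)),
    radius_um = vapply(realization$disks, function(d) d$radius, numeric(1)))
  write.csv(df, path, row.names = FALSE)
  meta <- list(roi_shape = realization$roi$shape,
               roi_size_um = realization$roi$size,
               roi_origin_um = realization$roi$origin,
               seed = realization$seed,
               area_fraction = realization$area_fraction,
               final_energy = realization$final_energy)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @param path CSV file path written by `write_phantom()`.
#' @export
read_phantom <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("x_um", "y_um", "radius_um") %in% names(df)))
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("phantom sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  roi <- roi_spec(meta$roi_shape, meta$roi_size_um,
                  origin = as.numeric(meta$roi_origin_um))
  disks <- lapply(seq_len(nrow(df)),
                  function(i) disk(c(df$x_um[i], df$y_um[i]), df$radius_um[i]))
  structure(list(disks = disks, roi = roi, seed = meta$seed,
                 final_energy = meta$final_energy,
                 area_fraction = meta$area_fraction,
                 proposals = NA_integer_, accepted = NA_integer_),
            class = "tissue_realization")
}
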