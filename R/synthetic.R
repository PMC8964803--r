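# Procedural test objects, probes, scan grids and simulated diffraction
# stacks. Everything is deterministic given its seed so the full pipeline is
# testable without any downloaded assets.

#' Siemens-star test object
#'
#' Radial binary-spoke resolution target mapped to a complex transmission:
#' spoke pixels get amplitude `amp_range[1]` and phase `phase_range[2]`,
#' background (including the inner disk and outside the outer radius) gets
#' amplitude `amp_range[2]` and phase `phase_range[1]`. The defaults emulate
#' a weakly absorbing, phase-shifting specimen on an empty (unit
#' transmission) background.
#'
#' @param size image side in pixels (>= 64).
#' @param n_spokes number of spokes (>= 2).
#' @param inner_radius inner cutoff as a fraction of `size` (spokes are drawn
#'   in the annulus between `inner_radius` and `outer_radius`).
#' @param outer_radius outer cutoff as a fraction of `size`.
#' @param amp_range `c(spoke, background)` amplitudes.
#' @param phase_range `c(background, spoke)` phases in radians.
#' @return complex `size x size` matrix.
#' @export
pty_star <- function(size, n_spokes = 32L, inner_radius = 0.06,
                     outer_radius = 0.45, amp_range = c(0.6, 1),
                     phase_range = c(0, 0.8)) {
  if (size < 64) stop("star size must be >= 64 pixels")
  if (n_spokes < 2) stop("a star needs at least 2 spokes")
  if (length(amp_range) != 2 || any(amp_range < 0))
    stop("amp_range must be two non-negative amplitudes")
  if (length(phase_range) != 2) stop("phase_range must have two entries")
  ctr <- (size + 1) / 2
  x <- matrix(rep(seq_len(size) - ctr, each = size), size, size)
  y <- matrix(rep(seq_len(size) - ctr, times = size), size, size)
  rho <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)  # (-pi, pi]
  sector <- floor((theta + pi) / (2 * pi / n_spokes))
  spoke <- (sector %% 2 == 0) & rho >= inner_radius * size &
    rho <= outer_radius * size
  amp <- ifelse(spoke, amp_range[1], amp_range[2])
  phs <- ifelse(spoke, phase_range[2], phase_range[1])
  matrix(complex(modulus = amp, argument = phs), size, size)
}

#' Procedural-texture test object
#'
#' Smooth seeded random texture (low-pass-filtered Gaussian noise) mapped to
#' amplitude and phase, standing in for photographic test images such as a
#' coin tableau. Amplitude spans `amp_range`, phase spans `phase_range`.
#'
#' @param size image side in pixels.
#' @param corr_length correlation length of the texture in pixels.
#' @param amp_range,phase_range output ranges as in [pty_star()].
#' @param seed RNG seed.
#' @return complex `size x size` matrix.
#' @export
pty_texture <- function(size, corr_length = 12, amp_range = c(0.5, 1),
                        phase_range = c(0, 1), seed = 1L) {
  if (size < 16) stop("texture size must be >= 16 pixels")
  smooth_field <- function(z) {
    f <- seq(0, size - 1); f <- pmin(f, size - f) / size
    k2 <- outer(f^2, f^2, "+")
    filt <- exp(-2 * (pi * corr_length)^2 * k2)
    Re(fft(fft(z) * filt, inverse = TRUE)) / length(z)
  }
  rescale <- function(z, range) {
    if (diff(range(z)) == 0) return(matrix(range[1], size, size))
    range[1] + (z - min(z)) / diff(range(z)) * diff(range)
  }
  with_seed(seed, {
    amp <- rescale(smooth_field(matrix(rnorm(size^2), size, size)), amp_range)
    phs <- rescale(smooth_field(matrix(rnorm(size^2), size, size)), phase_range)
    matrix(complex(modulus = amp, argument = phs), size, size)
  })
}

#' Synthetic illumination probe
#'
#' Disk (top-hat) or Gaussian amplitude profile, optionally with a quadratic
#' (defocus-like) phase, normalized to unit peak amplitude.
#'
#' @param S probe side in pixels (>= 8).
#' @param kind `"disk"` or `"gaussian"`.
#' @param radius top-hat radius in pixels (disk), default `S/4`.
#' @param sigma Gaussian width in pixels, default `S/6`.
#' @param defocus quadratic-phase coefficient: phase `defocus * (rho/S)^2`
#'   radians.
#' @return complex `S x S` matrix with `max(Mod(probe)) == 1`.
#' @export
pty_probe <- function(S, kind = c("disk", "gaussian"), radius = S / 4,
                      sigma = S / 6, defocus = 0) {
  kind <- match.arg(kind)
  if (S < 8) stop("probe side must be >= 8 pixels")
  ctr <- (S + 1) / 2
  x <- matrix(rep(seq_len(S) - ctr, each = S), S, S)
  y <- matrix(rep(seq_len(S) - ctr, times = S), S, S)
  rho2 <- x^2 + y^2
  amp <- switch(kind,
    disk = { if (radius <= 0) stop("disk radius must be positive")
             (rho2 <= radius^2) * 1 },
    gaussian = { if (sigma <= 0) stop("gaussian sigma must be positive")
                 exp(-rho2 / (2 * sigma^2)) })
  if (all(amp == 0)) stop("probe support is empty; increase radius")
  amp <- amp / max(amp)
  matrix(complex(modulus = amp, argument = defocus * rho2 / S^2), S, S)
}

#' Jittered raster scan grid
#'
#' Top-left footprint corners on a raster with the given step, plus seeded
#' uniform integer jitter, clipped so every footprint stays inside the
#' object. Overlap between adjacent footprints requires `step < S`.
#'
#' @param H,W object grid size.
#' @param S probe side.
#' @param step raster step in pixels (< S).
#' @param jitter maximum absolute jitter per axis in pixels (< step/2).
#' @param seed RNG seed for the jitter.
#' @return integer `n x 2` matrix of 0-based `(row, col)` positions.
#' @export
pty_scan <- function(H, W, S, step, jitter = 0, seed = 1L) {
  if (step >= S) stop("insufficient overlap: scan step must be smaller than the probe side")
  if (step < 1) stop("scan step must be >= 1 pixel")
  if (jitter >= step / 2) stop("jitter must be smaller than step/2")
  rows <- seq(0L, H - S, by = step)
  cols <- seq(0L, W - S, by = step)
  pos <- cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))
  if (jitter > 0) {
    pos <- with_seed(seed, {
      jit <- matrix(sample.int(2L * as.integer(jitter) + 1L, length(pos),
                               replace = TRUE) - as.integer(jitter) - 1L,
                    nrow(pos), 2L)
      pos + jit
    })
    pos[, 1] <- pmin(pmax(pos[, 1], 0L), H - S)
    pos[, 2] <- pmin(pmax(pos[, 2], 0L), W - S)
  }
  storage.mode(pos) <- "integer"
  colnames(pos) <- c("row", "col")
  pos
}

#' Bytes needed to hold a diffraction stack
#'
#' `S^2 * n * bytes_per_value`, the memory footprint that motivates
#' distributing the patterns over several workers (e.g. a 512-pixel detector
#' at 16K positions in 4-byte floats needs 16 GiB).
#'
#' @param S detector/probe side in pixels.
#' @param n number of diffraction patterns.
#' @param bytes_per_value bytes per stored value (4 for single precision).
#' @return numeric byte count (exact for any realistic size).
#' @export
pty_diffraction_bytes <- function(S, n, bytes_per_value) {
  stopifnot(S >= 0, n >= 0, bytes_per_value >= 0)
  as.numeric(S)^2 * as.numeric(n) * as.numeric(bytes_per_value)
}

#' Simulate a ptychography dataset
#'
#' Forms `d = |G psi|^2` from a ground-truth object, probe and scan grid;
#' optionally replaces the intensities by seeded Poisson photon counts with
#' per-pixel mean `flux * d / max(d)`. The ground truth is retained in the
#' returned dataset.
#'
#' @param obj complex ground-truth object.
#' @param probe complex probe.
#' @param positions scan grid as from [pty_scan()].
#' @param noise `"none"` or `"poisson"`.
#' @param flux peak expected photon count for Poisson noise.
#' @param seed RNG seed for the noise draws.
#' @return A list of class `pty_dataset`: `data` (S, S, n), `probe`,
#'   `positions`, `shape`, `ground_truth`, `spec` (simulation parameters).
#' @export
pty_simulate <- function(obj, probe, positions, noise = c("none", "poisson"),
                         flux = 1e5, seed = 1L) {
  noise <- match.arg(noise)
  obj <- as_complex_matrix(obj)
  d <- pty_intensities(pty_forward(obj, probe, positions))
  if (noise == "poisson") {
    if (flux <= 0) stop("poisson flux must be positive")
    lambda <- flux * d / max(d)
    counts <- with_seed(seed, rpois(length(lambda), lambda))
    d <- array(as.double(counts), dim = dim(d))
  }
  pty_dataset(d, probe, positions, dim(obj), ground_truth = obj,
              spec = list(noise = noise, flux = if (noise == "poisson") flux,
                          seed = seed))
}

#' Assemble a ptychography dataset object
#'
#' Validates mutual consistency of the diffraction stack, probe, scan grid
#' and object shape.
#'
#' @param data real `(S, S, n)` non-negative intensity stack.
#' @param probe complex `S x S` probe.
#' @param positions integer `n x 2` scan grid.
#' @param shape integer `c(H, W)` object size.
#' @param ground_truth optional complex `H x W` reference object.
#' @param spec optional list of simulation parameters (kept for provenance).
#' @return list of class `pty_dataset`.
#' @export
pty_dataset <- function(data, probe, positions, shape, ground_truth = NULL,
                        spec = NULL) {
  probe <- check_probe(probe)
  shape <- as.integer(shape)
  positions <- pty_check_scan(positions, shape, nrow(probe))
  data <- check_data_stack(data, nrow(probe), nrow(positions))
  if (!is.null(ground_truth)) {
    ground_truth <- as_complex_matrix(ground_truth, "ground truth")
    if (!all(dim(ground_truth) == shape))
      stop("ground truth shape does not match the declared object shape")
  }
  structure(list(data = data, probe = probe, positions = positions,
                 shape = shape, ground_truth = ground_truth, spec = spec),
            class = "pty_dataset")
}

#' @export
print.pty_dataset <- function(x, ...) {
  cat(sprintf("<pty_dataset> %d patterns, %dx%d detector, %dx%d object%s%s\n",
              dim(x$data)[3], dim(x$data)[1], dim(x$data)[2],
              x$shape[1], x$shape[2],
              if (!is.null(x$ground_truth)) ", with ground truth" else "",
              if (!is.null(x$spec$noise) && x$spec$noise != "none")
                paste0(", ", x$spec$noise, " noise") else ", noise-free"))
  invisible(x)
}
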