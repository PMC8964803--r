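# Domain geometry and the ptychography operator G = F Q, with F a unitary
# per-pattern 2-D DFT and Q probe-times-patch extraction. Scan positions are
# 0-based (row, col) top-left corners of half-open S x S footprints; a
# position is valid when the footprint lies fully inside the object grid.

#' Validate a scan-position matrix against an object/probe geometry
#'
#' @param positions integer matrix, n x 2, 0-based `(row, col)` top-left
#'   corners of probe footprints.
#' @param shape integer vector `c(H, W)`, object grid size in pixels.
#' @param S probe side length in pixels.
#' @return The positions coerced to an integer matrix, invisibly usable
#'   downstream; errors if any footprint leaves the grid.
#' @export
pty_check_scan <- function(positions, shape, S) {
  positions <- as_positions(positions)
  if (nrow(positions) < 1L) stop("scan grid must contain at least one position")
  H <- shape[1]; W <- shape[2]
  bad <- which(positions[, 1] < 0L | positions[, 2] < 0L |
               positions[, 1] > H - S | positions[, 2] > W - S)
  if (length(bad)) {
    stop(sprintf(
      "scan position %d (row=%d, col=%d) places the %dx%d probe footprint outside the %dx%d object",
      bad[1], positions[bad[1], 1], positions[bad[1], 2], S, S, H, W))
  }
  positions
}

as_positions <- function(positions) {
  if (is.null(dim(positions)) && length(positions) == 2L)
    positions <- matrix(positions, 1L, 2L)
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop("positions must be an n x 2 matrix of (row, col)")
  storage.mode(positions) <- "integer"
  positions
}

as_complex_matrix <- function(x, what = "object") {
  if (!is.matrix(x)) stop(sprintf("%s must be a matrix", what))
  if (!is.complex(x)) storage.mode(x) <- "complex"
  x
}

check_probe <- function(probe) {
  probe <- as_complex_matrix(probe, "probe")
  if (nrow(probe) != ncol(probe)) stop("probe must be square")
  if (all(probe == 0)) stop("probe must not be identically zero")
  probe
}

check_stack <- function(x, S, n, what = "stack") {
  d <- dim(x)
  if (length(d) != 3L || d[1] != S || d[2] != S || d[3] != n)
    stop(sprintf("%s must be an array of dim (%d, %d, %d), got (%s)",
                 what, S, S, n, paste(d, collapse = ", ")))
  x
}

#' Probe-times-patch extraction (the operator Q)
#'
#' Extracts the `S x S` patch of the object under each scan position and
#' multiplies it elementwise by the probe.
#'
#' @param obj complex `H x W` object transmission matrix.
#' @param probe complex `S x S` probe matrix.
#' @param positions integer `n x 2` matrix of 0-based `(row, col)` footprint
#'   corners.
#' @return complex array of dim `(S, S, n)`; slice `j` is
#'   `probe * obj[row_j + 1:S, col_j + 1:S]`.
#' @export
pty_apply_Q <- function(obj, probe, positions) {
  obj <- as_complex_matrix(obj); probe <- check_probe(probe)
  positions <- pty_check_scan(positions, dim(obj), nrow(probe))
  apply_Q_cpp(obj, probe, positions)
}

#' Adjoint of the probe-times-patch operator (Q^H)
#'
#' Multiplies each patch by the conjugate probe and scatter-adds it into an
#' `H x W` zero grid at its scan position; overlapping footprints accumulate.
#'
#' @param patches complex `(S, S, n)` patch stack.
#' @inheritParams pty_apply_Q
#' @param shape integer `c(H, W)` of the output grid.
#' @return complex `H x W` matrix.
#' @export
pty_apply_QH <- function(patches, probe, positions, shape) {
  probe <- check_probe(probe)
  positions <- pty_check_scan(positions, shape, nrow(probe))
  patches <- check_stack(patches, nrow(probe), nrow(positions), "patch stack")
  if (!is.complex(patches)) storage.mode(patches) <- "complex"
  apply_QH_cpp(patches, probe, positions, shape[1], shape[2])
}

#' Ptychography forward operator G = F Q
#'
#' Applies [pty_apply_Q()] and then an independent unitary (orthonormal) 2-D
#' discrete Fourier transform to each patch, giving the modeled far-field
#' wave at every scan position.
#'
#' @inheritParams pty_apply_Q
#' @return complex `(S, S, n)` far-field wave stack.
#' @export
pty_forward <- function(obj, probe, positions) {
  obj <- as_complex_matrix(obj); probe <- check_probe(probe)
  positions <- pty_check_scan(positions, dim(obj), nrow(probe))
  forward_cpp(obj, probe, positions)
}

#' Adjoint ptychography operator G^H = Q^H F^H
#'
#' Applies the unitary inverse transform per pattern followed by
#' [pty_apply_QH()]. Under the unitary convention this is the exact adjoint
#' of [pty_forward()].
#'
#' @param waves complex `(S, S, n)` far-field wave stack.
#' @inheritParams pty_apply_QH
#' @return complex `H x W` matrix.
#' @export
pty_adjoint <- function(waves, probe, positions, shape) {
  probe <- check_probe(probe)
  positions <- pty_check_scan(positions, shape, nrow(probe))
  waves <- check_stack(waves, nrow(probe), nrow(positions), "wave stack")
  if (!is.complex(waves)) storage.mode(waves) <- "complex"
  adjoint_cpp(waves, probe, positions, shape[1], shape[2])
}

#' Far-field intensities |G psi|^2
#'
#' @param waves complex wave stack (any dimension).
#' @return real array of the same shape, elementwise squared modulus.
#' @export
pty_intensities <- function(waves) {
  out <- Mod(waves)^2
  dim(out) <- dim(waves)
  out
}
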