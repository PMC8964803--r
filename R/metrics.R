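# Reconstruction quality metrics. The ML cost depends on psi only through
# |G psi|, so a reconstruction is determined up to a global phase; metrics
# are therefore computed on amplitude images after global-phase alignment.

#' Remove the global phase ambiguity of a reconstruction
#'
#' Multiplies `est` by `exp(-i theta)` with `theta = Arg(<ref, est>)`,
#' `<a,b> = sum conj(a) b`, which minimizes `||est * exp(-i theta) - ref||`
#' over all global phases.
#'
#' @param est complex estimate.
#' @param ref complex reference of the same shape.
#' @return phase-aligned complex matrix; if the inner product vanishes the
#'   estimate is returned unchanged with a warning.
#' @export
pty_align_phase <- function(est, ref) {
  if (!all(dim(est) == dim(ref))) stop("images must share a shape")
  ip <- sum(Conj(ref) * est)
  if (Mod(ip) == 0) {
    warning("zero inner product between estimate and reference; phase left unchanged")
    return(est)
  }
  est * exp(-1i * Arg(ip))
}

gaussian_kernel <- function(radius, sigma) {
  k <- dnorm(seq(-radius, radius), sd = sigma)
  k / sum(k)
}

# Separable 2-D convolution, "valid" output region (borders of width
# `radius` dropped). Input must be at least (2*radius+1) on each side.
filter2_valid <- function(x, kernel) {
  radius <- (length(kernel) - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  if (nr < length(kernel) || nc < length(kernel))
    stop(sprintf("image must be at least %d pixels per side for this window",
                 length(kernel)))
  # along rows (each column), then along columns
  cv <- function(m) {
    out <- matrix(0, nrow(m) - 2L * radius, ncol(m))
    for (t in seq_along(kernel))
      out <- out + kernel[t] * m[t:(t + nrow(out) - 1L), , drop = FALSE]
    out
  }
  t(cv(t(cv(x))))
}

#' Structural similarity index (SSIM)
#'
#' Standard single-scale SSIM with a Gaussian window (radius 7 pixels,
#' sigma 1.5) and the conventional stabilization constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`. Local statistics are averaged over
#' the interior region fully covered by the window, so the score is
#' symmetric in its two arguments.
#'
#' @param a,b real images of identical shape (amplitudes, after phase
#'   alignment, when scoring reconstructions).
#' @param data_range dynamic range `L`; defaults to the joint range of both
#'   images (1 is conventional for unit-normalized amplitudes).
#' @param radius,sigma Gaussian window geometry in pixels.
#' @return scalar in `[-1, 1]`; 1 means structurally identical.
#' @export
pty_ssim <- function(a, b, data_range = NULL, radius = 7L, sigma = 1.5) {
  if (!all(dim(a) == dim(b))) stop("images must share a shape")
  a <- as.double(a); dim(a) <- dim(b)
  b_ <- as.double(b); dim(b_) <- dim(a); b <- b_
  if (is.null(data_range)) data_range <- diff(range(c(a, b)))
  if (data_range <= 0) data_range <- 1
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  k <- gaussian_kernel(radius, sigma)
  mu_a <- filter2_valid(a, k); mu_b <- filter2_valid(b, k)
  va <- filter2_valid(a * a, k) - mu_a^2
  vb <- filter2_valid(b * b, k) - mu_b^2
  vab <- filter2_valid(a * b, k) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in decibels; identical images give `Inf`.
#'
#' @inheritParams pty_ssim
#' @param peak signal peak (> 0), e.g. the reference amplitude maximum.
#' @return scalar in dB.
#' @export
pty_psnr <- function(a, b, peak = 1) {
  if (!all(dim(a) == dim(b))) stop("images must share a shape")
  if (peak <= 0) stop("peak must be positive")
  mse <- mean((as.double(a) - as.double(b))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Iterate difference 2-norm
#'
#' `||psi_m - psi_{m-1}||_2`, the convergence-progress metric; 0 means the
#' iterates are identical.
#'
#' @param psi_m,psi_prev complex matrices of identical shape.
#' @return non-negative scalar.
#' @export
pty_iterate_diff_norm <- function(psi_m, psi_prev) {
  if (!all(dim(psi_m) == dim(psi_prev))) stop("iterates must share a shape")
  sqrt(sum(Mod(psi_m - psi_prev)^2))
}

#' Accuracy/convergence experiment across worker counts
#'
#' Reconstructs one dataset with the monolithic solver and, for each worker
#' count in `P_list` beyond 1, with the partitioned solver, recording
#' per-iteration cost, step 2-norm and (when the dataset carries a ground
#' truth) phase-aligned amplitude SSIM/PSNR. Reconstructions with different
#' worker counts follow the same convergence curve; `curve_agreement`
#' reports the largest absolute per-iteration SSIM deviation from the
#' monolithic run.
#'
#' @param dataset a `pty_dataset` (usually from [pty_simulate()]).
#' @param cfg a [pty_config()].
#' @param P_list integer worker counts, e.g. `c(1, 2, 4)`.
#' @param backend worker backend for the partitioned runs, see
#'   [pty_reconstruct_partitioned()].
#' @return list with `curves` (long data frame: P, iter, cost, step_norm,
#'   ssim, psnr), `results` (one `pty_result` per P), and
#'   `curve_agreement` (named numeric, NA when no ground truth).
#' @export
pty_run_accuracy_experiment <- function(dataset, cfg = pty_config(),
                                        P_list = c(1L, 2L, 4L),
                                        backend = "serial") {
  stopifnot(inherits(dataset, "pty_dataset"), length(P_list) >= 1)
  results <- list()
  for (P in P_list) {
    key <- as.character(P)
    results[[key]] <- if (P == 1L)
      pty_reconstruct(dataset, cfg = cfg)
    else
      pty_reconstruct_partitioned(dataset, P = P, cfg = cfg, backend = backend)
  }
  curves <- do.call(rbind, lapply(names(results), function(key) {
    r <- results[[key]]$record
    cbind(data.frame(P = as.integer(key)),
          r[, c("iter", "cost", "step_norm", "ssim", "psnr")])
  }))
  agreement <- rep(NA_real_, length(P_list))
  names(agreement) <- as.character(P_list)
  base <- results[[as.character(P_list[1])]]$record
  if (!all(is.na(base$ssim))) {
    for (key in names(results)) {
      r <- results[[key]]$record
      n <- min(nrow(r), nrow(base))
      agreement[key] <- max(abs(r$ssim[seq_len(n)] - base$ssim[seq_len(n)]),
                            na.rm = TRUE)
    }
  }
  list(curves = curves, results = results, curve_agreement = agreement)
}
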