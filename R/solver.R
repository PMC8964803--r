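# Poisson maximum-likelihood cost, Wirtinger gradient, Dai-Yuan conjugate
# directions, backtracking line search, and the monolithic reconstruction
# loop. Conventions fixed here:
#   * F(psi) = sum_j sum_px { |G psi|^2 - 2 d log|G psi| } is real-valued;
#     the gradient is dF/dpsi* so the first-order change along eta is
#     2 Re<grad, eta> with <a,b> = sum conj(a) b.
#   * |G psi| is clamped below at eps_guard inside the log and the division.

#' Solver configuration
#'
#' @param n_iters iteration count (default 128, the usual full-length run).
#' @param gamma0 initial (large) line-search step, reset every iteration.
#' @param shrink multiplicative step-shrink factor in (0, 1).
#' @param t line-search termination parameter; the trial step gamma is
#'   accepted once `F(psi + gamma * eta) <= F(psi) + gamma * t`. 0 in
#'   practice, i.e. any non-increase is accepted.
#' @param max_ls_steps cap on shrinks per line search; hitting it returns the
#'   last trial step with a warning.
#' @param eps_guard small positive clamp on |G psi| guarding `log` and the
#'   elementwise division for vanishing far-field amplitude.
#' @param init_mode object initialization: `"ones"` (unit transmission) or
#'   `"random"` (unit transmission plus a small seeded complex perturbation).
#' @param init_noise amplitude of the random perturbation when
#'   `init_mode = "random"`.
#' @param seed integer seed for any randomized initialization.
#' @param stop_tol if positive, stop early once the relative iterate change
#'   `||psi_m - psi_{m-1}|| / ||psi_m||` falls below this for
#'   `stop_patience` consecutive iterations. 0 disables early stopping.
#' @param stop_patience consecutive small-change iterations required to stop.
#' @param metrics_every if a reference object is supplied to the solver,
#'   compute SSIM/PSNR every this many iterations (1 = every iteration,
#'   0 = final iterate only).
#' @return A list of class `pty_config`.
#' @export
pty_config <- function(n_iters = 128L, gamma0 = 1, shrink = 0.5, t = 0,
                       max_ls_steps = 32L, eps_guard = 1e-32,
                       init_mode = c("ones", "random"), init_noise = 0.1,
                       seed = 1L, stop_tol = 0, stop_patience = 5L,
                       metrics_every = 1L) {
  init_mode <- match.arg(init_mode)
  stopifnot(n_iters >= 1L, gamma0 > 0, shrink > 0, shrink < 1,
            max_ls_steps >= 1L, eps_guard > 0, stop_tol >= 0)
  structure(list(n_iters = as.integer(n_iters), gamma0 = gamma0,
                 shrink = shrink, t = t, max_ls_steps = as.integer(max_ls_steps),
                 eps_guard = eps_guard, init_mode = init_mode,
                 init_noise = init_noise, seed = as.integer(seed),
                 stop_tol = stop_tol, stop_patience = as.integer(stop_patience),
                 metrics_every = as.integer(metrics_every)),
            class = "pty_config")
}

check_data_stack <- function(d, S, n) {
  d <- check_stack(d, S, n, "diffraction stack")
  if (!is.double(d)) storage.mode(d) <- "double"
  if (any(d < 0)) stop("diffraction intensities must be non-negative")
  d
}

#' Poisson maximum-likelihood cost
#'
#' `F(psi) = sum_j sum_px { |G psi|^2 - 2 d log|G psi| }`, the Poisson
#' negative log-likelihood of the measured counts up to a psi-independent
#' constant. Pixels with `d = 0` contribute only the intensity term.
#'
#' @inheritParams pty_apply_Q
#' @param d real `(S, S, n)` stack of non-negative measured intensities.
#' @param eps_guard lower clamp on |G psi| inside the logarithm.
#' @return real scalar.
#' @export
pty_cost <- function(obj, d, probe, positions, eps_guard = 1e-32) {
  obj <- as_complex_matrix(obj); probe <- check_probe(probe)
  positions <- pty_check_scan(positions, dim(obj), nrow(probe))
  d <- check_data_stack(d, nrow(probe), nrow(positions))
  cost_cpp(obj, probe, positions, d, eps_guard)
}

#' Gradient of the Poisson ML cost
#'
#' Wirtinger gradient `dF/dpsi* = G^H ( G psi - d / (G psi)^* )`; the
#' elementwise division keeps the far-field phase and clamps the modulus at
#' `eps_guard`. At noise-free-consistent data (`d = |G psi|^2`) the gradient
#' vanishes.
#'
#' @inheritParams pty_cost
#' @return complex `H x W` matrix with the object shape.
#' @export
pty_gradient <- function(obj, d, probe, positions, eps_guard = 1e-32) {
  obj <- as_complex_matrix(obj); probe <- check_probe(probe)
  positions <- pty_check_scan(positions, dim(obj), nrow(probe))
  d <- check_data_stack(d, nrow(probe), nrow(positions))
  grad_cpp(obj, probe, positions, d, eps_guard)
}

#' Dai-Yuan conjugate search direction
#'
#' `eta_m = -g_m + alpha * eta_prev` with
#' `alpha = ||g_m||^2 / Re<eta_prev, g_m - g_prev>` and
#' `<a,b> = sum conj(a) b`. When `eta_prev`/`grad_prev` are `NULL` (first
#' iteration) or the denominator magnitude falls below `eps_guard`, the
#' steepest-descent direction `-g_m` is returned (restart).
#'
#' @param grad_m current gradient (complex matrix).
#' @param grad_prev previous gradient or `NULL`.
#' @param eta_prev previous direction or `NULL`.
#' @param eps_guard restart threshold on the denominator magnitude.
#' @return complex matrix of the same shape.
#' @export
pty_dai_yuan_direction <- function(grad_m, grad_prev = NULL, eta_prev = NULL,
                                   eps_guard = 1e-32) {
  if (is.null(grad_prev) || is.null(eta_prev)) return(-grad_m)
  if (!all(dim(grad_m) == dim(grad_prev)) || !all(dim(grad_m) == dim(eta_prev)))
    stop("gradient and direction grids must share the object shape")
  num <- sum(Mod(grad_m)^2)
  den <- Re(sum(Conj(eta_prev) * (grad_m - grad_prev)))
  if (num == 0) return(-grad_m)  # alpha = 0 regardless of the denominator
  if (abs(den) < eps_guard) return(-grad_m)
  -grad_m + (num / den) * eta_prev
}

#' Backtracking line search
#'
#' Starting from `cfg$gamma0`, multiplies the trial step by `cfg$shrink`
#' until `F(psi + gamma * eta) <= F(psi) + gamma * cfg$t` or
#' `cfg$max_ls_steps` shrinks have been tried (then the last trial step is
#' returned with a warning).
#'
#' @inheritParams pty_cost
#' @param eta complex search direction with the object shape.
#' @param cfg a [pty_config()].
#' @param cost0 optional precomputed `F(psi)` to avoid one evaluation.
#' @return list with `gamma` (accepted step, always > 0), `shrinks`
#'   (shrink count), `cost` (cost at the accepted step), and `converged`
#'   (FALSE when the cap was hit).
#' @export
pty_line_search <- function(obj, eta, d, probe, positions, cfg = pty_config(),
                            cost0 = NULL) {
  if (is.null(cost0)) cost0 <- pty_cost(obj, d, probe, positions, cfg$eps_guard)
  evaluate <- function(gamma)
    pty_cost(obj + gamma * eta, d, probe, positions, cfg$eps_guard)
  gamma <- cfg$gamma0
  shrinks <- 0L
  repeat {
    cost_try <- evaluate(gamma)
    if (cost_try <= cost0 + gamma * cfg$t)
      return(list(gamma = gamma, shrinks = shrinks, cost = cost_try,
                  converged = TRUE))
    if (shrinks >= cfg$max_ls_steps) {
      warning(sprintf("line search hit the shrink cap (%d); returning the last trial step",
                      cfg$max_ls_steps))
      return(list(gamma = gamma, shrinks = shrinks, cost = cost_try,
                  converged = FALSE))
    }
    gamma <- gamma * cfg$shrink
    shrinks <- shrinks + 1L
  }
}

init_object <- function(shape, cfg) {
  psi <- matrix(complex(real = 1, imaginary = 0), shape[1], shape[2])
  if (cfg$init_mode == "random") {
    noise <- with_seed(cfg$seed, {
      complex(real = rnorm(prod(shape)), imaginary = rnorm(prod(shape)))
    })
    psi <- psi + cfg$init_noise * matrix(noise, shape[1], shape[2])
  }
  psi
}

record_row <- function(iter, cost, step_norm, gamma, shrinks, ssim, psnr) {
  data.frame(iter = iter, cost = cost, step_norm = step_norm, gamma = gamma,
             ls_shrinks = shrinks, ssim = ssim, psnr = psnr)
}

eval_metrics <- function(psi, reference) {
  aligned <- pty_align_phase(psi, reference)
  a <- Mod(aligned); b <- Mod(reference)
  list(ssim = pty_ssim(a, b), psnr = pty_psnr(a, b, peak = max(b)))
}

#' Reconstruct an object with the Dai-Yuan CG maximum-likelihood solver
#'
#' Runs `cfg$n_iters` iterations, each in four stages: gradient (GRAD),
#' Dai-Yuan direction (DIR), backtracking line search (LS), and the update
#' `psi <- psi + gamma * eta`. Deterministic given `cfg$seed`.
#'
#' @param d real `(S, S, n)` diffraction stack, or a `pty_dataset` (then
#'   `probe`, `positions` and `shape` are taken from it).
#' @inheritParams pty_cost
#' @param shape integer `c(H, W)` of the object to reconstruct.
#' @param cfg a [pty_config()].
#' @param reference optional complex ground-truth object; when given,
#'   phase-aligned amplitude SSIM/PSNR are recorded per
#'   `cfg$metrics_every`.
#' @param init optional complex starting object (overrides `cfg$init_mode`).
#' @return list of class `pty_result` with elements `object` (complex
#'   `H x W`), `record` (per-iteration data frame: iter, cost, step_norm,
#'   gamma, ls_shrinks, ssim, psnr), and `config`.
#' @export
pty_reconstruct <- function(d, probe = NULL, positions = NULL, shape = NULL,
                            cfg = pty_config(), reference = NULL, init = NULL) {
  if (inherits(d, "pty_dataset")) {
    probe <- d$probe; positions <- d$positions; shape <- d$shape
    if (is.null(reference)) reference <- d$ground_truth
    d <- d$data
  }
  probe <- check_probe(probe)
  positions <- pty_check_scan(positions, shape, nrow(probe))
  d <- check_data_stack(d, nrow(probe), nrow(positions))
  psi <- if (is.null(init)) init_object(shape, cfg) else as_complex_matrix(init)

  grad_prev <- NULL; eta_prev <- NULL
  rows <- vector("list", cfg$n_iters)
  cost_prev <- pty_cost(psi, d, probe, positions, cfg$eps_guard)
  quiet <- 0L
  m_done <- 0L
  for (m in seq_len(cfg$n_iters)) {
    g <- pty_gradient(psi, d, probe, positions, cfg$eps_guard)
    eta <- pty_dai_yuan_direction(g, grad_prev, eta_prev, cfg$eps_guard)
    ls <- pty_line_search(psi, eta, d, probe, positions, cfg, cost0 = cost_prev)
    psi <- psi + ls$gamma * eta
    step_norm <- ls$gamma * sqrt(sum(Mod(eta)^2))
    met <- list(ssim = NA_real_, psnr = NA_real_)
    if (!is.null(reference) && cfg$metrics_every > 0L &&
        m %% cfg$metrics_every == 0L)
      met <- eval_metrics(psi, reference)
    rows[[m]] <- record_row(m, ls$cost, step_norm, ls$gamma, ls$shrinks,
                            met$ssim, met$psnr)
    grad_prev <- g; eta_prev <- eta; cost_prev <- ls$cost
    m_done <- m
    if (cfg$stop_tol > 0) {
      rel <- step_norm / max(sqrt(sum(Mod(psi)^2)), .Machine$double.xmin)
      quiet <- if (rel < cfg$stop_tol) quiet + 1L else 0L
      if (quiet >= cfg$stop_patience) break
    }
  }
  record <- do.call(rbind, rows[seq_len(m_done)])
  if (!is.null(reference) && (cfg$metrics_every == 0L ||
                              is.na(record$ssim[m_done]))) {
    met <- eval_metrics(psi, reference)
    record$ssim[m_done] <- met$ssim; record$psnr[m_done] <- met$psnr
  }
  structure(list(object = psi, record = record, config = cfg),
            class = "pty_result")
}

#' Plain gradient-descent reconstruction (comparison solver)
#'
#' `psi_{m+1} = psi_m - gamma * grad F(psi_m)` with a constant small step.
#' Converges more slowly than the conjugate-gradient solver; provided for
#' comparison.
#'
#' @inheritParams pty_reconstruct
#' @param gamma constant step length, > 0 (or 0 for a frozen iterate).
#' @return A `pty_result`, as [pty_reconstruct()].
#' @export
pty_reconstruct_gd <- function(d, probe = NULL, positions = NULL, shape = NULL,
                               cfg = pty_config(), gamma, reference = NULL,
                               init = NULL) {
  if (inherits(d, "pty_dataset")) {
    probe <- d$probe; positions <- d$positions; shape <- d$shape
    if (is.null(reference)) reference <- d$ground_truth
    d <- d$data
  }
  if (gamma < 0) stop("gd step length must be >= 0")
  probe <- check_probe(probe)
  positions <- pty_check_scan(positions, shape, nrow(probe))
  d <- check_data_stack(d, nrow(probe), nrow(positions))
  psi <- if (is.null(init)) init_object(shape, cfg) else as_complex_matrix(init)
  rows <- vector("list", cfg$n_iters)
  for (m in seq_len(cfg$n_iters)) {
    g <- pty_gradient(psi, d, probe, positions, cfg$eps_guard)
    psi <- psi - gamma * g
    step_norm <- gamma * sqrt(sum(Mod(g)^2))
    met <- list(ssim = NA_real_, psnr = NA_real_)
    if (!is.null(reference) && cfg$metrics_every > 0L &&
        m %% cfg$metrics_every == 0L)
      met <- eval_metrics(psi, reference)
    rows[[m]] <- record_row(m, pty_cost(psi, d, probe, positions, cfg$eps_guard),
                            step_norm, gamma, 0L, met$ssim, met$psnr)
  }
  structure(list(object = psi, record = do.call(rbind, rows), config = cfg),
            class = "pty_result")
}

#' @export
print.pty_result <- function(x, ...) {
  r <- x$record
  cat(sprintf("<pty_result> %d x %d object, %d iterations\n",
              nrow(x$object), ncol(x$object), nrow(r)))
  cat(sprintf("  final cost %.6g, final step 2-norm %.3g\n",
              r$cost[nrow(r)], r$step_norm[nrow(r)]))
  if (!is.na(r$ssim[nrow(r)]))
    cat(sprintf("  final SSIM %.4f, PSNR %.1f dB (phase-aligned amplitude)\n",
                r$ssim[nrow(r)], r$psnr[nrow(r)]))
  invisible(x)
}
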