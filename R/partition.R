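# Partitioned execution of the CG-ML solver over P logical workers.
#
# The object is split into P contiguous strips along its longer axis. Each
# worker owns one strip plus a halo (the strip dilated by the probe side S),
# owns the diffraction patterns whose footprint center falls in its strip,
# and duplicates as halo patterns every pattern whose footprint intersects
# its halo region. Locally each worker stores psi over the footprint closure
# of its pattern set, so every local patch is extractable.
#
# One iteration runs in four stages:
#   GRAD  - each worker computes the ML gradient on its local region
#           (embarrassingly parallel; owned blocks equal the monolithic
#           gradient bitwise because footprints touching an owned strip are
#           all locally present and accumulate in the same order);
#   DIR   - a master worker gathers the owned gradient blocks, forms the
#           complete gradient, evaluates the Dai-Yuan direction exactly as
#           the monolithic solver, and scatters per-worker slices;
#   LS    - each trial step's cost is all-reduced: workers sum the Poisson
#           ML cost over their owned patterns only (each pattern counted
#           once) and the partials are added in ascending worker order;
#   update- psi <- psi + gamma * eta locally, then neighboring workers
#           exchange border strips so halo pixels equal their owners'.
#
# Internally the split axis is always rows: a wider-than-tall object is
# transposed on entry and the stitched result transposed back (the forward
# model commutes with transposition because the 2-D DFT is separable).

#' Partition an object grid and scan set over P workers
#'
#' Splits the object into `P` contiguous strips along its longer axis,
#' assigns every scan pattern an owner by footprint-center containment
#' (half-open strip intervals, so boundary centers go to the higher strip
#' deterministically), and lists halo duplicates by footprint intersection
#' with each strip's halo region (the strip dilated by `S`).
#'
#' @param shape integer `c(H, W)` object size.
#' @param P number of workers (>= 1).
#' @param S probe side in pixels (halo width).
#' @param positions integer `n x 2` scan grid, 0-based.
#' @return list of `P` partitions; each has `worker_id` (0-based), `axis`
#'   (`"row"` or `"col"`), `owned`, `halo`, `local` (half-open 0-based
#'   intervals along the split axis; `local` is the footprint closure
#'   actually stored), `owned_patterns`, `halo_patterns` (1-based pattern
#'   indices), and `neighbors` (worker ids overlapping the local region).
#' @export
pty_partition <- function(shape, P, S, positions) {
  P <- as.integer(P)
  stopifnot(P >= 1L, S >= 1L)
  positions <- pty_check_scan(positions, shape, S)
  axis <- if (shape[1] >= shape[2]) "row" else "col"
  L <- if (axis == "row") shape[1] else shape[2]
  coord <- if (axis == "row") positions[, 1] else positions[, 2]
  bounds <- floor(L * (0:P) / P)
  if (min(diff(bounds)) < S)
    stop(sprintf("infeasible split: %d workers give a strip of %d < S = %d pixels",
                 P, min(diff(bounds)), S))
  centers <- coord + (S - 1) / 2
  owner <- findInterval(centers, bounds, rightmost.closed = TRUE)  # 1..P
  bounds <- as.integer(bounds)
  lapply(seq_len(P), function(k) {
    lo <- bounds[k]; hi <- bounds[k + 1]
    halo <- c(max(lo - S, 0L), min(hi + S, L))
    owned_patterns <- which(owner == k)
    in_halo <- which(coord < halo[2] & coord + S > halo[1])
    halo_patterns <- setdiff(in_halo, owned_patterns)
    local_pat <- sort(c(owned_patterns, halo_patterns))
    local <- if (length(local_pat))
      c(min(halo[1], coord[local_pat]), max(halo[2], max(coord[local_pat]) + S))
    else halo
    local <- c(max(local[1], 0L), min(local[2], L))
    local <- as.integer(local)
    list(worker_id = k - 1L, axis = axis, owned = c(lo, hi), halo = halo,
         local = local, owned_patterns = owned_patterns,
         halo_patterns = halo_patterns, S = S, shape = shape, P = P)
  })
}

# neighbors: workers whose owned strip intersects this worker's local region
partition_neighbors <- function(partitions, k) {
  p <- partitions[[k]]
  ids <- vapply(partitions, function(q) {
    if (q$worker_id == p$worker_id) return(NA_integer_)
    if (q$owned[1] < p$local[2] && q$owned[2] > p$local[1]) q$worker_id
    else NA_integer_
  }, integer(1))
  ids[!is.na(ids)]
}

transpose_dataset <- function(ds) {
  dt <- array(NA_real_, dim(ds$data)[c(2, 1, 3)])
  for (j in seq_len(dim(ds$data)[3])) dt[, , j] <- t(ds$data[, , j])
  pty_dataset(dt, t(ds$probe), ds$positions[, c(2, 1), drop = FALSE],
              rev(ds$shape),
              ground_truth = if (!is.null(ds$ground_truth)) t(ds$ground_truth),
              spec = ds$spec)
}

# Build per-worker state: local psi slab, local pattern subsets with
# positions shifted into local coordinates, owned subsets for reductions.
#' Initialize worker states for a partitioned run
#'
#' @param dataset a `pty_dataset`.
#' @param partitions output of [pty_partition()] for the same geometry
#'   (row-axis partitions; see [pty_reconstruct_partitioned()] for the
#'   transposition handling of wide objects).
#' @param init complex starting object (`H x W`), already initialized.
#' @return list of worker states (`pty_worker`), each holding its local
#'   `psi`, local diffraction patterns and positions, and reduction subsets.
#' @export
pty_workers_init <- function(dataset, partitions, init) {
  lapply(seq_along(partitions), function(k) {
    p <- partitions[[k]]
    stopifnot(p$axis == "row")
    rows <- (p$local[1] + 1L):p$local[2]
    local_pat <- sort(c(p$owned_patterns, p$halo_patterns))
    pos_local <- dataset$positions[local_pat, , drop = FALSE]
    pos_local[, 1] <- pos_local[, 1] - p$local[1]
    owned_in_local <- local_pat %in% p$owned_patterns
    structure(list(
      id = p$worker_id,
      part = p,
      neighbors = partition_neighbors(partitions, k),
      psi = init[rows, , drop = FALSE],
      local_patterns = local_pat,
      pos_local = pos_local,
      d_local = dataset$data[, , local_pat, drop = FALSE],
      pos_owned = pos_local[owned_in_local, , drop = FALSE],
      d_owned = dataset$data[, , local_pat[owned_in_local], drop = FALSE]
    ), class = "pty_worker")
  })
}

#' GRAD stage: local ML gradient on one worker
#'
#' Computes the Poisson ML gradient over the worker's local region using its
#' owned and halo patterns. The restriction to the owned strip equals the
#' corresponding block of the monolithic gradient because every footprint
#' touching the owned strip is locally present and contributions accumulate
#' in the same (ascending pattern index) order.
#'
#' @param worker a worker state from [pty_workers_init()].
#' @param probe complex probe.
#' @param eps_guard clamp as in [pty_gradient()].
#' @return complex matrix over the worker's local region.
#' @export
pty_local_grad_stage <- function(worker, probe, eps_guard = 1e-32) {
  grad_cpp(worker$psi, probe, worker$pos_local, worker$d_local, eps_guard)
}

#' DIR stage: gather partial gradients, compute the Dai-Yuan direction,
#' scatter slices
#'
#' The master assembles the complete gradient by taking each strip from its
#' unique owner, evaluates the Dai-Yuan recursion exactly as
#' [pty_dai_yuan_direction()], and splits the direction into per-worker
#' local-region slices.
#'
#' @param local_grads list of per-worker local gradients (GRAD stage output).
#' @param partitions the partition list.
#' @param shape object shape `c(H, W)` (row-split orientation).
#' @param grad_prev,eta_prev master-retained history from the previous
#'   iteration (`NULL` at the first).
#' @param eps_guard restart threshold, as in [pty_dai_yuan_direction()].
#' @return list with `grad` and `eta` (full `H x W` matrices, master copy)
#'   and `slices` (per-worker local-region slices of `eta`).
#' @export
pty_dir_stage <- function(local_grads, partitions, shape, grad_prev = NULL,
                          eta_prev = NULL, eps_guard = 1e-32) {
  if (length(local_grads) != length(partitions))
    stop("one local gradient per worker is required")
  grad <- matrix(complex(real = 0, imaginary = 0), shape[1], shape[2])
  for (k in seq_along(partitions)) {
    p <- partitions[[k]]
    owned_rows <- (p$owned[1] + 1L):p$owned[2]
    grad[owned_rows, ] <-
      local_grads[[k]][owned_rows - p$local[1], , drop = FALSE]
  }
  eta <- pty_dai_yuan_direction(grad, grad_prev, eta_prev, eps_guard)
  slices <- lapply(partitions, function(p)
    eta[(p$local[1] + 1L):p$local[2], , drop = FALSE])
  list(grad = grad, eta = eta, slices = slices)
}

# Partial Poisson ML cost of one worker over its owned patterns only, at
# trial step gamma along its direction slice.
worker_partial_cost <- function(worker, eta_slice, gamma, probe, eps_guard) {
  psi_try <- if (gamma == 0) worker$psi else worker$psi + gamma * eta_slice
  cost_cpp(psi_try, probe, worker$pos_owned, worker$d_owned, eps_guard)
}

#' LS stage: all-reduce backtracking line search
#'
#' Each trial step, every worker computes the partial ML cost over its owned
#' patterns only (halo duplicates excluded so each pattern is counted
#' exactly once); partials are summed in ascending worker order and the
#' global scalar drives the same shrink loop as [pty_line_search()].
#'
#' @param workers worker-state list.
#' @param eta_slices per-worker direction slices (DIR stage output).
#' @param probe complex probe.
#' @param cfg a [pty_config()].
#' @param cost0 current global cost `F(psi_m)` (all-reduced).
#' @param apply_fun backend apply, `function(X, FUN)`; defaults to `lapply`.
#' @return list with `gamma`, `shrinks`, `cost` (accepted global cost) and
#'   `converged`, as [pty_line_search()].
#' @export
pty_ls_stage <- function(workers, eta_slices, probe, cfg, cost0,
                         apply_fun = lapply) {
  allreduce <- function(gamma) {
    partials <- apply_fun(seq_along(workers), function(k)
      worker_partial_cost(workers[[k]], eta_slices[[k]], gamma, probe,
                          cfg$eps_guard))
    bad <- which(!vapply(partials, is.finite, logical(1)))
    if (length(bad))
      stop(sprintf("non-finite partial cost on worker %d during line search",
                   workers[[bad[1]]]$id))
    tot <- 0
    for (p in partials) tot <- tot + p  # fixed ascending worker order
    tot
  }
  gamma <- cfg$gamma0
  shrinks <- 0L
  repeat {
    cost_try <- allreduce(gamma)
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

#' Update stage with border exchange
#'
#' Each worker updates its local `psi` by `gamma * eta`; afterwards every
#' pixel a worker stores outside its owned strip is overwritten with the
#' owning neighbor's value for the same coordinates, so halo pixels equal
#' their owners' exactly.
#'
#' @inheritParams pty_ls_stage
#' @param gamma the agreed global step.
#' @return the updated worker-state list.
#' @export
pty_update_exchange <- function(workers, eta_slices, gamma) {
  for (k in seq_along(workers))
    workers[[k]]$psi <- workers[[k]]$psi + gamma * eta_slices[[k]]
  ids <- vapply(workers, `[[`, integer(1), "id")
  for (k in seq_along(workers)) {
    w <- workers[[k]]
    for (nb in w$neighbors) {
      at <- which(ids == nb)
      if (length(at) != 1L)
        stop(sprintf("neighbor link %d of worker %d is missing", nb, w$id))
      v <- workers[[at]]
      lo <- max(w$part$local[1], v$part$owned[1])
      hi <- min(w$part$local[2], v$part$owned[2])
      if (hi <= lo) next
      workers[[k]]$psi[((lo + 1L):hi) - w$part$local[1], ] <-
        v$psi[((lo + 1L):hi) - v$part$local[1], , drop = FALSE]
    }
  }
  workers
}

# all-reduce of the current global cost F(psi): per-worker owned-pattern
# partials summed in ascending worker order
global_cost <- function(workers, probe, eps_guard, apply_fun = lapply) {
  partials <- apply_fun(seq_along(workers), function(k)
    worker_partial_cost(workers[[k]], 0, 0, probe, eps_guard))
  tot <- 0
  for (p in partials) tot <- tot + p
  tot
}

#' Stitch worker strips into the full object
#'
#' Concatenates the owned strips (halos discarded); owned strips tile the
#' grid so no blending is involved.
#'
#' @param workers worker-state list.
#' @param shape object shape `c(H, W)` (row-split orientation).
#' @return complex `H x W` matrix.
#' @export
pty_stitch <- function(workers, shape) {
  out <- matrix(complex(real = NA_real_), shape[1], shape[2])
  for (w in workers) {
    rows <- (w$part$owned[1] + 1L):w$part$owned[2]
    out[rows, ] <- w$psi[rows - w$part$local[1], , drop = FALSE]
  }
  if (anyNA(out)) stop("coverage gap: owned strips do not tile the object")
  out
}

make_backend <- function(backend, P) {
  switch(backend,
    serial = lapply,
    process = function(X, FUN) {
      cores <- max(1L, min(P, parallel::detectCores()))
      parallel::mclapply(X, FUN, mc.cores = cores)
    },
    device = stop("the 'device' backend is not available in this build; use 'serial' or 'process'"),
    stop(sprintf("unknown backend '%s'", backend)))
}

#' Partitioned CG-ML reconstruction
#'
#' Runs the four-stage iteration (GRAD, gather-scatter DIR, all-reduce LS,
#' update with border exchange) over `P` logical workers. Produces the same
#' iterate sequence as [pty_reconstruct()] up to floating-point
#' reassociation in the cost reduction; the `ConvergenceRecord` semantics
#' are identical. Worker 0 acts as the master for the DIR stage.
#'
#' @inheritParams pty_reconstruct
#' @param P number of logical workers.
#' @param backend `"serial"` (in-process loop, bitwise deterministic) or
#'   `"process"` (forked worker pool for the GRAD and LS stages).
#' @return A `pty_result`, as [pty_reconstruct()], with the partition list
#'   attached as `$partitions`.
#' @export
pty_reconstruct_partitioned <- function(d, probe = NULL, positions = NULL,
                                        shape = NULL, P = 2L,
                                        cfg = pty_config(),
                                        backend = c("serial", "process", "device"),
                                        reference = NULL, init = NULL) {
  backend <- match.arg(backend)
  if (!inherits(d, "pty_dataset"))
    d <- pty_dataset(d, probe, positions, shape, ground_truth = reference)
  if (is.null(reference)) reference <- d$ground_truth

  transposed <- d$shape[2] > d$shape[1]
  if (transposed) {
    d <- transpose_dataset(d)
    if (!is.null(reference)) reference <- t(reference)
    if (!is.null(init)) init <- t(init)
  }
  partitions <- pty_partition(d$shape, P, nrow(d$probe), d$positions)
  psi0 <- if (is.null(init)) init_object(d$shape, cfg) else as_complex_matrix(init)
  workers <- pty_workers_init(d, partitions, psi0)
  apply_fun <- make_backend(backend, P)

  grad_prev <- NULL; eta_prev <- NULL
  rows <- vector("list", cfg$n_iters)
  cost_prev <- global_cost(workers, d$probe, cfg$eps_guard, apply_fun)
  quiet <- 0L; m_done <- 0L
  for (m in seq_len(cfg$n_iters)) {
    stage <- "GRAD"
    res <- tryCatch({
      local_grads <- apply_fun(seq_along(workers), function(k)
        pty_local_grad_stage(workers[[k]], d$probe, cfg$eps_guard))
      stage <- "DIR"
      dir <- pty_dir_stage(local_grads, partitions, d$shape, grad_prev,
                           eta_prev, cfg$eps_guard)
      stage <- "LS"
      ls <- pty_ls_stage(workers, dir$slices, d$probe, cfg, cost0 = cost_prev,
                         apply_fun = apply_fun)
      stage <- "update"
      list(dir = dir, ls = ls,
           workers = pty_update_exchange(workers, dir$slices, ls$gamma))
    }, error = function(e)
      stop(sprintf("iteration %d, stage %s: %s", m, stage, conditionMessage(e)),
           call. = FALSE))
    dir <- res$dir; ls <- res$ls; workers <- res$workers
    step_norm <- ls$gamma * sqrt(sum(Mod(dir$eta)^2))
    met <- list(ssim = NA_real_, psnr = NA_real_)
    if (!is.null(reference) && cfg$metrics_every > 0L &&
        m %% cfg$metrics_every == 0L)
      met <- eval_metrics(pty_stitch(workers, d$shape), reference)
    rows[[m]] <- record_row(m, ls$cost, step_norm, ls$gamma, ls$shrinks,
                            met$ssim, met$psnr)
    grad_prev <- dir$grad; eta_prev <- dir$eta; cost_prev <- ls$cost
    m_done <- m
    if (cfg$stop_tol > 0) {
      psi_norm <- sqrt(sum(vapply(workers, function(w) {
        rows_o <- (w$part$owned[1] + 1L):w$part$owned[2]
        sum(Mod(w$psi[rows_o - w$part$local[1], , drop = FALSE])^2)
      }, numeric(1))))
      rel <- step_norm / max(psi_norm, .Machine$double.xmin)
      quiet <- if (rel < cfg$stop_tol) quiet + 1L else 0L
      if (quiet >= cfg$stop_patience) break
    }
  }
  psi <- pty_stitch(workers, d$shape)
  record <- do.call(rbind, rows[seq_len(m_done)])
  if (!is.null(reference) && (cfg$metrics_every == 0L ||
                              is.na(record$ssim[m_done]))) {
    met <- eval_metrics(psi, reference)
    record$ssim[m_done] <- met$ssim; record$psnr[m_done] <- met$psnr
  }
  if (transposed) psi <- t(psi)
  structure(list(object = psi, record = record, config = cfg,
                 partitions = partitions, P = P, backend = backend),
            class = "pty_result")
}
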