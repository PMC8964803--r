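# Partitioned four-stage solver: partition geometry, stage-by-stage
# agreement with the monolithic solver, and end-to-end equivalence.

test_that("owned strips tile the grid and every pattern has exactly one owner", {
  for (seed in 1:6) {
    set.seed(500 + seed)
    H <- sample(c(48, 64, 96), 1); W <- sample(c(48, 64), 1)
    S <- 8L; P <- sample(2:4, 1)
    scan <- pty_scan(H, W, S, step = 4, jitter = 1, seed = seed)
    parts <- pty_partition(c(H, W), P, S, scan)
    axis_len <- if (parts[[1]]$axis == "row") H else W
    owned <- do.call(rbind, lapply(parts, `[[`, "owned"))
    expect_equal(owned[1, 1], 0L)
    expect_equal(owned[P, 2], axis_len)
    if (P > 1) expect_equal(owned[-1, 1], owned[-P, 2])  # disjoint, covering
    owners <- unlist(lapply(parts, `[[`, "owned_patterns"))
    expect_equal(sort(owners), seq_len(nrow(scan)))     # single counting
  }
})

test_that("halo membership equals brute-force footprint intersection with the dilated strip", {
  H <- 64L; W <- 32L; S <- 8L
  scan <- pty_scan(H, W, S, step = 4, jitter = 1, seed = 9)
  parts <- pty_partition(c(H, W), 2L, S, scan)
  coord <- scan[, 1]  # row split
  for (p in parts) {
    in_halo <- which(coord < p$halo[2] & coord + S > p$halo[1])
    expect_setequal(c(p$owned_patterns, p$halo_patterns), in_halo)
    expect_length(intersect(p$owned_patterns, p$halo_patterns), 0)
  }
  # infeasible split: strip narrower than the probe
  expect_error(pty_partition(c(H, W), 16L, S, scan), "infeasible")
})

test_that("single-worker partition is degenerate: all owned, halo empty, stitch is identity", {
  ds <- star_dataset(size = 64, S = 16, step = 8, seed = 2)
  parts <- pty_partition(ds$shape, 1L, 16L, ds$positions)
  expect_length(parts, 1)
  expect_length(parts[[1]]$halo_patterns, 0)
  expect_equal(sort(parts[[1]]$owned_patterns), seq_len(nrow(ds$positions)))
  workers <- pty_workers_init(ds, parts, ds$ground_truth)
  expect_equal(pty_stitch(workers, ds$shape), ds$ground_truth)
})

test_that("local gradients agree with the monolithic gradient on owned strips", {
  ds <- star_dataset(size = 64, S = 16, step = 6, seed = 4)
  set.seed(61)
  psi <- rcmat(64, 64)
  g_mono <- pty_gradient(psi, ds$data, ds$probe, ds$positions)
  for (P in c(2L, 4L)) {
    parts <- pty_partition(ds$shape, P, 16L, ds$positions)
    workers <- pty_workers_init(ds, parts, psi)
    for (k in seq_len(P)) {
      gl <- pty_local_grad_stage(workers[[k]], ds$probe)
      p <- parts[[k]]
      rows <- (p$owned[1] + 1L):p$owned[2]
      expect_identical(gl[rows - p$local[1], ], g_mono[rows, ])  # bitwise
    }
  }
})

test_that("dropping a halo pattern that touches the owned strip breaks gradient agreement", {
  ds <- star_dataset(size = 64, S = 16, step = 6, seed = 4)
  set.seed(62)
  psi <- rcmat(64, 64)
  g_mono <- pty_gradient(psi, ds$data, ds$probe, ds$positions)
  parts <- pty_partition(ds$shape, 2L, 16L, ds$positions)
  p <- parts[[2]]
  coord <- ds$positions[, 1]
  # the pattern must reach the owned strip through the probe's nonzero rows,
  # not just its nominal footprint (the disk probe is zero near the edge)
  sup <- range(which(rowSums(Mod(ds$probe)) > 0)) - 1L
  touching <- p$halo_patterns[coord[p$halo_patterns] + sup[2] >= p$owned[1] &
                              coord[p$halo_patterns] + sup[1] < p$owned[2]]
  expect_gt(length(touching), 0)
  p_broken <- p
  p_broken$halo_patterns <- setdiff(p$halo_patterns, touching[1])
  workers <- pty_workers_init(ds, list(parts[[1]], p_broken), psi)
  gl <- pty_local_grad_stage(workers[[2]], ds$probe)
  rows <- (p$owned[1] + 1L):p$owned[2]
  expect_gt(max(Mod(gl[rows - p$local[1], ] - g_mono[rows, ])), 1e-8)
})

test_that("DIR stage assembles the exact gradient and reproduces the monolithic direction", {
  ds <- star_dataset(size = 64, S = 16, step = 6, seed = 5)
  set.seed(63)
  psi <- rcmat(64, 64)
  g_mono <- pty_gradient(psi, ds$data, ds$probe, ds$positions)
  parts <- pty_partition(ds$shape, 4L, 16L, ds$positions)
  workers <- pty_workers_init(ds, parts, psi)
  grads <- lapply(workers, pty_local_grad_stage, probe = ds$probe)
  dir0 <- pty_dir_stage(grads, parts, ds$shape)
  expect_identical(dir0$grad, g_mono)            # blockwise bitwise assembly
  expect_identical(dir0$eta, -g_mono)            # iteration 0: steepest descent
  for (k in seq_len(4)) {
    p <- parts[[k]]
    expect_identical(dir0$slices[[k]], dir0$eta[(p$local[1] + 1L):p$local[2], ])
  }
  # with history: identical to the monolithic Dai-Yuan update
  set.seed(64)
  g_prev <- rcmat(64, 64); eta_prev <- rcmat(64, 64)
  dir1 <- pty_dir_stage(grads, parts, ds$shape, g_prev, eta_prev)
  expect_equal(dir1$eta, pty_dai_yuan_direction(g_mono, g_prev, eta_prev),
               tolerance = 1e-12)
})

test_that("all-reduce partial costs sum to the monolithic cost and the line search agrees", {
  ds <- star_dataset(size = 64, S = 16, step = 6, seed = 6)
  set.seed(65)
  psi <- rcmat(64, 64)
  cfg <- pty_config()
  mono_cost <- pty_cost(psi, ds$data, ds$probe, ds$positions)
  parts <- pty_partition(ds$shape, 3L, 16L, ds$positions)
  workers <- pty_workers_init(ds, parts, psi)
  zero_slices <- lapply(workers, function(w) 0)
  ls0 <- pty_ls_stage(workers, zero_slices, ds$probe, cfg, cost0 = mono_cost)
  expect_equal(ls0$gamma, cfg$gamma0)   # zero direction: first trial accepted
  expect_equal(ls0$shrinks, 0L)
  expect_lt(abs(ls0$cost - mono_cost) / abs(mono_cost), 1e-12)

  # a real direction: same gamma and shrink count as the monolithic search
  grads <- lapply(workers, pty_local_grad_stage, probe = ds$probe)
  dir0 <- pty_dir_stage(grads, parts, ds$shape)
  ls_mono <- pty_line_search(psi, dir0$eta, ds$data, ds$probe, ds$positions, cfg)
  ls_part <- pty_ls_stage(workers, dir0$slices, ds$probe, cfg, cost0 = mono_cost)
  expect_equal(ls_part$gamma, ls_mono$gamma)
  expect_equal(ls_part$shrinks, ls_mono$shrinks)
  expect_lt(abs(ls_part$cost - ls_mono$cost) / abs(ls_mono$cost), 1e-12)
})

test_that("after update and exchange, halo pixels equal their owners bitwise", {
  ds <- star_dataset(size = 64, S = 16, step = 6, seed = 7)
  parts <- pty_partition(ds$shape, 4L, 16L, ds$positions)
  workers <- pty_workers_init(ds, parts, matrix(1 + 0i, 64, 64))
  grads <- lapply(workers, pty_local_grad_stage, probe = ds$probe)
  dir0 <- pty_dir_stage(grads, parts, ds$shape)
  workers <- pty_update_exchange(workers, dir0$slices, 0.03)
  full <- pty_stitch(workers, ds$shape)
  for (w in workers) {
    rows <- (w$part$local[1] + 1L):w$part$local[2]
    expect_identical(w$psi, full[rows, ])   # every stored pixel == owner's
  }
})

test_that("partitioned runs match the monolithic solver and are deterministic", {
  ds <- star_dataset(size = 64, S = 16, step = 6, seed = 8)
  cfg <- pty_config(n_iters = 12, metrics_every = 0)
  mono <- pty_reconstruct(ds, cfg = cfg)
  for (P in c(2L, 4L)) {
    part <- pty_reconstruct_partitioned(ds, P = P, cfg = cfg)
    expect_lt(max(abs(part$record$cost - mono$record$cost) /
                  abs(mono$record$cost)), 1e-10)
    expect_lt(max(Mod(part$object - mono$object)) / max(Mod(mono$object)),
              1e-10)
  }
  # degenerate P = 1 reduces to the monolithic solver almost exactly
  p1 <- pty_reconstruct_partitioned(ds, P = 1L, cfg = cfg)
  expect_lt(max(abs(p1$record$cost - mono$record$cost) /
                abs(mono$record$cost)), 1e-12)
  # serial backend: bitwise determinism
  r1 <- pty_reconstruct_partitioned(ds, P = 2L, cfg = cfg)
  r2 <- pty_reconstruct_partitioned(ds, P = 2L, cfg = cfg)
  expect_identical(r1$object, r2$object)
  expect_identical(r1$record, r2$record)
})

test_that("wide objects are split along columns and still match the monolithic solver", {
  obj <- pty_star(64)[1:32 + 16, ]     # 32 x 64: wider than tall
  probe <- pty_probe(8, "gaussian")
  scan <- pty_scan(32, 64, 8, step = 4, jitter = 1, seed = 12)
  ds <- pty_simulate(obj, probe, scan)
  parts <- pty_partition(ds$shape, 2L, 8L, ds$positions)
  expect_equal(parts[[1]]$axis, "col")
  cfg <- pty_config(n_iters = 8, metrics_every = 0)
  mono <- pty_reconstruct(ds, cfg = cfg)
  part <- pty_reconstruct_partitioned(ds, P = 2L, cfg = cfg)
  expect_lt(max(Mod(part$object - mono$object)) / max(Mod(mono$object)), 1e-6)
})

test_that("the process backend reproduces the serial backend", {
  ds <- star_dataset(size = 64, S = 16, step = 8, seed = 10)
  cfg <- pty_config(n_iters = 3, metrics_every = 0)
  serial <- pty_reconstruct_partitioned(ds, P = 2L, cfg = cfg, backend = "serial")
  proc <- pty_reconstruct_partitioned(ds, P = 2L, cfg = cfg, backend = "process")
  expect_equal(proc$object, serial$object, tolerance = 1e-12)
  expect_error(pty_reconstruct_partitioned(ds, P = 2L, cfg = cfg,
                                           backend = "device"),
               "not available")
})
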