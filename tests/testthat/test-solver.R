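# Poisson ML cost/gradient, Dai-Yuan directions, line search, and the
# monolithic CG/GD reconstruction loops.

test_that("cost matches a scalar-loop oracle and handles zero counts", {
  ins <- tiny_instance(7, H = 6, W = 6, S = 2, n = 2)
  expect_equal(pty_cost(ins$obj, ins$d, ins$probe, ins$positions),
               oracle_cost(ins$obj, ins$d, ins$probe, ins$positions),
               tolerance = 1e-12)

  # d = 0: only the intensity term survives
  d0 <- array(0, dim(ins$d))
  w <- pty_forward(ins$obj, ins$probe, ins$positions)
  expect_equal(pty_cost(ins$obj, d0, ins$probe, ins$positions),
               sum(Mod(w)^2), tolerance = 1e-12)

  # at a noise-free-consistent object the cost is sum(d - d log d)
  d_true <- pty_intensities(w)
  expect_true(all(d_true > 0))
  expect_equal(pty_cost(ins$obj, d_true, ins$probe, ins$positions),
               sum(d_true - d_true * log(d_true)), tolerance = 1e-10)

  expect_error(pty_cost(ins$obj, -ins$d, ins$probe, ins$positions),
               "non-negative")
})

test_that("gradient vanishes at noise-free data and reduces to G^H G psi when d = 0", {
  ins <- tiny_instance(8)
  d_true <- pty_intensities(pty_forward(ins$obj, ins$probe, ins$positions))
  g <- pty_gradient(ins$obj, d_true, ins$probe, ins$positions)
  ghg <- pty_adjoint(pty_forward(ins$obj, ins$probe, ins$positions),
                     ins$probe, ins$positions, ins$shape)
  expect_lt(sqrt(sum(Mod(g)^2)), 1e-8 * sqrt(sum(Mod(ghg)^2)))

  d0 <- array(0, dim(ins$d))
  expect_equal(pty_gradient(ins$obj, d0, ins$probe, ins$positions), ghg,
               tolerance = 1e-12)
})

test_that("gradient matches central finite differences of the cost along random directions", {
  eps <- 1e-6
  for (seed in 1:22) {
    ins <- tiny_instance(300 + seed, H = 7, W = 9, S = 3, n = 4)
    set.seed(400 + seed)
    eta <- rcmat(7, 9)
    g <- pty_gradient(ins$obj, ins$d, ins$probe, ins$positions)
    fp <- pty_cost(ins$obj + eps * eta, ins$d, ins$probe, ins$positions)
    fm <- pty_cost(ins$obj - eps * eta, ins$d, ins$probe, ins$positions)
    fd <- (fp - fm) / (2 * eps)
    an <- 2 * Re(cip(g, eta))
    expect_lt(abs(fd - an) / max(abs(an), 1e-12), 1e-4)
  }
})

test_that("Dai-Yuan direction follows the recursion and its degenerate branches", {
  # hand-computed 2-vector case: alpha = 1, direction = (-1, -1)
  g_m <- matrix(c(1 + 0i, 0 + 0i), 1, 2)
  g_prev <- matrix(c(0 + 0i, 1 + 0i), 1, 2)
  eta_prev <- matrix(c(0 + 0i, -1 + 0i), 1, 2)
  expect_equal(pty_dai_yuan_direction(g_m, g_prev, eta_prev),
               matrix(c(-1 + 0i, -1 + 0i), 1, 2))

  # first iteration: steepest descent
  expect_equal(pty_dai_yuan_direction(g_m), -g_m)
  # zero gradient: zero direction regardless of history
  z <- matrix(0 + 0i, 1, 2)
  expect_equal(pty_dai_yuan_direction(z, g_prev, eta_prev), z)
  # vanishing denominator: restart to steepest descent
  expect_equal(pty_dai_yuan_direction(g_m, g_m, eta_prev), -g_m)
  # recursion agrees with a direct evaluation on random grids
  set.seed(5)
  a <- rcmat(4, 4); b <- rcmat(4, 4); e <- rcmat(4, 4)
  alpha <- sum(Mod(a)^2) / Re(cip(e, a - b))
  expect_equal(pty_dai_yuan_direction(a, b, e), -a + alpha * e,
               tolerance = 1e-12)
})

test_that("backtracking line search accepts, shrinks, and matches a brute-force scan", {
  ins <- tiny_instance(9)
  cfg <- pty_config(gamma0 = 1, shrink = 0.5, max_ls_steps = 32)

  # zero direction: accepted immediately at gamma0 (t = 0, cost unchanged)
  z <- matrix(0 + 0i, ins$shape[1], ins$shape[2])
  ls <- pty_line_search(ins$obj, z, ins$d, ins$probe, ins$positions, cfg)
  expect_equal(ls$gamma, cfg$gamma0)
  expect_equal(ls$shrinks, 0L)

  # a genuine descent direction small enough to be accepted first try
  g <- pty_gradient(ins$obj, ins$d, ins$probe, ins$positions)
  eta <- -1e-6 * g
  ls <- pty_line_search(ins$obj, eta, ins$d, ins$probe, ins$positions, cfg)
  expect_equal(ls$shrinks, 0L)
  expect_equal(ls$gamma, cfg$gamma0)
  expect_gt(ls$gamma, 0)

  # 1x1 object (cost gamma -> |2 - gamma|^2 - 2 log|2 - gamma| computable in
  # closed form): shrink count must match an exhaustive scan over the
  # geometric step sequence
  cfg1 <- pty_config(gamma0 = 2.2, shrink = 0.5, max_ls_steps = 32)
  obj1 <- matrix(2 + 0i, 1, 1); probe1 <- matrix(1 + 0i, 1, 1)
  pos1 <- cbind(0L, 0L); d1 <- array(1, c(1, 1, 1))
  eta1 <- matrix(-1 + 0i, 1, 1)
  cost1 <- function(psi) Mod(psi)^2 - 2 * d1[1] * log(Mod(psi))
  f0 <- cost1(obj1[1])
  gammas <- cfg1$gamma0 * cfg1$shrink^(0:cfg1$max_ls_steps)
  expected_shrinks <- which(sapply(gammas, function(gm)
    cost1(obj1[1] + gm * eta1[1]) <= f0))[1] - 1L
  expect_gt(expected_shrinks, 0L)  # the first trial really is rejected
  ls <- pty_line_search(obj1, eta1, d1, probe1, pos1, cfg1)
  expect_equal(ls$shrinks, expected_shrinks)
  expect_equal(ls$gamma, cfg1$gamma0 * cfg1$shrink^expected_shrinks)
})

test_that("CG reconstruction is a fixed point at ground truth and decreases cost monotonically", {
  ds <- star_dataset(size = 96, S = 32, step = 8, seed = 13)
  cfg <- pty_config(n_iters = 8, metrics_every = 0)

  at_truth <- pty_reconstruct(ds, cfg = cfg, init = ds$ground_truth)
  expect_equal(at_truth$object, ds$ground_truth, tolerance = 1e-12)
  expect_true(all(at_truth$record$step_norm < 1e-10))

  res <- pty_reconstruct(ds, cfg = pty_config(n_iters = 15, metrics_every = 0))
  expect_true(all(res$record$ls_shrinks < res$config$max_ls_steps))
  expect_true(all(diff(res$record$cost) <= 0))
})

test_that("seeded runs are bitwise reproducible", {
  ds <- star_dataset(size = 96, S = 32, step = 8, seed = 13)
  cfg <- pty_config(n_iters = 5, init_mode = "random", seed = 77,
                    metrics_every = 0)
  r1 <- pty_reconstruct(ds, cfg = cfg)
  r2 <- pty_reconstruct(ds, cfg = cfg)
  expect_identical(r1$object, r2$object)
  expect_identical(r1$record, r2$record)
})

test_that("gradient descent with zero step or at ground truth stays put, and CG converges no slower", {
  ds <- star_dataset(size = 96, S = 32, step = 8, seed = 13)
  cfg <- pty_config(n_iters = 5, metrics_every = 0)
  frozen <- pty_reconstruct_gd(ds, cfg = cfg, gamma = 0)
  expect_equal(frozen$object,
               matrix(1 + 0i, ds$shape[1], ds$shape[2]))
  at_truth <- pty_reconstruct_gd(ds, cfg = cfg, gamma = 0.01,
                                 init = ds$ground_truth)
  expect_equal(at_truth$object, ds$ground_truth, tolerance = 1e-10)

  cfg2 <- pty_config(n_iters = 20, metrics_every = 0)
  cg <- pty_reconstruct(ds, cfg = cfg2)
  gd <- pty_reconstruct_gd(ds, cfg = cfg2, gamma = 0.02)
  target <- gd$record$cost[20]
  iters_cg <- which(cg$record$cost <= target)[1]
  expect_lte(iters_cg, 20)
})
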