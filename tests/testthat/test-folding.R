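# Off-lattice folding model: potentials, gradients, Brownian dynamics,
# RMSD superposition, native ensembles and folding probabilities.

cfg0 <- physics_config()

test_that("pair potential has the stated asymptotics and minimum", {
  # H-H: attractive tail, approaches 0 from below
  expect_lt(pair_potential(3, "H", "H", cfg0), 0)
  expect_gt(pair_potential(3, "H", "H", cfg0), -0.01)
  # like charges: screened repulsion, approaches 0 from above
  expect_gt(pair_potential(3, "+", "+", cfg0), 0)
  # uncharged attractive pair: LJ minimum -B^2/(4A) at r = (2A/B)^(1/6)
  A <- cfg0$lj_A["P", "P"]; B <- cfg0$lj_B["P", "P"]
  rmin <- (2 * A / B)^(1 / 6)
  expect_equal(pair_potential(rmin, "P", "P", cfg0), -B^2 / (4 * A),
               tolerance = 1e-12)
  h <- 1e-5
  expect_lt(abs(pair_potential(rmin + h, "P", "P", cfg0) -
                  pair_potential(rmin - h, "P", "P", cfg0)) / (2 * h), 1e-3)
  expect_error(pair_potential(0, "H", "H", cfg0), "positive")
})

test_that("physics_config enforces the qualitative interaction orderings", {
  badB <- matrix(1, 4, 4, dimnames = list(c("H", "P", "+", "-"),
                                          c("H", "P", "+", "-")))
  expect_error(physics_config(lj_B = badB), "H-H attraction")
  badB["H", "H"] <- 2; badB["H", "P"] <- 0.5
  expect_error(physics_config(lj_B = badB), "symmetric")
})

test_that("chain energy: springs vanish at rest length, pairs accounted", {
  # 3 collinear P monomers at exact rest length: only the (1,3) LJ pair
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  e <- chain_energy(X, "PPP", cfg0)
  expect_equal(e, pair_potential(2, "P", "P", cfg0), tolerance = 1e-12)
  expect_error(chain_energy(X, "PP", cfg0), "match")
})

test_that("energy and RMSD are invariant under rigid motions", {
  set.seed(191)
  for (rep in 1:5) {
    X <- init_conformation(7, cfg0)
    s <- "+HPHPH-"
    R <- random_rotation()
    Y <- X %*% t(R) + matrix(stats::rnorm(3), 7, 3, byrow = TRUE)
    expect_equal(chain_energy(Y, s, cfg0), chain_energy(X, s, cfg0),
                 tolerance = 1e-10)
    expect_lt(rmsd(X, Y), 1e-10)
  }
  Z <- init_conformation(5, cfg0)
  expect_equal(rmsd(Z, Z), 0, tolerance = 1e-12)
})

test_that("analytic gradient matches finite differences", {
  set.seed(201)
  for (s in c("+HPHH-", "+P+-PH-", "HHHH")) {
    n <- nchar(s)
    X <- init_conformation(n, cfg0) * 1.1  # off rest length
    g <- chain_gradient(X, s, cfg0)
    fd <- matrix(0, n, 3)
    h <- 1e-6
    for (i in seq_len(n)) for (k in 1:3) {
      Xp <- X; Xm <- X
      Xp[i, k] <- Xp[i, k] + h; Xm[i, k] <- Xm[i, k] - h
      fd[i, k] <- (chain_energy(Xp, s, cfg0) - chain_energy(Xm, s, cfg0)) /
        (2 * h)
    }
    expect_lt(max(abs(g - fd)) / max(abs(g)), 1e-6)
  }
})

test_that("zero-temperature dynamics descend the energy surface", {
  # dimer at rest length: zero gradient, zero noise -> fixed point
  X <- rbind(c(0, 0, 0), c(cfg0$rest_length, 0, 0))
  X1 <- brownian_step(X, "PP", cfg0, temperature = 0)
  expect_equal(X1, X, tolerance = 1e-12)
  # perturbed chain: energy strictly decreases per T = 0 step
  set.seed(211)
  Y <- init_conformation(6, cfg0) * 1.15
  s <- "+HHHH-"
  for (step in 1:20) {
    Y2 <- brownian_step(Y, s, cfg0, temperature = 0)
    expect_lt(chain_energy(Y2, s, cfg0), chain_energy(Y, s, cfg0))
    Y <- Y2
  }
})

test_that("centre-of-mass diffusion follows the 2 T dt law", {
  # for a dimer, spring forces are internal: the centre of mass diffuses
  # freely with per-coordinate variance (noise_coeff * T * dt / 2) per step
  set.seed(221)
  Tn <- 0.4; nsteps <- 40; nrep <- 300
  disp <- replicate(nrep, {
    X <- rbind(c(0, 0, 0), c(cfg0$rest_length, 0, 0))
    com0 <- colMeans(X)
    for (i in seq_len(nsteps))
      X <- brownian_step(X, "PP", cfg0, temperature = Tn)
    colMeans(X) - com0
  })
  v <- mean(disp^2)  # pooled over 3 coordinates x nrep
  expected <- cfg0$noise_coeff * Tn * cfg0$dt / 2 * nsteps
  se <- stats::sd(as.vector(disp^2)) / sqrt(length(disp))
  expect_lt(abs(v - expected), 4 * se)
})

test_that("harmonic dimer bond length equilibrates to variance 1/k", {
  # stationary density ~ exp(-E/T): bond length fluctuations have variance
  # approximately T / (spring_k * T) = 1/spring_k for a stiff spring
  set.seed(231)
  X <- rbind(c(0, 0, 0), c(cfg0$rest_length, 0, 0))
  r <- numeric(4000)
  for (i in seq_along(r)) {
    for (k in 1:5) X <- brownian_step(X, "PP", cfg0)
    r[i] <- sqrt(sum((X[2, ] - X[1, ])^2))
  }
  expect_lt(abs(stats::var(r) - 1 / cfg0$spring_k) / (1 / cfg0$spring_k),
            0.25)
})

test_that("RMSD superposition matches an optimisation oracle", {
  set.seed(241)
  P <- matrix(stats::rnorm(12), 4, 3)
  Q <- matrix(stats::rnorm(12), 4, 3)
  direct <- rmsd(P, Q)
  # oracle: brute-force minimisation over Euler angles + translation
  obj <- function(par) {
    ca <- cos(par[1]); sa <- sin(par[1])
    cb <- cos(par[2]); sb <- sin(par[2])
    cc <- cos(par[3]); sc <- sin(par[3])
    Rz <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cc, -sc, 0, sc, cc), 3, 3, byrow = TRUE)
    M <- P %*% t(Rz %*% Ry %*% Rx)
    M <- sweep(M, 2, par[4:6], "+")
    sqrt(mean(rowSums((M - Q)^2)))
  }
  best <- Inf
  for (i in 1:30) {
    fit <- stats::optim(c(stats::runif(3, -pi, pi), stats::rnorm(3)), obj,
                        method = "BFGS")
    best <- min(best, fit$value)
  }
  expect_equal(direct, best, tolerance = 1e-5)
  expect_lte(direct, best + 1e-8)  # Kabsch is the true optimum
  expect_error(rmsd(P, Q[1:3, ]), "same number")
})

test_that("native ensemble recovers a planted majority cluster", {
  set.seed(251)
  baseA <- init_conformation(6, cfg0)
  # scaling separates shapes in RMSD terms (translation would not: the
  # superposition quotients it out)
  baseB <- baseA * 3
  confs <- c(jittered_cluster(baseA, 7), jittered_cluster(baseB, 3))
  ens <- build_native_ensemble("+HHHH-", 10, cfg0,
                               quench_fun = make_planted_quencher(confs))
  expect_length(ens$members, 7L)
  expect_true(all(vapply(ens$members, function(m) rmsd(m, baseA) < 0.1,
                         logical(1))))
  expect_gt(ens$threshold, 0)
  # clustering is invariant under input order
  set.seed(252)
  perm <- sample(10)
  ens2 <- build_native_ensemble("+HHHH-", 10, cfg0,
                                quench_fun = make_planted_quencher(confs[perm]))
  expect_length(ens2$members, 7L)
})

test_that("degenerate ensembles and memberships are handled", {
  base <- init_conformation(5, cfg0)
  same <- lapply(1:4, function(i) base)
  ens <- build_native_ensemble("+HHH-", 4, cfg0,
                               quench_fun = make_planted_quencher(same))
  expect_length(ens$members, 4L)
  expect_equal(ens$threshold, 0)       # median = MAD = 0
  expect_true(in_native_ensemble(ens, base))  # non-strict membership
  # all-singleton case errors (scale separation; translations would not do)
  apart <- lapply(1:4, function(i) base * 2^i)
  expect_error(build_native_ensemble("+HHH-", 4, cfg0,
                                     make_planted_quencher(apart)),
               "singleton")
})

test_that("folding probability counts ensemble membership exactly", {
  set.seed(261)
  baseA <- init_conformation(6, cfg0)
  baseB <- baseA * 3
  ens <- build_native_ensemble(
    "+HHHH-", 8, cfg0,
    quench_fun = make_planted_quencher(jittered_cluster(baseA, 8)))
  # 10 fresh samples: 3 in-basin, 7 far away -> P = 0.3 exactly
  fresh <- c(jittered_cluster(baseA, 3), jittered_cluster(baseB, 7))
  p <- folding_probability("+HHHH-", ens, 10, cfg0,
                           quench_fun = make_planted_quencher(fresh))
  expect_equal(p, 0.3)
})

test_that("real quenches: hydrophobic chains collapse, repulsive chains do not", {
  set.seed(271)
  fast <- physics_config(equil_steps = 300, quench_steps = 800)
  qh <- quench("+HHHHHH-", fast)
  expect_true(qh$converged)
  # all-P chain with purely repulsive non-bonded interactions stays
  # extended (H-H attraction stays strongest so the config validates)
  B <- fast$lj_B
  B["P", "P"] <- -0.5
  rep_cfg <- physics_config(lj_B = B, equil_steps = 300, quench_steps = 800)
  qp <- quench("PPPPPPPP", rep_cfg)
  expect_gt(radius_of_gyration(qp$coords), radius_of_gyration(qh$coords))
  # fixed seed, bit-identical conformation
  q1 <- with_seed(5, quench("+HHHHHH-", fast))
  q2 <- with_seed(5, quench("+HHHHHH-", fast))
  expect_identical(q1$coords, q2$coords)
})

test_that("XYZ serialisation round-trips conformations", {
  set.seed(281)
  confs <- list(init_conformation(5, cfg0), init_conformation(5, cfg0))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(confs, "+HPH-", path)
  back <- read_xyz(path)
  expect_length(back$coords, 2L)
  expect_identical(back$types, c("+", "H", "P", "H", "-"))
  expect_equal(back$coords[[1]], unname(confs[[1]]), tolerance = 1e-9)
})

test_that("monomer sequences are validated", {
  expect_error(assert_monomer_sequence("HP"), "at least 3")
  expect_error(assert_monomer_sequence("+HX-"), "invalid monomer")
  expect_error(assert_monomer_sequence("HHH"), "charged")
  expect_silent(assert_monomer_sequence("+HH-"))
  expect_silent(assert_monomer_sequence("HHH", require_charged_ends = FALSE))
})
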