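# Desk-scale off-lattice heteropolymer folding simulator.
#
# The model polymer is a flexible chain of point-like monomers of four
# types: hydrophobic H, hydrophilic P, and charged + and -.  Nearest
# neighbours along the chain are connected by stiff harmonic springs with
# rest length a; next-nearest neighbours and beyond interact through a
# Lennard-Jones 12-6 potential plus a Debye-Hueckel screened Coulomb term.
# Folding kinetics are over-damped Brownian dynamics.  All published
# numerical coefficients of this family of models are configuration fields
# here; the defaults reproduce the qualitative interaction orderings
# (HH attraction strongest, H-P repulsive, H-charged more repulsive) and
# no quantitative result in the package depends on their exact values.

MONOMER_TYPES <- c("H", "P", "+", "-")

#' Physics configuration for the folding model
#'
#' @param rest_length spring rest length a (sets the length unit).
#' @param spring_k spring stiffness per unit temperature; the spring energy
#'   is (k T / 2) (|x_{i+1} - x_i| - a)^2.
#' @param temperature folding/equilibration temperature T (energy units).
#' @param quench_temperature temperature T_q used during quenching.
#' @param debye_length Debye-Hueckel screening length.
#' @param lj_A,lj_B symmetric 4x4 Lennard-Jones coefficient tables indexed
#'   by monomer type (order H, P, +, -).  `lj_A` is the repulsive 1/r^12
#'   coefficient, `lj_B` the 1/r^6 coefficient (positive = attraction,
#'   negative = long-range repulsion).
#' @param charges named charges per monomer type.
#' @param dt integration time step.
#' @param noise_coeff coefficient c in the displacement noise variance
#'   c T dt (2 for the standard over-damped convention).
#' @param max_move cap on the deterministic per-monomer displacement in one
#'   step, a numerical safeguard against Lennard-Jones core blowups.
#' @param equil_steps equilibration steps at `temperature` before a quench.
#' @param quench_steps annealing steps at `quench_temperature`.
#' @param stationarity_tol projected-gradient tolerance at which the final
#'   energy minimisation is considered stationary.
#' @param max_quench_steps iteration budget for the final minimisation.
#' @param cluster_radius RMSD radius delta for single-linkage clustering of
#'   quenched conformations.
#' @param mad_multiplier multiplier c of the MAD in the native-ensemble
#'   membership threshold (median + c * MAD).
#' @return an object of class `"physics_config"`.
#' @export
physics_config <- function(rest_length = 1,
                           spring_k = 100,
                           temperature = 0.3,
                           quench_temperature = 0.02,
                           debye_length = 2,
                           lj_A = NULL,
                           lj_B = NULL,
                           charges = c(H = 0, P = 0, `+` = 1, `-` = -1),
                           dt = 0.002,
                           noise_coeff = 2,
                           max_move = 0.1,
                           equil_steps = 2000L,
                           quench_steps = 3000L,
                           stationarity_tol = 1e-6,
                           max_quench_steps = 500L,
                           cluster_radius = 0.6,
                           mad_multiplier = 3) {
  if (is.null(lj_A)) {
    lj_A <- matrix(1, 4, 4, dimnames = list(MONOMER_TYPES, MONOMER_TYPES))
  }
  if (is.null(lj_B)) {
    # HH attraction strongest; P/charged pairs mildly attractive;
    # H-P repulsive and H-charged more repulsive (negative B)
    lj_B <- matrix(1, 4, 4, dimnames = list(MONOMER_TYPES, MONOMER_TYPES))
    lj_B["H", "H"] <- 2
    lj_B["H", "P"] <- lj_B["P", "H"] <- -0.5
    lj_B["H", "+"] <- lj_B["+", "H"] <- -1
    lj_B["H", "-"] <- lj_B["-", "H"] <- -1
  }
  stopifnot(rest_length > 0, spring_k > 0, temperature >= 0,
            quench_temperature >= 0, debye_length > 0, dt > 0,
            noise_coeff > 0, max_move > 0, cluster_radius > 0,
            mad_multiplier >= 0)
  if (!isTRUE(all.equal(lj_A, t(lj_A))) || !isTRUE(all.equal(lj_B, t(lj_B))))
    stop("Lennard-Jones coefficient tables must be symmetric")
  if (any(lj_B["H", "H"] <= lj_B[cbind(c("P", "+", "-"), c("P", "+", "-"))]))
    stop("the H-H attraction must be the strongest like-pair attraction")
  structure(list(rest_length = rest_length, spring_k = spring_k,
                 temperature = temperature,
                 quench_temperature = quench_temperature,
                 debye_length = debye_length, lj_A = lj_A, lj_B = lj_B,
                 charges = charges, dt = dt, noise_coeff = noise_coeff,
                 max_move = max_move, equil_steps = as.integer(equil_steps),
                 quench_steps = as.integer(quench_steps),
                 stationarity_tol = stationarity_tol,
                 max_quench_steps = as.integer(max_quench_steps),
                 cluster_radius = cluster_radius,
                 mad_multiplier = mad_multiplier),
            class = "physics_config")
}

#' Validate a monomer sequence
#'
#' Sequences are strings over H (hydrophobic), P (hydrophilic), + and -
#' (charged).  Model sequences fix both endpoint monomers to charged types,
#' mimicking the proximity of chain termini.
#'
#' @param s a character string.
#' @param require_charged_ends enforce charged endpoints (default TRUE).
#' @return `s`, invisibly; errors on violation.
#' @export
assert_monomer_sequence <- function(s, require_charged_ends = TRUE) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(chars) < 3L) stop("monomer sequences need at least 3 monomers")
  bad <- setdiff(chars, MONOMER_TYPES)
  if (length(bad))
    stop("invalid monomer type(s): ", paste(bad, collapse = ", "))
  if (require_charged_ends &&
      !all(chars[c(1L, length(chars))] %in% c("+", "-")))
    stop("endpoint monomers must be charged (+ or -)")
  invisible(s)
}

#' Pairwise non-bonded interaction energy
#'
#' A_ij / r^12 - B_ij / r^6 + q_i q_j exp(-r / lambda_D) / r, the
#' Lennard-Jones plus screened-Coulomb potential acting between monomers
#' that are not nearest neighbours along the chain.
#'
#' @param r distance(s), strictly positive.
#' @param type_i,type_j monomer types (single characters).
#' @param cfg a [physics_config()].
#' @return energy value(s).
#' @export
pair_potential <- function(r, type_i, type_j, cfg = physics_config()) {
  if (any(r <= 0)) stop("pair distances must be strictly positive")
  A <- cfg$lj_A[type_i, type_j]
  B <- cfg$lj_B[type_i, type_j]
  qq <- cfg$charges[[type_i]] * cfg$charges[[type_j]]
  A / r^12 - B / r^6 + qq * exp(-r / cfg$debye_length) / r
}

# Precompute per-sequence interaction tables: non-bonded pair indices with
# their A, B, q_i q_j coefficients.
chain_pair_params <- function(s, cfg) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) stop("chain too short")
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- pairs[, 2] - pairs[, 1] >= 2L
  i <- pairs[keep, 1]; j <- pairs[keep, 2]
  list(n = n, types = chars, i = i, j = j,
       A = cfg$lj_A[cbind(chars[i], chars[j])],
       B = cfg$lj_B[cbind(chars[i], chars[j])],
       qq = unname(cfg$charges[chars[i]] * cfg$charges[chars[j]]))
}

#' Total energy of a chain conformation
#'
#' Sum of [pair_potential()] over all non-nearest-neighbour pairs plus the
#' harmonic spring energy (k T / 2) (|x_{i+1} - x_i| - a)^2 over bonded
#' neighbours.  Depends only on pairwise distances, hence invariant under
#' rigid motions.
#'
#' @param coords numeric n x 3 matrix of monomer coordinates.
#' @param s monomer sequence string of length n.
#' @param cfg a [physics_config()].
#' @param pp optional precomputed [chain_pair_params()] table.
#' @return total energy (scalar).
#' @export
chain_energy <- function(coords, s, cfg = physics_config(), pp = NULL) {
  if (is.null(pp)) pp <- chain_pair_params(s, cfg)
  if (nrow(coords) != pp$n)
    stop("coordinate rows (", nrow(coords), ") do not match sequence length (",
         pp$n, ")")
  d <- coords[pp$i, , drop = FALSE] - coords[pp$j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  if (any(r <= 0)) stop("coincident non-bonded monomers (r = 0)")
  e_pair <- sum(pp$A / r^12 - pp$B / r^6 +
                  pp$qq * exp(-r / cfg$debye_length) / r)
  db <- coords[-1, , drop = FALSE] - coords[-pp$n, , drop = FALSE]
  rb <- sqrt(rowSums(db^2))
  e_spring <- 0.5 * cfg$spring_k * cfg$temperature *
    sum((rb - cfg$rest_length)^2)
  e_pair + e_spring
}

#' Analytic gradient of the chain energy
#'
#' @inheritParams chain_energy
#' @return n x 3 matrix, the derivative of [chain_energy()] with respect to
#'   each coordinate.
#' @export
chain_gradient <- function(coords, s, cfg = physics_config(), pp = NULL) {
  if (is.null(pp)) pp <- chain_pair_params(s, cfg)
  n <- pp$n
  if (nrow(coords) != n) stop("coordinate rows do not match sequence length")
  g <- matrix(0, n, 3)

  d <- coords[pp$i, , drop = FALSE] - coords[pp$j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  if (any(r <= 0)) stop("coincident non-bonded monomers (r = 0)")
  expf <- exp(-r / cfg$debye_length)
  # dV/dr of the pair potential
  dVdr <- -12 * pp$A / r^13 + 6 * pp$B / r^7 -
    pp$qq * expf * (1 / (cfg$debye_length * r) + 1 / r^2)
  contrib <- d * (dVdr / r)
  acc <- rowsum(rbind(contrib, -contrib), group = c(pp$i, pp$j))
  g[as.integer(rownames(acc)), ] <- acc

  db <- coords[-1, , drop = FALSE] - coords[-n, , drop = FALSE]
  rb <- sqrt(rowSums(db^2))
  kT <- cfg$spring_k * cfg$temperature
  spring <- db * (kT * (rb - cfg$rest_length) / rb)
  g[-n, ] <- g[-n, ] - spring
  g[-1, ] <- g[-1, ] + spring
  if (any(!is.finite(g))) stop("non-finite energy gradient (diverged configuration)")
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One over-damped Brownian dynamics step
#'
#' Updates every coordinate by minus the energy gradient times dt plus a
#' Gaussian kick of zero mean and variance `noise_coeff * T * dt`,
#' independent across monomers, coordinates and steps.  The deterministic
#' displacement of each monomer is capped at `max_move` to keep the Euler
#' scheme stable near the Lennard-Jones core.
#'
#' @param coords n x 3 coordinate matrix.
#' @param s monomer sequence.
#' @param cfg a [physics_config()].
#' @param temperature temperature for the noise term (defaults to
#'   `cfg$temperature`).
#' @param pp optional precomputed pair table.
#' @return updated n x 3 coordinate matrix.
#' @export
brownian_step <- function(coords, s, cfg = physics_config(),
                          temperature = cfg$temperature, pp = NULL) {
  if (is.null(pp)) pp <- chain_pair_params(s, cfg)
  g <- chain_gradient(coords, s, cfg, pp)
  move <- -g * cfg$dt
  norms <- sqrt(rowSums(move^2))
  over <- norms > cfg$max_move
  if (any(over))
    move[over, ] <- move[over, , drop = FALSE] * (cfg$max_move / norms[over])
  if (temperature > 0)
    move <- move + matrix(stats::rnorm(3 * nrow(coords),
                                       sd = sqrt(cfg$noise_coeff *
                                                   temperature * cfg$dt)),
                          ncol = 3)
  coords + move
}

run_dynamics <- function(coords, s, cfg, n_steps, temperature, pp = NULL) {
  if (is.null(pp)) pp <- chain_pair_params(s, cfg)
  for (step in seq_len(n_steps))
    coords <- brownian_step(coords, s, cfg, temperature, pp)
  coords
}

#' Random initial chain conformation
#'
#' A random walk with bond length equal to the spring rest length.
#'
#' @param n number of monomers.
#' @param cfg a [physics_config()].
#' @return n x 3 coordinate matrix.
#' @export
init_conformation <- function(n, cfg = physics_config()) {
  dirs <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2)) * cfg$rest_length
  rbind(c(0, 0, 0), apply(dirs, 2, cumsum))
}

#' Quench a sequence to a low-energy conformation
#'
#' Three stages: (1) equilibration at the folding temperature; (2)
#' annealing at the quench temperature via Brownian dynamics; (3) a final
#' zero-temperature energy minimisation (L-BFGS on the analytic gradient,
#' stopping at projected-gradient tolerance `stationarity_tol` or after
#' `max_quench_steps` iterations), so the returned conformation is a
#' well-defined local energy minimum suitable for RMSD clustering.
#'
#' @param s monomer sequence string.
#' @param cfg a [physics_config()].
#' @param init optional starting coordinates (default: random chain).
#' @return list with `coords` (n x 3), `energy`, `converged` (logical:
#'   minimisation reached stationarity within budget), `steps`
#'   (minimisation iterations).
#' @export
quench <- function(s, cfg = physics_config(), init = NULL) {
  assert_monomer_sequence(s, require_charged_ends = FALSE)
  pp <- chain_pair_params(s, cfg)
  coords <- if (is.null(init)) init_conformation(pp$n, cfg) else init
  coords <- run_dynamics(coords, s, cfg, cfg$equil_steps, cfg$temperature, pp)
  coords <- run_dynamics(coords, s, cfg, cfg$quench_steps,
                         cfg$quench_temperature, pp)
  n <- pp$n
  opt <- stats::optim(
    as.vector(coords),
    fn = function(x) chain_energy(matrix(x, n, 3), s, cfg, pp),
    gr = function(x) as.vector(chain_gradient(matrix(x, n, 3), s, cfg, pp)),
    method = "L-BFGS-B",
    control = list(maxit = cfg$max_quench_steps,
                   pgtol = cfg$stationarity_tol))
  coords <- matrix(opt$par, n, 3)
  list(coords = coords, energy = opt$value,
       converged = opt$convergence == 0L,
       steps = as.integer(opt$counts[["function"]]))
}

#' Root-mean-square deviation after optimal superposition
#'
#' Minimum RMSD between two conformations over all rigid motions
#' (translation plus proper rotation), computed with the Kabsch algorithm.
#'
#' @param c1,c2 n x 3 coordinate matrices with equal n.
#' @return nonnegative scalar.
#' @export
rmsd <- function(c1, c2) {
  if (!is.matrix(c1) || !is.matrix(c2) || ncol(c1) != 3 || ncol(c2) != 3)
    stop("conformations must be n x 3 matrices")
  if (nrow(c1) != nrow(c2))
    stop("conformations must have the same number of monomers")
  p <- sweep(c1, 2, colMeans(c1))
  q <- sweep(c2, 2, colMeans(c2))
  sv <- svd(crossprod(p, q))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((p %*% t(R) - q)^2)))
}

#' Build the native structure ensemble of a sequence
#'
#' Performs `n_quench` independent quenches, clusters the resulting
#' conformations by single linkage at RMSD radius delta
#' (`cfg$cluster_radius`), and takes the largest cluster as the native
#' structure ensemble.  The membership threshold for new conformations is
#' median + c * MAD of the nearest-neighbour RMSDs within the ensemble
#' (raw median absolute deviation, `c = cfg$mad_multiplier`); a degenerate
#' ensemble of identical members gets threshold = median.
#'
#' @param s monomer sequence.
#' @param n_quench number of quenches (>= 2; thousands at production
#'   scale, config-reducible for desk-scale runs).
#' @param cfg a [physics_config()].
#' @param quench_fun quench backend, a `function(s, cfg)` returning a list
#'   with `coords`; replaceable by deterministic mocks in tests.
#' @return an object of class `"native_ensemble"`: list with `members`
#'   (list of coordinate matrices), `delta`, `nn_distances`, `median`,
#'   `mad`, `threshold`, `n_quench`.
#' @export
build_native_ensemble <- function(s, n_quench, cfg = physics_config(),
                                  quench_fun = quench) {
  stopifnot(n_quench >= 2)
  confs <- lapply(seq_len(n_quench), function(i) quench_fun(s, cfg)$coords)
  D <- matrix(0, n_quench, n_quench)
  for (i in seq_len(n_quench - 1L))
    for (j in (i + 1L):n_quench)
      D[i, j] <- D[j, i] <- rmsd(confs[[i]], confs[[j]])
  cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "single"),
                      h = cfg$cluster_radius)
  sizes <- tabulate(cl)
  if (max(sizes) < 2L)
    stop("all clusters are singletons: no reproducible fold at radius ",
         cfg$cluster_radius)
  big <- which(cl == which.max(sizes))
  Dm <- D[big, big, drop = FALSE]
  diag(Dm) <- Inf
  nn <- apply(Dm, 1, min)
  m <- stats::median(nn)
  mu <- stats::mad(nn, constant = 1)
  structure(list(members = confs[big], delta = cfg$cluster_radius,
                 nn_distances = nn, median = m, mad = mu,
                 threshold = m + cfg$mad_multiplier * mu,
                 n_quench = n_quench),
            class = "native_ensemble")
}

#' @export
print.native_ensemble <- function(x, ...) {
  cat(sprintf(paste0("Native structure ensemble: %d/%d conformations, ",
                     "delta = %g, membership threshold = %g\n"),
              length(x$members), x$n_quench, x$delta, x$threshold))
  invisible(x)
}

#' Does a conformation belong to a native ensemble?
#'
#' @param ens a `"native_ensemble"`.
#' @param coords n x 3 coordinate matrix.
#' @return logical: is the shortest RMSD to any member within the
#'   ensemble's membership threshold?  (Non-strict comparison, so the
#'   degenerate all-identical ensemble with threshold 0 still accepts
#'   exact copies.)
#' @export
in_native_ensemble <- function(ens, coords) {
  stopifnot(inherits(ens, "native_ensemble"))
  for (m in ens$members)
    if (rmsd(coords, m) <= ens$threshold) return(TRUE)
  FALSE
}

#' Probability of folding to a reference native ensemble
#'
#' Quenches the sequence `n_samples` times and reports the fraction of
#' final conformations that fall inside the reference ensemble's
#' membership threshold.  The resolution of the estimate is 1/n_samples.
#'
#' @param s monomer sequence.
#' @param ref a `"native_ensemble"` (typically of another sequence's, or
#'   the same sequence's, native structure).
#' @param n_samples number of quenches (>= 1).
#' @param cfg a [physics_config()].
#' @param quench_fun quench backend (see [build_native_ensemble()]).
#' @return a probability in \[0, 1\].
#' @export
folding_probability <- function(s, ref, n_samples, cfg = physics_config(),
                                quench_fun = quench) {
  stopifnot(inherits(ref, "native_ensemble"), n_samples >= 1)
  hits <- 0L
  for (i in seq_len(n_samples))
    if (in_native_ensemble(ref, quench_fun(s, cfg)$coords)) hits <- hits + 1L
  hits / n_samples
}

#' Write conformations to an XYZ file
#'
#' Plain-text XYZ: atom count, comment line, then one `type x y z` row per
#' monomer; multiple conformations are concatenated as frames.
#'
#' @param confs a coordinate matrix or list of coordinate matrices.
#' @param s monomer sequence (types become the element column).
#' @param path output path.
#' @param comment comment line content.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(confs, s, path, comment = "ruggedpaths conformation") {
  if (is.matrix(confs)) confs <- list(confs)
  types <- strsplit(s, "", fixed = TRUE)[[1]]
  con <- file(path, "wt")
  on.exit(close(con))
  for (X in confs) {
    if (nrow(X) != length(types)) stop("coordinate/sequence length mismatch")
    writeLines(as.character(nrow(X)), con)
    writeLines(comment, con)
    writeLines(sprintf("%s %.10g %.10g %.10g", types, X[, 1], X[, 2], X[, 3]),
               con)
  }
  invisible(path)
}

#' Read conformations from an XYZ file
#'
#' @param path XYZ file written by [write_xyz()].
#' @return list with `coords` (list of n x 3 matrices) and `types`
#'   (character vector of monomer types from the first frame).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  types <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    X <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (is.null(types)) types <- vapply(rows, `[`, character(1), 1L)
    out[[length(out) + 1L]] <- X
    i <- i + 2L + n
  }
  list(coords = out, types = types)
}
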