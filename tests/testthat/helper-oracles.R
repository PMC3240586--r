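# Independent brute-force oracles and fixture builders used across the
# suite.  Oracles deliberately avoid the package's optimised code paths.

# -- fixtures ---------------------------------------------------------------

all_binary_genotypes <- function(L) {
  apply(expand.grid(rep(list(c("0", "1")), L))[, L:1, drop = FALSE],
        1, paste, collapse = "")
}

# Full binary hypercube with the given fitness vector (recycled).
cube_landscape <- function(L, fitness) {
  genos <- sort(all_binary_genotypes(L), method = "radix")
  landscape(genos, rep_len(fitness, length(genos)))
}

# Strictly additive landscape on the full binary L-cube with peak "1...1":
# fitness is the sum of per-site positive contributions for each '1'.
additive_cube <- function(L, contributions = NULL) {
  if (is.null(contributions)) contributions <- seq(0.5, 1, length.out = L)
  genos <- sort(all_binary_genotypes(L), method = "radix")
  gm <- do.call(rbind, strsplit(genos, ""))
  fitness <- as.numeric((gm == "1") %*% contributions)
  landscape(genos, fitness)
}

# Random sub-landscape of the binary L-cube: keep each genotype with
# probability p_keep (at least 2 kept), i.i.d. uniform fitness.
random_landscape <- function(L, p_keep = 0.8) {
  genos <- all_binary_genotypes(L)
  keep <- stats::runif(length(genos)) < p_keep
  if (sum(keep) < 2) keep[sample(length(genos), 2)] <- TRUE
  landscape(genos[keep], stats::runif(sum(keep)))
}

# -- oracles ----------------------------------------------------------------

# Brute-force count of fitness-monotonic simple paths: enumerate every
# permutation of the differing sites explicitly.
bf_count_monotonic <- function(ls, start, peak) {
  sites <- which(strsplit(start, "")[[1]] != strsplit(peak, "")[[1]])
  if (!length(sites)) return(1)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  target <- strsplit(peak, "")[[1]]
  total <- 0
  for (ord in perms(sites)) {
    cur <- strsplit(start, "")[[1]]
    f_prev <- fitness_of(ls, start)
    ok <- TRUE
    for (s in ord) {
      cur[s] <- target[s]
      g <- paste(cur, collapse = "")
      f_cur <- fitness_of(ls, g)
      if (is.na(f_cur) || f_cur <= f_prev) { ok <- FALSE; break }
      f_prev <- f_cur
    }
    if (ok) total <- total + 1
  }
  total
}

# Brute-force local roughness: double loop over genotypes and candidate
# neighbours via pairwise Hamming distances.
bf_local_roughness <- function(ls) {
  n <- length(ls$genotypes)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    difs <- c()
    for (j in seq_len(n)) {
      if (i == j) next
      if (hamming_distance(ls$genotypes[i], ls$genotypes[j]) == 1L)
        difs <- c(difs, ls$fitness[i] - ls$fitness[j])
    }
    vals[i] <- sqrt(mean(difs^2))
  }
  mean(vals)
}

# Brute-force tree component straight from the definition.
bf_tree_component <- function(ls) {
  keep <- vapply(seq_along(ls$genotypes), function(i) {
    fitter <- 0L
    for (j in seq_along(ls$genotypes)) {
      if (i == j) next
      if (hamming_distance(ls$genotypes[i], ls$genotypes[j]) == 1L &&
          ls$fitness[j] > ls$fitness[i])
        fitter <- fitter + 1L
    }
    fitter <= 1L
  }, logical(1))
  ls$genotypes[keep]
}

# Breadth-first shortest path distances from a set of source genotypes,
# walking the present Hamming-1 graph by pairwise distance checks.
bf_bfs_distance <- function(ls, sources) {
  n <- length(ls$genotypes)
  dist <- rep(NA_integer_, n)
  dist[match(sources, ls$genotypes)] <- 0L
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (hamming_distance(ls$genotypes[i], ls$genotypes[j]) != 1L) next
        if (!is.na(dist[j]) && (is.na(dist[i]) || dist[i] > dist[j] + 1L)) {
          dist[i] <- dist[j] + 1L
          changed <- TRUE
        }
      }
    }
  }
  stats::setNames(dist, ls$genotypes)
}

# Unweighted mean pairwise divergence of a list of paths, using the
# scalar path_divergence() pair by pair (cross-checks the vectorised
# bundle machinery).
bf_mean_pairwise_divergence <- function(paths) {
  P <- length(paths)
  tot <- 0
  for (i in seq_len(P))
    for (j in seq_len(P))
      tot <- tot + path_divergence(paths[[i]], paths[[j]])
  tot / P^2
}

# Deterministic "planted" quench backend: serves conformations from a
# prearranged list, cycling in order.
make_planted_quencher <- function(confs) {
  k <- 0L
  function(s, cfg) {
    k <<- if (k >= length(confs)) 1L else k + 1L
    list(coords = confs[[k]], converged = TRUE)
  }
}

# A tight cluster of conformations: base + small deterministic jitter.
jittered_cluster <- function(base, n, scale = 0.01) {
  lapply(seq_len(n), function(i) base + scale * sin(i + seq_along(base)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
           1 - 2 * (q[2]^2 + q[3]^2)),
         3, 3, byrow = TRUE)
}
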