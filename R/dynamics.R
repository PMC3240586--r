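# Evolutionary dynamics on a landscape in the low mutation-rate limit:
# misfolding-cost fitness, Kimura fixation probabilities, adaptive-walk
# trajectory sampling, bundle construction and the selection-pressure sweep.

#' Misfolding-cost fitness
#'
#' A sequence that folds correctly with probability P produces on average
#' A (1 - P) / P misfolded copies before an abundance A of correctly folded
#' copies is reached.  Fitness is the negative of that number:
#' f = -A (1 - P) / P.  It is zero iff P = 1 and strictly increasing in P.
#' Non-positive folding probabilities give `-Inf` (inviable).
#'
#' @param P folding probability/probabilities in (0, 1\].
#' @param A required abundance (strength of selection), positive.
#' @return numeric vector of fitness values.
#' @export
misfolding_fitness <- function(P, A) {
  stopifnot(A > 0)
  if (any(P > 1 + 1e-12)) stop("folding probabilities cannot exceed 1")
  out <- ifelse(P <= 0, -Inf, -A * (1 - pmin(P, 1)) / pmin(P, 1))
  # exact zero at P = 1
  out[P >= 1] <- 0
  out
}

#' Kimura fixation probability (diploid, low mutation rate)
#'
#' Probability that a new mutant with selection coefficient s fixes in a
#' diploid population of effective size N_e:
#' u = (1 - exp(-2 s)) / (1 - exp(-4 N_e s)), with the continuous limit
#' 1 / (2 N_e) at s = 0.  The implementation is numerically stable for
#' extreme |s| (exponents are handled in log space and clamped), and
#' `s = -Inf` (inviable mutants) gives exactly 0.
#'
#' @param s selection coefficient(s), typically the fitness difference
#'   mutant minus resident.
#' @param N_e effective population size, positive.
#' @return fixation probabilities in \[0, 1\] (values above 1 can only arise
#'   for N_e < 1/2, outside the model's domain of validity).
#' @export
fixation_probability <- function(s, N_e) {
  stopifnot(N_e > 0)
  out <- numeric(length(s))
  for (i in seq_along(s)) {
    si <- s[i]
    if (is.nan(si)) { out[i] <- NaN; next }
    if (si == -Inf) { out[i] <- 0; next }
    if (si == Inf) { out[i] <- 1; next }
    a <- 2 * si; b <- 4 * N_e * si
    if (abs(b) < 1e-9 || abs(a) < 1e-12) {
      # neutral limit a/b = 1/(2 N_e)
      out[i] <- 1 / (2 * N_e)
    } else if (si > 0) {
      # both expm1 terms positive; -a may underflow harmlessly
      num <- -expm1(-a)
      den <- if (b > 700) 1 else -expm1(-b)
      out[i] <- num / den
    } else {
      # s < 0: u = (e^{-a} - 1)/(e^{-b} - 1) = e^{b - a} (1 - e^{a})/(1 - e^{b})
      # with a, b < 0; for strongly deleterious mutants this underflows to 0
      if (-b > 700) {
        log_u <- (b - a) + log1p(-exp(a)) # log1p fine: exp(a) < 1
        out[i] <- exp(log_u)
      } else {
        out[i] <- expm1(-a) / expm1(-b)
      }
    }
  }
  out
}

#' Selection parameters for trajectory sampling
#'
#' @param N_e effective population size (diploid Kimura dynamics).  The
#'   default of 1000 is large enough that neutral fixations are rare.
#' @param abundance required abundance A; for landscapes whose fitness
#'   column is a folding probability (see `fitness`), selection pressure is
#'   the product N_e * A.
#' @param mode `"kimura"` (fixation probabilities of Kimura's formula),
#'   `"strong_limit"` (only fitness-increasing mutations fix, all
#'   equiprobable) or `"neutral_limit"` (all present neighbours
#'   equiprobable: a random walk on the landscape).
#' @param max_steps cap on the number of fixed substitutions per walk;
#'   walks hitting the cap are flagged as truncated and excluded from
#'   bundles.
#' @param fitness `"direct"` (the landscape's fitness column is used as
#'   is, s = f_mutant - f_resident) or `"misfolding"` (the fitness column
#'   is a folding probability P, converted by [misfolding_fitness()] with
#'   abundance A before differences are taken).
#' @return an object of class `"selection_params"`.
#' @export
selection_params <- function(N_e = 1000, abundance = 1,
                             mode = c("kimura", "strong_limit", "neutral_limit"),
                             max_steps = 10000L,
                             fitness = c("direct", "misfolding")) {
  mode <- match.arg(mode)
  fitness <- match.arg(fitness)
  stopifnot(N_e > 0, abundance > 0, max_steps > 0)
  structure(list(N_e = N_e, abundance = abundance, mode = mode,
                 max_steps = as.integer(max_steps), fitness = fitness),
            class = "selection_params")
}

# Effective fitness values used for selection coefficients.
walk_fitness <- function(ls, params) {
  if (params$fitness == "misfolding")
    misfolding_fitness(ls$fitness, params$abundance)
  else ls$fitness
}

# Precompute, for every node, neighbour indices and their jump weights.
# Proposals are uniform over all single-site mutations; proposals leaving
# the landscape are rejected (weight 0), so the embedded jump chain over
# *fixed* states picks a present neighbour with probability proportional to
# its fixation probability.  Sampling the jump chain directly is equivalent
# in path law to the propose/reject scheme and does not stall at weak
# selection.
walk_tables <- function(ls, params) {
  adj <- landscape_adjacency(ls)
  f <- walk_fitness(ls, params)
  weights <- vector("list", length(adj))
  is_peak <- logical(length(adj))
  for (i in seq_along(adj)) {
    nb <- adj[[i]]
    is_peak[i] <- !length(nb) || all(f[nb] <= f[i])
    if (!length(nb)) { weights[[i]] <- numeric(0); next }
    w <- switch(params$mode,
      strong_limit = as.numeric(f[nb] > f[i]),
      neutral_limit = rep(1, length(nb)),
      kimura = fixation_probability(f[nb] - f[i], params$N_e))
    weights[[i]] <- w
  }
  list(adj = adj, weights = weights, is_peak = is_peak, fitness = f)
}

sample_walk <- function(ls, start_idx, params, tables) {
  path <- integer(params$max_steps + 1L)
  path[1L] <- start_idx
  cur <- start_idx
  steps <- 0L
  truncated <- FALSE
  repeat {
    if (tables$is_peak[cur]) break
    if (steps >= params$max_steps) { truncated <- TRUE; break }
    nb <- tables$adj[[cur]]
    w <- tables$weights[[cur]]
    tot <- sum(w)
    if (!is.finite(tot) || tot <= 0) { truncated <- TRUE; break }
    cur <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L, prob = w)]
    steps <- steps + 1L
    path[steps + 1L] <- cur
  }
  list(path = ls$genotypes[path[seq_len(steps + 1L)]],
       terminal = ls$genotypes[cur], truncated = truncated)
}

#' Sample one adaptive-walk trajectory
#'
#' Starting from a non-peak genotype, mutations are proposed uniformly over
#' all single-site changes and fixed with the probability given by the
#' selected mode (Kimura fixation probability by default); proposals
#' leaving the landscape are rejected as inviable.  The walk records fixed
#' genotypes only and stops when it reaches a fitness peak (a genotype with
#' no strictly fitter present neighbour) or after `max_steps` fixations
#' (flagged as truncated).
#'
#' @param ls a `landscape`
#' @param start a non-peak genotype present in `ls`.
#' @param params a [selection_params()].
#' @return list with `path` (character vector of fixed genotypes, starting
#'   at `start`), `terminal`, and `truncated` (logical).
#' @export
sample_trajectory <- function(ls, start, params = selection_params()) {
  stopifnot(inherits(ls, "landscape"), inherits(params, "selection_params"))
  i0 <- match(start, ls$genotypes)
  if (is.na(i0)) stop("start genotype '", start, "' is not in the landscape")
  tables <- walk_tables(ls, params)
  if (tables$is_peak[i0])
    stop("start genotype '", start, "' is a fitness peak")
  sample_walk(ls, i0, params, tables)
}

#' Build trajectory bundles by repeated adaptive walks
#'
#' From every non-peak genotype (or a supplied subset), samples
#' `walks_per_start` trajectories under the given selection parameters and
#' groups them into bundles keyed by (start, terminal peak).  Occurrence
#' probabilities are empirical path frequencies within each bundle.
#' Truncated walks are excluded from bundles and counted.
#'
#' @param ls a `landscape`
#' @param walks_per_start number of walks from each start (>= 1).
#' @param params a [selection_params()].
#' @param starts optional character vector of start genotypes; defaults to
#'   every non-peak genotype.
#' @return an object of class `"trajectory_ensemble"`: list with `bundles`
#'   (list of [path_bundle()]), `n_truncated`, `params`.
#' @export
build_bundles <- function(ls, walks_per_start, params = selection_params(),
                          starts = NULL) {
  stopifnot(inherits(ls, "landscape"), walks_per_start >= 1)
  tables <- walk_tables(ls, params)
  if (is.null(starts)) {
    starts <- ls$genotypes[!tables$is_peak]
  } else {
    idx <- match(starts, ls$genotypes)
    if (anyNA(idx)) stop("start genotype(s) not in the landscape")
    if (any(tables$is_peak[idx]))
      stop("start genotype(s) are fitness peaks: ",
           paste(starts[tables$is_peak[idx]], collapse = ", "))
  }
  n_truncated <- 0L
  # per (start, terminal) key: a counting environment of collapsed paths
  store <- new.env(hash = TRUE)
  for (g in starts) {
    i0 <- match(g, ls$genotypes)
    for (w in seq_len(walks_per_start)) {
      walk <- sample_walk(ls, i0, params, tables)
      if (walk$truncated) { n_truncated <- n_truncated + 1L; next }
      key <- paste(g, walk$terminal, sep = " -> ")
      pkey <- paste(walk$path, collapse = ",")
      bucket <- get0(key, envir = store, inherits = FALSE)
      if (is.null(bucket)) {
        bucket <- new.env(hash = TRUE)
        assign(key, bucket, envir = store)
      }
      cnt <- get0(pkey, envir = bucket, inherits = FALSE)
      assign(pkey, if (is.null(cnt)) 1L else cnt + 1L, envir = bucket)
    }
  }
  bundles <- list()
  for (key in sort(ls(store))) {
    ends <- strsplit(key, " -> ", fixed = TRUE)[[1]]
    bucket <- get(key, envir = store)
    pkeys <- sort(ls(bucket))
    counts <- vapply(pkeys, function(k) get(k, envir = bucket), integer(1))
    paths <- lapply(strsplit(pkeys, ",", fixed = TRUE), identity)
    bundles[[length(bundles) + 1L]] <-
      path_bundle(ends[1], ends[2], paths,
                  probs = unname(counts) / sum(counts),
                  n_obs = sum(counts))
  }
  structure(list(bundles = bundles, n_truncated = n_truncated,
                 params = params),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d bundle(s), %d truncated walk(s), mode %s\n",
              length(x$bundles), x$n_truncated, x$params$mode))
  invisible(x)
}

#' Mean path divergence as a function of selection pressure
#'
#' Sweeps the selection pressure N_e * A over the supplied values with N_e
#' held fixed (the abundance A carries the pressure), building trajectory
#' bundles under Kimura dynamics at each pressure and summarising them as a
#' divergence profile.  At low pressure evolution is a random walk probing
#' only the landscape's topology; at high pressure only fitness-increasing
#' mutations fix and the divergence saturates.
#'
#' @param ls a `landscape` whose fitness column is interpreted according to
#'   `fitness` (see [selection_params()]); the `"misfolding"` choice treats
#'   it as a folding probability, which makes the pressure knob exactly
#'   N_e * A.
#' @param pressures numeric vector of N_e * A values, sorted ascending.
#' @param walks_per_start walks per non-peak start at each pressure.
#' @param N_e fixed effective population size.
#' @param fitness passed to [selection_params()].
#' @param max_steps passed to [selection_params()].
#' @return named list (one element per pressure) of
#'   [divergence_profile()] objects, with attribute `"n_truncated"`.
#' @export
selection_sweep <- function(ls, pressures, walks_per_start = 100,
                            N_e = 1000, fitness = "misfolding",
                            max_steps = 10000L) {
  stopifnot(inherits(ls, "landscape"), length(pressures) >= 1)
  if (is.unsorted(pressures)) stop("'pressures' must be sorted ascending")
  out <- vector("list", length(pressures))
  names(out) <- as.character(pressures)
  truncated <- integer(length(pressures))
  for (k in seq_along(pressures)) {
    params <- selection_params(N_e = N_e, abundance = pressures[k] / N_e,
                               mode = "kimura", max_steps = max_steps,
                               fitness = fitness)
    ens <- build_bundles(ls, walks_per_start, params)
    truncated[k] <- ens$n_truncated
    out[[k]] <- divergence_profile(ens$bundles)
  }
  attr(out, "n_truncated") <- truncated
  out
}
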