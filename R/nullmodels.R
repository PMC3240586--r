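# Null models: scrambled (permuted) landscapes with Z-scores, and the
# noisy-additive landscape generator that provides a family of synthetic
# landscapes of continuously tunable roughness.

#' Scramble a landscape
#'
#' Returns a landscape with the same genotype set (hence identical
#' topology) whose fitness values have been reassigned by a uniformly
#' random permutation.  The fitness multiset is preserved exactly.
#'
#' @param ls a `landscape`
#' @return a `landscape`.
#' @export
scramble <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  n <- length(ls$genotypes)
  if (n < 2L) return(ls)
  landscape(ls$genotypes, ls$fitness[sample.int(n)], alphabet = ls$alphabet)
}

# Registry of named landscape characteristics usable in zscore().
landscape_metric_registry <- function() {
  list(
    peak_fraction = function(ls) length(find_peaks(ls)) / length(ls$genotypes),
    deviation_from_additivity = function(ls) deviation_from_additivity(ls),
    variability_explained = function(ls) variability_explained(ls),
    local_roughness = local_roughness,
    mean_tree_distance = mean_tree_distance,
    monotonic_path_fraction = monotonic_path_fraction,
    mean_path_divergence = mean_path_divergence)
}

#' Names of the built-in landscape characteristics
#' @return character vector of metric names accepted by [zscore()].
#' @export
landscape_metrics <- function() names(landscape_metric_registry())

#' Z-score of a landscape characteristic against scrambled landscapes
#'
#' Computes a characteristic on the original landscape and on `n_perm`
#' independently scrambled copies, and reports the deviation of the
#' original from the permutation mean in units of the permutation standard
#' deviation.  Strongly negative or positive Z-scores indicate that the
#' original landscape is more correlated than an uncorrelated landscape
#' with the same fitness distribution and topology.
#'
#' @param ls a `landscape`
#' @param metric a metric name from [landscape_metrics()], or a function
#'   `landscape -> number`.
#' @param n_perm number of scrambled landscapes (>= 2; 100 by default).
#' @return an object of class `"zscore_report"`: list with `metric`,
#'   `original`, `perm_mean`, `perm_sd`, `z` (NA with a warning when the
#'   permutation SD is zero), `n_permutations`.
#' @export
zscore <- function(ls, metric, n_perm = 100) {
  stopifnot(inherits(ls, "landscape"), n_perm >= 2)
  if (is.character(metric)) {
    reg <- landscape_metric_registry()
    if (!metric %in% names(reg))
      stop("unknown metric '", metric, "'; available: ",
           paste(names(reg), collapse = ", "))
    metric_name <- metric
    metric_fun <- reg[[metric]]
  } else if (is.function(metric)) {
    metric_name <- deparse(substitute(metric))[1]
    metric_fun <- metric
  } else stop("'metric' must be a name or a function")
  original <- metric_fun(ls)
  perms <- vapply(seq_len(n_perm), function(i) metric_fun(scramble(ls)),
                  numeric(1))
  mu <- mean(perms)
  sdv <- stats::sd(perms)
  z <- if (sdv == 0) {
    warning("permutation standard deviation is zero; Z-score undefined")
    NA_real_
  } else (original - mu) / sdv
  structure(list(metric = metric_name, original = original,
                 perm_mean = mu, perm_sd = sdv, z = z,
                 n_permutations = as.integer(n_perm)),
            class = "zscore_report")
}

#' @export
print.zscore_report <- function(x, ...) {
  cat(sprintf("%s: original %g, permutations %g +/- %g (n = %d), Z = %s\n",
              x$metric, x$original, x$perm_mean, x$perm_sd,
              x$n_permutations,
              if (is.na(x$z)) "undefined" else sprintf("%.3f", x$z)))
  invisible(x)
}

#' Noise specification for the additive landscape generator
#'
#' @param kind `"multiplicative"` (fitness multiplied by U^nu with
#'   U ~ Uniform(0,1)), `"additive"` (zero-mean Gaussian of standard
#'   deviation `sigma` added), or `"none"`.
#' @param nu positive exponent of the multiplicative perturbation; small
#'   `nu` means factors close to 1 and a nearly additive landscape.
#' @param sigma standard deviation of the additive Gaussian noise.
#' @param lambda_rate rate of the exponential distribution from which the
#'   negative per-substitution fitness differentials are drawn.  `NULL`
#'   (default) resolves to the number of sites at generation time, so the
#'   mean single-substitution fitness drop is 1/length and the additive
#'   fitness declines from 1 at the peak to about 0 at the antipode.
#' @return an object of class `"noise_spec"`.
#' @export
noise_spec <- function(kind = c("multiplicative", "additive", "none"),
                       nu = 1, sigma = 0.1, lambda_rate = NULL) {
  kind <- match.arg(kind)
  stopifnot(nu >= 0, sigma >= 0,
            is.null(lambda_rate) || lambda_rate > 0)
  structure(list(kind = kind, nu = nu, sigma = sigma,
                 lambda_rate = lambda_rate),
            class = "noise_spec")
}

all_genotypes <- function(length, alphabet) {
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), length),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  do.call(paste0, rev(grid))
}

#' Generate an additive landscape perturbed by noise
#'
#' Builds a strictly additive landscape anchored at a designated peak with
#' fitness 1: every (site, non-peak state) substitution carries a negative
#' fitness differential drawn from an exponential distribution, and the
#' additive fitness of a genotype is 1 plus the sum of the differentials of
#' the substitutions separating it from the peak.  The summed fitness of
#' each non-peak genotype is then perturbed once by the chosen noise
#' (multiplicative U^nu or additive Gaussian); genotypes whose perturbed
#' fitness is strictly positive are retained, and the result is restricted
#' to the connected component containing the peak, whose fitness stays
#' exactly 1.
#'
#' @param length number of sites (>= 1).
#' @param alphabet character vector of symbols (default binary `0/1`).
#' @param noise a [noise_spec()].
#' @param peak designated peak genotype; defaults to the first alphabet
#'   symbol repeated.
#' @return a `landscape`; attribute `"generator"` records the peak, the
#'   differential matrix and the noise specification.
#' @export
generate_noisy_additive <- function(length, alphabet = c("0", "1"),
                                    noise = noise_spec(), peak = NULL) {
  stopifnot(length >= 1, inherits(noise, "noise_spec"))
  alphabet <- sort(unique(as.character(alphabet)), method = "radix")
  k <- base::length(alphabet)
  if (k < 2L) stop("alphabet needs at least 2 symbols")
  if (k^length > 2^20) stop("sequence space too large to enumerate")
  if (is.null(peak)) peak <- paste(rep(alphabet[1], length), collapse = "")
  peak_chars <- strsplit(peak, "", fixed = TRUE)[[1]]
  if (base::length(peak_chars) != length || !all(peak_chars %in% alphabet))
    stop("'peak' must be a length-", length, " string over the alphabet")
  rate <- if (is.null(noise$lambda_rate)) length else noise$lambda_rate

  # differentials: sites x alphabet states; 0 at the peak state
  diffs <- matrix(0, nrow = length, ncol = k,
                  dimnames = list(NULL, alphabet))
  for (i in seq_len(length)) {
    others <- alphabet != peak_chars[i]
    diffs[i, others] <- -stats::rexp(sum(others), rate = rate)
  }

  genos <- all_genotypes(length, alphabet)
  gm <- genotype_matrix(genos)
  fitness <- rep(1, base::length(genos))
  for (i in seq_len(length))
    fitness <- fitness + diffs[i, ][gm[, i]]

  is_peak <- genos == peak
  n_other <- sum(!is_peak)
  fitness[!is_peak] <- switch(noise$kind,
    none = fitness[!is_peak],
    multiplicative = fitness[!is_peak] *
      stats::runif(n_other)^noise$nu,
    additive = fitness[!is_peak] + stats::rnorm(n_other, sd = noise$sigma))

  keep <- fitness > 0 | is_peak
  ls <- landscape(genos[keep], fitness[keep], alphabet = alphabet)
  ls <- connected_component(ls, peak)
  attr(ls, "generator") <- list(peak = peak, differentials = diffs,
                                noise = noise, lambda_rate = rate)
  ls
}

#' Generate a family of noisy-additive landscapes
#'
#' One landscape per (noise level, seed) pair, reproducible from the seeds.
#'
#' @param length,alphabet as in [generate_noisy_additive()].
#' @param nu_grid numeric vector of multiplicative-noise exponents.
#' @param seeds integer vector of RNG seeds.
#' @param kind noise kind for the whole family (`"multiplicative"` by
#'   default; for `"additive"`, `nu_grid` is interpreted as sigma values).
#' @param lambda_rate optional exponential rate override.
#' @return list of landscapes; each element carries attributes
#'   `"noise_level"` and `"seed"`.
#' @export
noise_family <- function(length, alphabet = c("0", "1"),
                         nu_grid = c(0.5, 1, 2, 4),
                         seeds = 1:20,
                         kind = "multiplicative",
                         lambda_rate = NULL) {
  stopifnot(base::length(nu_grid) >= 1, base::length(seeds) >= 1)
  out <- list()
  for (nu in nu_grid) {
    for (seed in seeds) {
      spec <- if (kind == "additive")
        noise_spec(kind = "additive", sigma = nu, lambda_rate = lambda_rate)
      else if (kind == "none")
        noise_spec(kind = "none", lambda_rate = lambda_rate)
      else noise_spec(kind = "multiplicative", nu = nu,
                      lambda_rate = lambda_rate)
      ls <- with_seed(seed, generate_noisy_additive(length, alphabet, spec))
      attr(ls, "noise_level") <- nu
      attr(ls, "seed") <- seed
      out[[base::length(out) + 1L]] <- ls
    }
  }
  out
}
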