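# Roughness statistics of a fitness landscape: peak-anchored additive model
# fit, local roughness, peaks and plateaus, and the tree component.

#' Fit the peak-anchored additive model
#'
#' Models the fitness of every genotype as the peak fitness plus the sum of
#' per-substitution contributions: one free coefficient for each
#' (site, non-peak state) pair, where the peak is the main peak of the
#' landscape.  Coefficients are chosen by least squares, minimising the sum
#' of squared differences between observed and predicted fitness; when the
#' design is rank deficient (sparse landscapes) the minimum-norm solution is
#' taken, computed via the singular value decomposition.  Contributions are
#' not sign-constrained.
#'
#' @param ls a `landscape` with at least 2 entries.
#' @return An object of class `"additive_fit"`: list with `peak`,
#'   `contributions` (named numeric, names `"<site>:<state>"`), `fitted`
#'   (named by genotype), `residuals`, `ss_residual`, `ss_fitness`,
#'   `rms_residual`.
#' @export
fit_additive <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  n <- length(ls$genotypes)
  if (n < 2L) stop("need at least 2 genotypes to fit an additive model")
  peak <- main_peak(ls)
  f_peak <- fitness_of(ls, peak)
  L <- ls$length
  peak_chars <- strsplit(peak, "", fixed = TRUE)[[1]]
  geno <- genotype_matrix(ls$genotypes)

  # columns: (site, state) for every non-peak state at that site
  sites <- integer(0); states <- character(0)
  for (i in seq_len(L)) {
    others <- setdiff(ls$alphabet, peak_chars[i])
    sites <- c(sites, rep(i, length(others)))
    states <- c(states, others)
  }
  X <- matrix(0, n, length(sites))
  for (k in seq_along(sites))
    X[, k] <- as.numeric(geno[, sites[k]] == states[k])
  y <- ls$fitness - f_peak

  coef <- pseudo_solve(X, y)
  fitted <- f_peak + as.numeric(X %*% coef)
  resid <- ls$fitness - fitted
  names(fitted) <- ls$genotypes
  names(coef) <- paste0(sites, ":", states)
  structure(list(peak = peak,
                 contributions = coef,
                 fitted = fitted,
                 residuals = stats::setNames(resid, ls$genotypes),
                 ss_residual = sum(resid^2),
                 ss_fitness = sum(ls$fitness^2),
                 rms_residual = sqrt(mean(resid^2))),
            class = "additive_fit")
}

# Minimum-norm least-squares solution via SVD pseudoinverse.
pseudo_solve <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) return(rep(0, ncol(X)))
  as.numeric(sv$v[, keep, drop = FALSE] %*%
               ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep]))
}

#' @export
print.additive_fit <- function(x, ...) {
  cat(sprintf("Additive model anchored at peak %s: %d coefficients\n",
              x$peak, length(x$contributions)))
  cat(sprintf("  ss_residual = %g, ss_fitness = %g, deviation = %g\n",
              x$ss_residual, x$ss_fitness,
              deviation_from_additivity(x)))
  invisible(x)
}

#' Deviation from additivity
#'
#' The residual sum of squares of the additive model fit scaled by the sum
#' of squared fitness values (equivalently, residual mean square over mean
#' squared fitness).  Zero for a perfectly additive landscape.
#'
#' @param fit an `"additive_fit"` from [fit_additive()], or a `landscape`
#'   (fitted on the fly).
#' @return dimensionless nonnegative number.
#' @export
deviation_from_additivity <- function(fit) {
  if (inherits(fit, "landscape")) fit <- fit_additive(fit)
  stopifnot(inherits(fit, "additive_fit"))
  if (fit$ss_fitness == 0)
    stop("deviation from additivity is undefined for an all-zero landscape")
  fit$ss_residual / fit$ss_fitness
}

#' Fraction of fitness variability explained by the additive model
#'
#' One minus [deviation_from_additivity()]: compares the sum of squared
#' residuals with the sum of squared fitness values.
#'
#' @inheritParams deviation_from_additivity
#' @return a number no greater than 1.
#' @export
variability_explained <- function(fit) {
  if (inherits(fit, "landscape")) fit <- fit_additive(fit)
  1 - deviation_from_additivity(fit)
}

#' Local roughness
#'
#' For each genotype, the root-mean-square difference between its fitness
#' and the fitness of its present neighbours; those per-node RMS values are
#' then averaged arithmetically over the whole landscape.
#'
#' @param ls a `landscape`; every genotype must have at least one neighbour.
#' @return nonnegative number.
#' @export
local_roughness <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  adj <- landscape_adjacency(ls)
  deg <- lengths(adj)
  if (any(deg == 0L))
    stop("isolated genotype(s) with no neighbours: ",
         paste(ls$genotypes[deg == 0L], collapse = ", "))
  per_node <- vapply(seq_along(adj), function(i) {
    sqrt(mean((ls$fitness[i] - ls$fitness[adj[[i]]])^2))
  }, numeric(1))
  mean(per_node)
}

#' Fitness peaks of a landscape
#'
#' All genotypes with no strictly fitter neighbour.  "Fitter" means strictly
#' greater fitness, so members of flat plateaus qualify as peaks.
#'
#' @param ls a `landscape`
#' @return character vector of peak genotypes (lexicographic order).
#' @export
find_peaks <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  adj <- landscape_adjacency(ls)
  is_peak <- vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    !length(nb) || all(ls$fitness[nb] <= ls$fitness[i])
  }, logical(1))
  ls$genotypes[is_peak]
}

#' Tree component of a landscape
#'
#' The set of genotypes with at most one strictly fitter neighbour.  Uphill
#' walks restricted to the tree component never branch, so evolution on it
#' is deterministic under strong selection.  Always a superset of
#' [find_peaks()].
#'
#' @param ls a `landscape`
#' @return character vector of genotypes (lexicographic order).
#' @export
tree_component <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  adj <- landscape_adjacency(ls)
  in_tree <- vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    sum(ls$fitness[nb] > ls$fitness[i]) <= 1L
  }, logical(1))
  ls$genotypes[in_tree]
}

#' Mean shortest distance to the tree component
#'
#' Graph-shortest-path distance (edges are present Hamming-1 pairs) from
#' each genotype to the nearest member of the tree component, averaged over
#' the landscape; tree-component members contribute zero.  A genotype with
#' no path to the tree component is counted at the landscape's Hamming
#' diameter plus one, with a warning (this can only happen in landscapes
#' with several connected components).
#'
#' @param ls a `landscape`
#' @return nonnegative number.
#' @export
mean_tree_distance <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  adj <- landscape_adjacency(ls)
  tree <- tree_component(ls)
  src <- match(tree, ls$genotypes)
  n <- length(ls$genotypes)
  dist <- rep(NA_integer_, n)
  dist[src] <- 0L
  frontier <- src
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  if (anyNA(dist)) {
    diameter <- max(hamming_matrix(ls$genotypes))
    warning(sum(is.na(dist)),
            " genotype(s) cannot reach the tree component; counted at ",
            "diameter + 1 = ", diameter + 1L)
    dist[is.na(dist)] <- diameter + 1L
  }
  mean(dist)
}

#' Roughness report: the landscape characteristics in one pass
#'
#' Computes the four roughness statistics (deviation from additivity, local
#' roughness, peak fraction, mean distance to the tree component) together
#' with the additive model's explained variability and, optionally, the two
#' path-predictability statistics (monotonic path fraction and exhaustive
#' strong-selection mean path divergence).
#'
#' @param ls a `landscape`
#' @param paths logical; also compute the path-predictability statistics
#'   (exhaustive enumeration; feasible for small Hamming distances).
#' @return an object of class `"roughness_report"` (a named list).
#' @export
roughness_report <- function(ls, paths = TRUE) {
  stopifnot(inherits(ls, "landscape"))
  fit <- fit_additive(ls)
  peaks <- find_peaks(ls)
  out <- list(
    n = length(ls$genotypes),
    deviation_from_additivity = deviation_from_additivity(fit),
    variability_explained = variability_explained(fit),
    local_roughness = local_roughness(ls),
    n_peaks = length(peaks),
    peak_fraction = length(peaks) / length(ls$genotypes),
    mean_tree_distance = mean_tree_distance(ls))
  if (paths) {
    out$monotonic_path_fraction <- monotonic_path_fraction(ls)
    out$mean_path_divergence <- mean_path_divergence(ls)
  }
  class(out) <- "roughness_report"
  out
}

#' @export
print.roughness_report <- function(x, ...) {
  cat("Landscape characteristics:\n")
  for (nm in setdiff(names(x), "n"))
    cat(sprintf("  %-28s %g\n", nm, x[[nm]]))
  invisible(x)
}
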