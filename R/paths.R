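# Path predictability: monotonic path counting over the Hamming graph and
# mean path divergence of trajectory bundles.
#
# A "simple" path between two genotypes changes each differing site exactly
# once, directly to its target state, in some order; there are d! of them
# for genotypes differing at d sites, whatever the alphabet size.  A
# "monotonic" path is a simple path along which fitness strictly increases
# at every step (the paths available in the strong-selection limit).

#' Total number of simple paths between genotypes at Hamming distance d
#'
#' @param d nonnegative integer Hamming distance.
#' @return `factorial(d)`.
#' @export
total_simple_paths <- function(d) {
  stopifnot(all(d >= 0))
  factorial(d)
}

# Positions at which two genotypes differ.
differing_sites <- function(a, b) {
  which(charToRaw(a) != charToRaw(b))
}

# Replace sites `pos` of genotype `g` with the corresponding characters of
# `target`.
splice_sites <- function(g, target, pos) {
  ch <- strsplit(g, "", fixed = TRUE)[[1]]
  tg <- strsplit(target, "", fixed = TRUE)[[1]]
  ch[pos] <- tg[pos]
  paste(ch, collapse = "")
}

#' Count fitness-monotonic simple paths between two genotypes
#'
#' Counts the orderings of the sites differing between `start` and `peak`
#' such that every intermediate genotype is present in the landscape and
#' fitness strictly increases at every step.  Computed by dynamic
#' programming over subsets of the differing sites (site subsets determine
#' intermediate genotypes uniquely on simple paths), which agrees with
#' brute-force enumeration.
#'
#' @param ls a `landscape`
#' @param start,peak genotypes present in `ls`.
#' @return nonnegative integer-valued number (1 when `start == peak`:
#'   the empty path).
#' @export
count_monotonic_paths <- function(ls, start, peak) {
  stopifnot(inherits(ls, "landscape"))
  index <- landscape_index(ls)
  i0 <- genotype_position(ls, start, index)
  i1 <- genotype_position(ls, peak, index)
  if (is.na(i0)) stop("start genotype '", start, "' is not in the landscape")
  if (is.na(i1)) stop("peak genotype '", peak, "' is not in the landscape")
  sites <- differing_sites(start, peak)
  d <- length(sites)
  if (d == 0L) return(1)
  if (d > 25L) stop("subset dynamic programming limited to 25 differing sites")

  nsub <- bitwShiftL(1L, d)
  counts <- numeric(nsub)
  fit <- rep(NA_real_, nsub)     # fitness of the genotype for each subset
  present <- logical(nsub)
  counts[1L] <- 1                 # empty subset = start
  fit[1L] <- ls$fitness[i0]
  present[1L] <- TRUE
  # genotype string for subset S computed incrementally is not cheaper in R;
  # build it directly per subset
  for (S in seq_len(nsub - 1L)) {
    members <- which(bitwAnd(bitwShiftR(S, seq_len(d) - 1L), 1L) == 1L)
    g <- splice_sites(start, peak, sites[members])
    j <- genotype_position(ls, g, index)
    if (is.na(j)) next
    present[S + 1L] <- TRUE
    fS <- ls$fitness[j]
    fit[S + 1L] <- fS
    total <- 0
    for (m in members) {
      Sprev <- bitwAnd(S, bitwNot(bitwShiftL(1L, m - 1L)))
      if (present[Sprev + 1L] && fS > fit[Sprev + 1L])
        total <- total + counts[Sprev + 1L]
    }
    counts[S + 1L] <- total
  }
  counts[nsub]
}

#' Enumerate fitness-monotonic simple paths between two genotypes
#'
#' Recursive enumeration of the paths counted by
#' [count_monotonic_paths()].  Intended for landscapes with small Hamming
#' distances (the number of paths can grow as d!).
#'
#' @inheritParams count_monotonic_paths
#' @return list of character vectors, each a genotype sequence from `start`
#'   to `peak`; `list(start)` when the two coincide.
#' @export
enumerate_monotonic_paths <- function(ls, start, peak) {
  stopifnot(inherits(ls, "landscape"))
  index <- landscape_index(ls)
  if (is.na(genotype_position(ls, start, index)))
    stop("start genotype '", start, "' is not in the landscape")
  if (is.na(genotype_position(ls, peak, index)))
    stop("peak genotype '", peak, "' is not in the landscape")
  sites <- differing_sites(start, peak)
  if (!length(sites)) return(list(start))
  out <- list()
  recurse <- function(current, f_current, remaining, acc) {
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (s in remaining) {
      nxt <- splice_sites(current, peak, s)
      j <- genotype_position(ls, nxt, index)
      if (is.na(j)) next
      f_next <- ls$fitness[j]
      if (f_next > f_current)
        recurse(nxt, f_next, setdiff(remaining, s), c(acc, nxt))
    }
  }
  recurse(start, fitness_of(ls, start), sites, start)
  out
}

#' Fraction of monotonic paths to the main peak
#'
#' For each non-peak genotype x at Hamming distance d from the main peak,
#' the number of fitness-monotonic simple paths from x to the peak is
#' divided by the total number d! of simple paths; the fractions are then
#' averaged over all L - 1 non-peak genotypes.  Equals 1 on a strictly
#' additive landscape and decreases as the landscape gets rougher.
#'
#' @param ls a `landscape` with at least 2 entries.
#' @return a fraction in \[0, 1\].
#' @export
monotonic_path_fraction <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  if (length(ls$genotypes) < 2L)
    stop("need at least 2 genotypes")
  peak <- main_peak(ls)
  others <- setdiff(ls$genotypes, peak)
  fracs <- vapply(others, function(g) {
    d <- hamming_distance(g, peak)
    count_monotonic_paths(ls, g, peak) / total_simple_paths(d)
  }, numeric(1))
  mean(fracs)
}

#' A bundle of evolutionary paths sharing start and end points
#'
#' @param start,end genotype strings.
#' @param paths list of character vectors; every path must begin at `start`
#'   and end at `end` (consecutive nodes at Hamming distance 1).
#' @param probs occurrence probabilities, one per path; nonnegative,
#'   summing to 1.  Defaults to uniform.
#' @param n_obs number of observations (walks) behind the bundle; used as
#'   the weight when profiles are aggregated.  Defaults to the number of
#'   paths.
#' @return an object of class `"path_bundle"`.
#' @export
path_bundle <- function(start, end, paths, probs = NULL, n_obs = NULL) {
  if (!length(paths)) stop("a bundle needs at least one path")
  ok <- vapply(paths, function(p) {
    length(p) >= 1L && p[1] == start && p[length(p)] == end
  }, logical(1))
  if (!all(ok)) stop("every path must run from '", start, "' to '", end, "'")
  if (is.null(probs)) probs <- rep(1 / length(paths), length(paths))
  if (length(probs) != length(paths)) stop("one probability per path required")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("probabilities must be nonnegative and sum to 1")
  structure(list(start = start, end = end, paths = paths,
                 probs = probs / sum(probs),
                 n_obs = if (is.null(n_obs)) length(paths) else n_obs),
            class = "path_bundle")
}

#' @export
print.path_bundle <- function(x, ...) {
  cat(sprintf("Path bundle %s -> %s: %d distinct path(s), %d observation(s)\n",
              x$start, x$end, length(x$paths), x$n_obs))
  invisible(x)
}

#' Divergence between two evolutionary paths
#'
#' The directed divergence from p to q is the mean, over the genotypes of
#' p, of the shortest Hamming distance to any genotype of q.  By default
#' the two directed divergences are averaged, which makes the measure
#' symmetric; `symmetric = FALSE` returns the directed value.
#'
#' @param p,q character vectors of genotypes (non-empty).
#' @param symmetric logical.
#' @return nonnegative number; zero iff each path's genotypes all lie on
#'   the other path.
#' @export
path_divergence <- function(p, q, symmetric = TRUE) {
  if (!length(p) || !length(q)) stop("paths must be non-empty")
  H <- hamming_matrix(p, q)
  forward <- mean(apply(H, 1, min))
  if (!symmetric) return(forward)
  (forward + mean(apply(H, 2, min))) / 2
}

#' Mean divergence of a path bundle
#'
#' The expected divergence of two paths drawn independently (with
#' replacement) from the bundle according to their occurrence
#' probabilities: sum over path pairs (i, j) of P_i P_j D(p_i, p_j).
#' Small bundles are quantified pair by pair; internally the pairwise
#' divergence matrix is built in a vectorised pass over the bundle's
#' genotype set.
#'
#' @param b a [path_bundle()].
#' @return nonnegative number (0 for a single-path bundle).
#' @export
bundle_mean_divergence <- function(b) {
  stopifnot(inherits(b, "path_bundle"))
  D <- bundle_divergence_matrix(b)
  as.numeric(t(b$probs) %*% D %*% b$probs)
}

# Pairwise symmetric divergence matrix of the paths in a bundle,
# vectorised over the unique genotypes appearing in the bundle.
bundle_divergence_matrix <- function(b) {
  P <- length(b$paths)
  nodes <- unlist(b$paths, use.names = FALSE)
  path_id <- rep(seq_len(P), lengths(b$paths))
  uniq <- unique(nodes)
  node_u <- match(nodes, uniq)
  HU <- hamming_matrix(uniq)                  # U x U node distances
  # m[u, j] = min Hamming distance from unique node u to any node of path j
  m <- matrix(0L, length(uniq), P)
  for (j in seq_len(P)) {
    cols <- node_u[path_id == j]
    m[, j] <- if (length(cols) == 1L) HU[, cols]
              else do.call(pmin, lapply(cols, function(cc) HU[, cc]))
  }
  # G[i, j] = mean over nodes of path i of m[., j]
  G <- rowsum(m[node_u, , drop = FALSE], group = path_id) /
    as.vector(lengths(b$paths))
  (G + t(G)) / 2
}

#' Divergence profile of a collection of path bundles
#'
#' Bundle mean divergences are averaged arithmetically within groups of
#' bundles whose start and end points are separated by the same Hamming
#' distance.  The overall value is the mean over bundles weighted by each
#' bundle's observation count.
#'
#' @param bundles list of [path_bundle()] objects (at least one).
#' @return an object of class `"divergence_profile"`: list with
#'   `per_distance` (named numeric, names are Hamming distances),
#'   `n_bundles` per distance, `overall`, and `bundle_stats` (a data frame
#'   with one row per bundle: `distance`, `divergence`, `n_obs`).
#' @export
divergence_profile <- function(bundles) {
  if (!length(bundles)) stop("need at least one bundle")
  stopifnot(all(vapply(bundles, inherits, logical(1), "path_bundle")))
  d <- vapply(bundles, function(b) hamming_distance(b$start, b$end), numeric(1))
  div <- vapply(bundles, bundle_mean_divergence, numeric(1))
  w <- vapply(bundles, function(b) b$n_obs, numeric(1))
  ord <- sort(unique(d))
  per <- vapply(ord, function(dd) mean(div[d == dd]), numeric(1))
  nb <- vapply(ord, function(dd) sum(d == dd), numeric(1))
  structure(list(per_distance = stats::setNames(per, ord),
                 n_bundles = stats::setNames(nb, ord),
                 overall = stats::weighted.mean(div, w),
                 bundle_stats = data.frame(distance = d, divergence = div,
                                           n_obs = w)),
            class = "divergence_profile")
}

#' @export
print.divergence_profile <- function(x, ...) {
  cat("Mean path divergence by Hamming distance between endpoints:\n")
  print(round(x$per_distance, 4))
  cat(sprintf("Overall (weighted): %g\n", x$overall))
  invisible(x)
}

#' Exhaustive monotonic path bundles to the main peak
#'
#' For every non-peak genotype with at least one fitness-monotonic simple
#' path to the main peak, builds the bundle of all such paths with uniform
#' occurrence probabilities.  This is the exhaustive counterpart of the
#' strong-selection limit on landscapes where uphill moves are
#' equiprobable.
#'
#' @param ls a `landscape`
#' @return list of [path_bundle()] objects (possibly empty).
#' @export
monotonic_path_bundles <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  peak <- main_peak(ls)
  out <- list()
  for (g in setdiff(ls$genotypes, peak)) {
    paths <- enumerate_monotonic_paths(ls, g, peak)
    if (length(paths))
      out[[length(out) + 1L]] <- path_bundle(g, peak, paths,
                                            n_obs = length(paths))
  }
  out
}

#' Landscape-wide mean path divergence (exhaustive)
#'
#' Overall mean divergence of the exhaustive monotonic path bundles to the
#' main peak ([monotonic_path_bundles()]), weighted by bundle path counts.
#' Returns 0 when no genotype has a monotonic path to the peak.
#'
#' @param ls a `landscape`
#' @return nonnegative number.
#' @export
mean_path_divergence <- function(ls) {
  bundles <- monotonic_path_bundles(ls)
  if (!length(bundles)) return(0)
  divergence_profile(bundles)$overall
}
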