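# Assembly of folding fitness landscapes by mutational expansion around a
# robustly folding seed sequence, and simulated-annealing search for
# compact robust folders.
#
# Both algorithms talk to the folding physics through a pluggable "folding
# oracle" (a function from sequence to folding probability), so they can be
# exercised with deterministic mocks as well as the real simulator.

#' Radius of gyration of a conformation
#'
#' Root-mean-square distance of the monomers from their centroid.
#'
#' @param coords n x 3 coordinate matrix.
#' @return nonnegative scalar.
#' @export
radius_of_gyration <- function(coords) {
  if (!is.matrix(coords) || ncol(coords) != 3 || nrow(coords) < 1)
    stop("'coords' must be a non-empty n x 3 matrix")
  sqrt(mean(rowSums(sweep(coords, 2, colMeans(coords))^2)))
}

#' Folding oracle backed by the simulator
#'
#' Returns a function mapping a monomer sequence to its probability of
#' folding to the given reference native ensemble, estimated from
#' `n_samples` quenches.
#'
#' @param ref a `"native_ensemble"`.
#' @param n_samples quenches per probability estimate.
#' @param cfg a [physics_config()].
#' @param quench_fun quench backend (see [build_native_ensemble()]).
#' @return `function(sequence) -> probability`.
#' @export
make_folding_oracle <- function(ref, n_samples, cfg = physics_config(),
                                quench_fun = quench) {
  force(ref); force(n_samples); force(cfg); force(quench_fun)
  function(s) folding_probability(s, ref, n_samples, cfg, quench_fun)
}

#' Build configuration for landscape assembly
#'
#' @param p_min folding-probability inclusion threshold in (0, 1\].
#' @param max_sequences safety cap on the number of included sequences.
#' @return an object of class `"build_config"`.
#' @export
build_config <- function(p_min = 0.1, max_sequences = 100000L) {
  stopifnot(p_min > 0, p_min <= 1, max_sequences >= 1)
  structure(list(p_min = p_min, max_sequences = as.integer(max_sequences)),
            class = "build_config")
}

#' Assemble a folding fitness landscape by mutational expansion
#'
#' Breadth-first expansion from a seed sequence: every single-substitution
#' mutant (endpoint monomers immutable) is examined with the folding
#' oracle against the FIXED reference structure of the seed; mutants with
#' folding probability >= `p_min` are added to the landscape and their own
#' mutants examined in turn, until the frontier empties.  The landscape's
#' fitness column records the folding probability (convert downstream with
#' [misfolding_fitness()] or sample walks with `fitness = "misfolding"`).
#'
#' @param seed_seq monomer sequence whose native structure defines the
#'   reference (charged endpoints enforced).
#' @param oracle `function(sequence) -> folding probability`, e.g. from
#'   [make_folding_oracle()].
#' @param bc a [build_config()].
#' @param alphabet monomer alphabet (default the four standard types).
#' @param fixed_ends keep the first and last positions immutable.
#' @return a `landscape` whose fitness values are folding probabilities;
#'   attribute `"provenance"` records `n_examined` (oracle calls) and
#'   `n_included`.
#' @export
expand_landscape <- function(seed_seq, oracle, bc = build_config(),
                             alphabet = MONOMER_TYPES, fixed_ends = TRUE) {
  assert_monomer_sequence(seed_seq, require_charged_ends = fixed_ends)
  stopifnot(inherits(bc, "build_config"), is.function(oracle))
  p_seed <- oracle(seed_seq)
  n_examined <- 1L
  if (p_seed < bc$p_min)
    stop("seed sequence folds with probability ", p_seed,
         " < p_min = ", bc$p_min)
  L <- nchar(seed_seq)
  sites <- if (fixed_ends) seq(2L, L - 1L) else seq_len(L)
  included <- new.env(hash = TRUE)
  examined <- new.env(hash = TRUE)
  assign(seed_seq, p_seed, envir = included)
  assign(seed_seq, TRUE, envir = examined)
  frontier <- seed_seq
  while (length(frontier)) {
    nxt <- character(0)
    for (g in frontier) {
      chars <- strsplit(g, "", fixed = TRUE)[[1]]
      for (i in sites) {
        for (sym in alphabet) {
          if (sym == chars[i]) next
          mut <- chars; mut[i] <- sym
          mg <- paste(mut, collapse = "")
          if (!is.null(get0(mg, envir = examined, inherits = FALSE))) next
          assign(mg, TRUE, envir = examined)
          p <- oracle(mg)
          n_examined <- n_examined + 1L
          if (p >= bc$p_min) {
            assign(mg, p, envir = included)
            nxt <- c(nxt, mg)
          }
        }
      }
    }
    frontier <- nxt
    if (length(base::ls(included)) > bc$max_sequences)
      stop("landscape exceeded max_sequences = ", bc$max_sequences)
  }
  genos <- sort(base::ls(included), method = "radix")
  probs <- vapply(genos, function(g) get(g, envir = included), numeric(1))
  out <- landscape(genos, unname(probs), alphabet = alphabet)
  attr(out, "provenance") <- list(n_examined = n_examined,
                                  n_included = length(genos),
                                  p_min = bc$p_min, seed = seed_seq)
  out
}

#' Annealing configuration
#'
#' @param schedule positive, non-increasing vector of temperatures, one
#'   per proposal; an all-zero schedule degenerates to greedy hill
#'   climbing.
#' @return an object of class `"anneal_config"`.
#' @export
anneal_config <- function(schedule = 0.05 * 0.999^(0:999)) {
  stopifnot(length(schedule) >= 1, all(schedule >= 0),
            !is.unsorted(rev(schedule)))
  structure(list(schedule = schedule), class = "anneal_config")
}

#' Simulated-annealing search for high-objective sequences
#'
#' Metropolis search over monomer sequences: each proposal changes one
#' interior monomer (endpoints never mutate) to a random different type,
#' and is accepted if the objective improves or with probability
#' exp(delta / temperature) otherwise.  The default objective for finding
#' compact robust folders is the correct-folding probability divided by the
#' cube of the native conformation's radius of gyration; any
#' `function(sequence) -> value` to maximise can be supplied.
#'
#' @param start monomer sequence to start from.
#' @param objective `function(sequence) -> numeric` to maximise.
#' @param ac an [anneal_config()].
#' @param alphabet monomer alphabet.
#' @param fixed_ends keep endpoint monomers immutable.
#' @return list with `best` (best-seen sequence), `best_objective`,
#'   `n_accepted`.
#' @export
anneal_search <- function(start, objective, ac = anneal_config(),
                          alphabet = MONOMER_TYPES, fixed_ends = TRUE) {
  assert_monomer_sequence(start, require_charged_ends = fixed_ends)
  stopifnot(is.function(objective), inherits(ac, "anneal_config"))
  L <- nchar(start)
  sites <- if (fixed_ends) seq(2L, L - 1L) else seq_len(L)
  current <- start
  f_current <- objective(current)
  best <- current; f_best <- f_current
  n_accepted <- 0L
  chars <- strsplit(current, "", fixed = TRUE)[[1]]
  for (temp in ac$schedule) {
    i <- if (length(sites) == 1L) sites else sample(sites, 1L)
    choices <- setdiff(alphabet, chars[i])
    sym <- if (length(choices) == 1L) choices else sample(choices, 1L)
    prop_chars <- chars; prop_chars[i] <- sym
    proposal <- paste(prop_chars, collapse = "")
    f_prop <- objective(proposal)
    delta <- f_prop - f_current
    accept <- delta > 0 ||
      (temp > 0 && stats::runif(1) < exp(delta / temp))
    if (accept) {
      current <- proposal; chars <- prop_chars; f_current <- f_prop
      n_accepted <- n_accepted + 1L
      if (f_current > f_best) { best <- current; f_best <- f_current }
    }
  }
  list(best = best, best_objective = f_best, n_accepted = n_accepted)
}

#' Compactness-weighted folding objective
#'
#' The simulated-annealing objective for compact robust folders: the
#' probability of folding to the sequence's own native ensemble divided by
#' the cube of the ensemble's mean radius of gyration.
#'
#' @param n_quench quenches used to build each sequence's native ensemble.
#' @param n_samples quenches per folding-probability estimate.
#' @param cfg a [physics_config()].
#' @param quench_fun quench backend.
#' @return `function(sequence) -> numeric` (0 when no reproducible fold
#'   exists).
#' @export
compact_folder_objective <- function(n_quench = 20, n_samples = 10,
                                     cfg = physics_config(),
                                     quench_fun = quench) {
  force(n_quench); force(n_samples); force(cfg); force(quench_fun)
  function(s) {
    ens <- tryCatch(build_native_ensemble(s, n_quench, cfg, quench_fun),
                    error = function(e) NULL)
    if (is.null(ens)) return(0)
    p <- folding_probability(s, ens, n_samples, cfg, quench_fun)
    rg <- mean(vapply(ens$members, radius_of_gyration, numeric(1)))
    p / rg^3
  }
}
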