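# End-to-end toy pipeline: regenerates the package's headline analyses on
# synthetic noisy-additive landscapes — roughness characteristics across a
# noise family, original-versus-scrambled comparisons, roughness/divergence
# correlations, and a selection-pressure sweep.

#' Run the toy replication pipeline on synthetic landscapes
#'
#' Generates a family of noisy-additive landscapes over a grid of
#' multiplicative-noise exponents, computes the six landscape
#' characteristics for each landscape and for scrambled copies, summarises
#' original-versus-scrambled contrasts and the rank correlations between
#' roughness measures and path divergence, and runs a selection-pressure
#' sweep on one low-noise family member.  All randomness flows from
#' `seed`.  Results are returned as a nested list and, when `out_dir` is
#' given, also written as JSON files (`family.json`,
#' `scramble_comparison.json`, `correlations.json`, `sweep.json`,
#' `manifest.json`).
#'
#' @param seed integer root seed.
#' @param out_dir optional output directory (created if needed).
#' @param length sites per genotype of the synthetic landscapes.
#' @param alphabet genotype alphabet.
#' @param nu_grid multiplicative-noise exponents of the family.
#' @param n_seeds landscapes per noise level.
#' @param n_scrambles scrambled copies per landscape.
#' @param pressures N_e * A values of the selection sweep.
#' @param walks_per_start walks per start in the sweep.
#' @return the report list, invisibly when `out_dir` is given.
#' @export
replicate_toy <- function(seed = 1, out_dir = NULL,
                          length = 5, alphabet = c("0", "1"),
                          nu_grid = c(0.5, 1, 2, 4), n_seeds = 20,
                          n_scrambles = 5,
                          pressures = c(0.001, 0.01, 0.1, 1, 10, 100),
                          walks_per_start = 100) {
  t0 <- proc.time()[["elapsed"]]
  seeds <- derive_seed(seed, "family") + seq_len(n_seeds) - 1L
  family <- noise_family(length, alphabet, nu_grid = nu_grid, seeds = seeds)

  rows <- list()
  scram_rows <- list()
  for (ls in family) {
    rep_orig <- roughness_report(ls, paths = TRUE)
    rows[[length(rows) + 1L]] <- c(
      noise_level = attr(ls, "noise_level"), seed = attr(ls, "seed"),
      unclass(rep_orig)[c("n", "deviation_from_additivity",
                          "local_roughness", "peak_fraction",
                          "mean_tree_distance", "monotonic_path_fraction",
                          "mean_path_divergence")])
    for (k in seq_len(n_scrambles)) {
      sc <- with_seed(derive_seed(seed, paste0("scram", attr(ls, "seed"),
                                               "_", attr(ls, "noise_level"),
                                               "_", k)),
                      scramble(ls))
      peaks <- find_peaks(sc)
      scram_rows[[length(scram_rows) + 1L]] <- c(
        noise_level = attr(ls, "noise_level"),
        peak_fraction = length(peaks) / n_genotypes(sc),
        monotonic_path_fraction = monotonic_path_fraction(sc),
        mean_path_divergence = mean_path_divergence(sc))
    }
  }
  fam <- as.data.frame(do.call(rbind, lapply(rows, unlist)))
  scr <- as.data.frame(do.call(rbind, lapply(scram_rows, unlist)))

  comparison <- list(
    original = list(peak_fraction = mean(fam$peak_fraction),
                    monotonic_path_fraction = mean(fam$monotonic_path_fraction),
                    mean_path_divergence = mean(fam$mean_path_divergence)),
    scrambled = list(peak_fraction = mean(scr$peak_fraction),
                     monotonic_path_fraction = mean(scr$monotonic_path_fraction),
                     mean_path_divergence = mean(scr$mean_path_divergence)))

  correlations <- list(
    divergence_vs_deviation =
      stats::cor(fam$mean_path_divergence, fam$deviation_from_additivity,
                 method = "spearman"),
    divergence_vs_peak_fraction =
      stats::cor(fam$mean_path_divergence, fam$peak_fraction,
                 method = "spearman"),
    divergence_vs_tree_distance =
      stats::cor(fam$mean_path_divergence, fam$mean_tree_distance,
                 method = "spearman"),
    divergence_vs_local_roughness =
      stats::cor(fam$mean_path_divergence, fam$local_roughness,
                 method = "spearman"))
  correlations$sign_pattern <- paste0(
    ifelse(correlations$divergence_vs_deviation < 0, "-", "+"),
    ifelse(correlations$divergence_vs_peak_fraction < 0, "-", "+"),
    ifelse(correlations$divergence_vs_tree_distance < 0, "-", "+"),
    ifelse(correlations$divergence_vs_local_roughness < 0, "-", "+"))

  sweep_ls <- with_seed(derive_seed(seed, "sweep_landscape"),
                        generate_noisy_additive(length, alphabet,
                                                noise_spec(nu = 0.5)))
  sweep <- with_seed(derive_seed(seed, "sweep"),
                     selection_sweep(sweep_ls, pressures,
                                     walks_per_start = walks_per_start))
  sweep_tbl <- lapply(sweep, function(pr)
    list(per_distance = as.list(pr$per_distance), overall = pr$overall))

  report <- list(
    family = fam,
    scrambles = scr,
    comparison = comparison,
    correlations = correlations,
    sweep = sweep_tbl,
    manifest = list(seed = seed, length = length,
                    alphabet = paste(alphabet, collapse = ""),
                    nu_grid = nu_grid, n_seeds = n_seeds,
                    n_scrambles = n_scrambles, pressures = pressures,
                    walks_per_start = walks_per_start,
                    elapsed_s = proc.time()[["elapsed"]] - t0,
                    package_version = as.character(utils::packageVersion("ruggedpaths"))))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(fam, file.path(out_dir, "family.json"),
                         dataframe = "rows", digits = NA)
    jsonlite::write_json(comparison, file.path(out_dir, "scramble_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(correlations, file.path(out_dir, "correlations.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(sweep_tbl, file.path(out_dir, "sweep.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}
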