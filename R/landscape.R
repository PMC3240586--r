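# Genotype-fitness landscape container and Hamming-graph operations.
#
# A landscape maps fixed-length genotype strings over a finite alphabet to
# real fitness values.  Adjacency is implicit: two genotypes are neighbours
# iff their Hamming distance is 1 and both are present in the landscape.
# Genotypes absent from the landscape are treated as inviable everywhere
# downstream (effectively fitness -Inf).

#' Construct a fitness landscape
#'
#' A landscape is a mapping from fixed-length genotype strings over a finite
#' alphabet to finite real fitness values.  Genotypes are stored in
#' lexicographic (C locale) order so that all operations with documented
#' tie-breaks are deterministic.
#'
#' @param genotypes character vector of genotype strings, all of the same
#'   nonzero length, no duplicates.  Symbols must be single-byte (ASCII).
#' @param fitness numeric vector of finite fitness values, one per genotype.
#' @param alphabet optional character vector of allowed symbols; defaults to
#'   the set of symbols observed in `genotypes`.  Supplying it explicitly
#'   matters when the landscape does not exhaust the alphabet (e.g. a
#'   4-letter alphabet observed only partially), since the alphabet sets the
#'   neighbourhood size in Hamming space.
#' @return An object of class `"landscape"`: a list with elements
#'   `genotypes`, `fitness`, `alphabet`, `length` (sites per genotype).
#' @examples
#' ls <- landscape(c("00", "01", "10", "11"), c(0.3, 0.6, 0.5, 1.0))
#' main_peak(ls)
#' @export
landscape <- function(genotypes, fitness, alphabet = NULL) {
  if (!is.character(genotypes) || length(genotypes) < 1L)
    stop("'genotypes' must be a non-empty character vector")
  if (!is.numeric(fitness) || length(fitness) != length(genotypes))
    stop("'fitness' must be numeric and match 'genotypes' in length")
  if (anyNA(genotypes)) stop("genotypes must not contain NA")
  if (any(!is.finite(fitness))) stop("all fitness values must be finite")
  dup <- duplicated(genotypes)
  if (any(dup))
    stop("duplicate genotypes: ", paste(unique(genotypes[dup]), collapse = ", "))
  L <- unique(nchar(genotypes, type = "bytes"))
  if (length(L) != 1L)
    stop("all genotypes must have the same length")
  if (L == 0L) stop("genotypes must be non-empty strings")
  observed <- sort(unique(unlist(strsplit(genotypes, "", fixed = TRUE))),
                   method = "radix")
  if (is.null(alphabet)) {
    alphabet <- observed
  } else {
    alphabet <- sort(unique(as.character(alphabet)), method = "radix")
    if (any(nchar(alphabet, type = "bytes") != 1L))
      stop("alphabet symbols must be single characters")
    if (!all(observed %in% alphabet))
      stop("genotypes use symbols outside the declared alphabet: ",
           paste(setdiff(observed, alphabet), collapse = ", "))
  }
  ord <- order(genotypes, method = "radix")
  obj <- list(genotypes = genotypes[ord],
              fitness = as.numeric(fitness)[ord],
              alphabet = alphabet,
              length = as.integer(L))
  class(obj) <- "landscape"
  obj
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("Fitness landscape: %d genotypes, %d sites, |alphabet| = %d\n",
              length(x$genotypes), x$length, length(x$alphabet)))
  cat(sprintf("  fitness range [%g, %g], main peak %s\n",
              min(x$fitness), max(x$fitness), main_peak(x)))
  invisible(x)
}

#' Number of genotypes in a landscape
#' @param ls a `landscape`
#' @return integer count of genotypes present.
#' @export
n_genotypes <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  length(ls$genotypes)
}

#' @export
as.data.frame.landscape <- function(x, ...) {
  data.frame(genotype = x$genotypes, fitness = x$fitness,
             stringsAsFactors = FALSE)
}

# Hashed genotype -> index lookup.  Rebuilt on demand; landscapes are small
# enough that construction is cheap relative to repeated linear match().
landscape_index <- function(ls) {
  env <- new.env(hash = TRUE, size = max(length(ls$genotypes), 29L))
  for (i in seq_along(ls$genotypes)) assign(ls$genotypes[i], i, envir = env)
  env
}

genotype_position <- function(ls, g, index = NULL) {
  if (!is.null(index)) {
    i <- get0(g, envir = index, inherits = FALSE)
    if (is.null(i)) NA_integer_ else i
  } else {
    match(g, ls$genotypes)
  }
}

#' Fitness of one or more genotypes
#'
#' @param ls a `landscape`
#' @param g character vector of genotypes
#' @return numeric vector of fitness values; absent genotypes give `NA`.
#' @export
fitness_of <- function(ls, g) {
  stopifnot(inherits(ls, "landscape"))
  ls$fitness[match(g, ls$genotypes)]
}

#' Hamming distance between genotype strings
#'
#' Number of sites at which two equal-length strings differ.
#'
#' @param a,b character vectors (recycled to a common length pairwise).
#' @return integer vector of distances.
#' @examples
#' hamming_distance("00000", "11111")  # 5
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) {
    ra <- charToRaw(a[i]); rb <- charToRaw(b[i])
    if (length(ra) != length(rb))
      stop("genotypes must have equal length: '", a[i], "' vs '", b[i], "'")
    out[i] <- sum(ra != rb)
  }
  out
}

# Split genotypes into an n x L character matrix.
genotype_matrix <- function(genotypes) {
  if (length(genotypes) == 0L) return(matrix(character(0), 0, 0))
  matrix(unlist(strsplit(genotypes, "", fixed = TRUE), use.names = FALSE),
         nrow = length(genotypes), byrow = TRUE)
}

# Pairwise Hamming distances between two genotype sets (integer matrix).
hamming_matrix <- function(a, b = a) {
  ma <- genotype_matrix(a); mb <- genotype_matrix(b)
  if (ncol(ma) != ncol(mb)) stop("genotypes must have equal length")
  H <- matrix(0L, nrow(ma), nrow(mb))
  for (s in seq_len(ncol(ma)))
    H <- H + outer(ma[, s], mb[, s], "!=")
  H
}

# All single-site mutants of genotype g over the landscape's alphabet,
# in deterministic (site-major, symbol lexicographic) order.
all_mutants <- function(g, alphabet) {
  chars <- strsplit(g, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- character(L * (length(alphabet) - 1L))
  k <- 0L
  for (i in seq_len(L)) {
    for (sym in alphabet) {
      if (sym == chars[i]) next
      mut <- chars
      mut[i] <- sym
      k <- k + 1L
      out[k] <- paste(mut, collapse = "")
    }
  }
  out[seq_len(k)]
}

#' Present Hamming-1 neighbours of a genotype
#'
#' Returns the genotypes present in the landscape at Hamming distance
#' exactly 1 from `g`, in lexicographic order.
#'
#' @param ls a `landscape`
#' @param g a genotype present in `ls`
#' @return character vector (possibly empty).
#' @export
neighbors <- function(ls, g) {
  stopifnot(inherits(ls, "landscape"))
  if (is.na(match(g, ls$genotypes)))
    stop("genotype '", g, "' is not in the landscape")
  cand <- all_mutants(g, ls$alphabet)
  sort(cand[cand %in% ls$genotypes], method = "radix")
}

# Adjacency list: for each genotype index, integer indices of its present
# neighbours (ascending, hence lexicographic given the sorted store).
landscape_adjacency <- function(ls) {
  idx <- landscape_index(ls)
  n <- length(ls$genotypes)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- all_mutants(ls$genotypes[i], ls$alphabet)
    hits <- vapply(cand, function(g) {
      j <- get0(g, envir = idx, inherits = FALSE)
      if (is.null(j)) NA_integer_ else j
    }, integer(1), USE.NAMES = FALSE)
    adj[[i]] <- sort(hits[!is.na(hits)])
  }
  adj
}

#' Main peak of a landscape
#'
#' The genotype with maximal fitness.  Exact ties are broken by taking the
#' lexicographically smallest genotype, so the result is reproducible.
#'
#' @param ls a `landscape`
#' @return a genotype string.
#' @export
main_peak <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  # store is lexicographically sorted, so the first maximum is the answer
  ls$genotypes[which.max(ls$fitness)]
}

#' Connected component of a landscape around a genotype
#'
#' Breadth-first search over present Hamming-1 edges starting from `g`;
#' returns the sub-landscape of all reachable genotypes.
#'
#' @param ls a `landscape`
#' @param g a genotype present in `ls`
#' @return a `landscape` restricted to the component containing `g`.
#' @export
connected_component <- function(ls, g) {
  stopifnot(inherits(ls, "landscape"))
  start <- match(g, ls$genotypes)
  if (is.na(start)) stop("genotype '", g, "' is not in the landscape")
  adj <- landscape_adjacency(ls)
  n <- length(ls$genotypes)
  seen <- logical(n)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  landscape(ls$genotypes[seen], ls$fitness[seen], alphabet = ls$alphabet)
}

#' Write a landscape to a TSV file
#'
#' Two tab-separated columns, `genotype` and `fitness`, with a header line.
#' Fitness is serialised with 17 significant digits so that a write/read
#' cycle reproduces the landscape exactly.
#'
#' @param ls a `landscape`
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(ls, path) {
  stopifnot(inherits(ls, "landscape"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("genotype\tfitness", con)
  writeLines(paste(ls$genotypes, sprintf("%.17g", ls$fitness), sep = "\t"),
             con)
  invisible(path)
}

#' Read a landscape from a two-column TSV file
#'
#' Expects the format produced by [write_landscape()]: a header line
#' `genotype<TAB>fitness` followed by one row per genotype.  Lines starting
#' with `#` are ignored.
#'
#' @param path input file path.
#' @param alphabet optional explicit alphabet (see [landscape()]).
#' @return a `landscape`.
#' @export
read_landscape <- function(path, alphabet = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", colClasses = c("character", "numeric"),
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("genotype", "fitness") %in% names(df)))
    stop("expected columns 'genotype' and 'fitness' in ", path)
  landscape(df$genotype, df$fitness, alphabet = alphabet)
}

#' Loading specification for experimental genotype-fitness tables
#'
#' Describes how a combinatorial mutant table should be interpreted:
#' whether genotypes appear as explicit strings or as one 0/1
#' presence/absence column per named substitution, which fitness-proxy
#' transform to apply (e.g. log for minimum inhibitory concentrations),
#' and whether to min-max normalise the result onto \[0, 1\].
#'
#' @param mode `"genotype"` (an explicit genotype string column) or
#'   `"binary"` (one 0/1 column per substitution; the genotype string is
#'   their concatenation in column order).
#' @param genotype_col name of the genotype column (`mode = "genotype"`).
#' @param substitution_cols character vector of 0/1 column names
#'   (`mode = "binary"`).
#' @param value_col name of the fitness(-proxy) column.
#' @param transform `"identity"` or `"log"` (decimal logarithm; requires
#'   strictly positive values).
#' @param normalize logical; min-max map fitness onto \[0, 1\] after the
#'   transform.  A landscape with a single distinct value maps to 0.
#' @param transform_first logical; apply the proxy transform before
#'   normalisation (default).  Ordering only matters for the log transform.
#' @return an object of class `"load_spec"`.
#' @export
load_spec <- function(mode = c("genotype", "binary"),
                      genotype_col = "genotype",
                      substitution_cols = NULL,
                      value_col = "fitness",
                      transform = c("identity", "log"),
                      normalize = FALSE,
                      transform_first = TRUE) {
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  if (mode == "binary" && (is.null(substitution_cols) || !length(substitution_cols)))
    stop("binary mode requires 'substitution_cols'")
  structure(list(mode = mode, genotype_col = genotype_col,
                 substitution_cols = substitution_cols, value_col = value_col,
                 transform = transform, normalize = normalize,
                 transform_first = transform_first),
            class = "load_spec")
}

apply_proxy_transform <- function(values, transform, rows) {
  if (transform == "log") {
    bad <- which(values <= 0)
    if (length(bad))
      stop("log transform requires strictly positive values; offending row(s): ",
           paste(rows[bad], collapse = ", "))
    values <- log10(values)
  }
  values
}

minmax_normalize <- function(values) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Load an experimental genotype-fitness table
#'
#' Reads a TSV mutant table according to a [load_spec()]: either an explicit
#' genotype column, or the binary-library convention where each of a handful
#' of named substitutions has its own 0/1 presence column (the genotype is
#' their concatenation).  The fitness proxy is transformed (optionally by a
#' decimal log, as is conventional for minimum inhibitory concentrations)
#' and optionally min-max normalised onto \[0, 1\].
#'
#' @param path TSV file path (header row required; `#` comments allowed).
#' @param spec a [load_spec()].
#' @param alphabet optional explicit alphabet for the resulting landscape.
#' @return a `landscape`.
#' @export
load_landscape <- function(path, spec = load_spec(), alphabet = NULL) {
  stopifnot(inherits(spec, "load_spec"))
  # read everything as character so genotype strings like "00" survive;
  # numeric columns are converted explicitly below
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          quote = "", check.names = FALSE,
                          colClasses = "character")
  if (!spec$value_col %in% names(df))
    stop("value column '", spec$value_col, "' not found in ", path)
  if (spec$mode == "genotype") {
    if (!spec$genotype_col %in% names(df))
      stop("genotype column '", spec$genotype_col, "' not found in ", path)
    genos <- as.character(df[[spec$genotype_col]])
  } else {
    missing_cols <- setdiff(spec$substitution_cols, names(df))
    if (length(missing_cols))
      stop("substitution column(s) not found: ", paste(missing_cols, collapse = ", "))
    cols <- lapply(spec$substitution_cols, function(cn) {
      v <- df[[cn]]
      if (!all(v %in% c(0, 1)))
        stop("substitution column '", cn, "' must be 0/1")
      as.integer(v)
    })
    genos <- do.call(paste0, cols)
  }
  if (anyDuplicated(genos))
    stop("duplicate genotypes in ", path, ": ",
         paste(unique(genos[duplicated(genos)]), collapse = ", "))
  values <- as.numeric(df[[spec$value_col]])
  rows <- seq_along(values) + 1L  # 1-based data rows after the header
  if (spec$transform_first) {
    values <- apply_proxy_transform(values, spec$transform, rows)
    if (spec$normalize) values <- minmax_normalize(values)
  } else {
    if (spec$normalize) values <- minmax_normalize(values)
    values <- apply_proxy_transform(values, spec$transform, rows)
  }
  landscape(genos, values, alphabet = alphabet)
}

#' Min-max normalise a landscape onto \[0, 1\]
#'
#' @param ls a `landscape`
#' @return a `landscape` with fitness linearly rescaled so the minimum maps
#'   to 0 and the maximum to 1 (a constant landscape maps to 0).
#' @export
normalize_landscape <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  landscape(ls$genotypes, minmax_normalize(ls$fitness), alphabet = ls$alphabet)
}
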