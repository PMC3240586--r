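# Landscape container, Hamming-graph operations and file I/O.

test_that("hamming_distance counts differing sites and checks lengths", {
  expect_identical(hamming_distance("AAA", "AAA"), 0L)
  expect_identical(hamming_distance("00000", "11111"), 5L)
  expect_identical(hamming_distance("HP+-", "HP-+"), 2L)
  expect_identical(hamming_distance(c("00", "01"), c("01", "01")), c(1L, 0L))
  expect_error(hamming_distance("00", "000"), "equal length")
})

test_that("landscape construction validates its invariants", {
  expect_error(landscape(character(0), numeric(0)), "non-empty")
  expect_error(landscape(c("00", "00"), c(1, 2)), "duplicate")
  expect_error(landscape(c("0", "00"), c(1, 2)), "same length")
  expect_error(landscape("01", Inf), "finite")
  expect_error(landscape("01", 1, alphabet = c("0")), "outside")
  ls <- landscape(c("10", "01"), c(2, 1))
  expect_identical(ls$genotypes, c("01", "10"))  # lexicographic store
  expect_identical(fitness_of(ls, c("10", "01", "11")), c(2, 1, NA))
})

test_that("neighbors returns present Hamming-1 genotypes in order", {
  ls <- cube_landscape(2, 1:4)
  expect_identical(neighbors(ls, "00"), c("01", "10"))
  sparse <- landscape(c("00", "11"), c(1, 2))
  expect_identical(neighbors(sparse, "00"), character(0))
  expect_error(neighbors(sparse, "01"), "not in the landscape")
  # full 4-letter alphabet, length 2: (|alphabet| - 1) * length neighbours
  genos <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           function(a, b) paste0(b, a)))
  full4 <- landscape(genos, seq_along(genos))
  for (g in c("AA", "CT", "GG"))
    expect_length(neighbors(full4, g), 6L)
})

test_that("neighbour relation is symmetric on random landscapes", {
  set.seed(101)
  for (rep in 1:10) {
    ls <- random_landscape(4, p_keep = 0.6)
    for (g in ls$genotypes) {
      for (nb in neighbors(ls, g))
        expect_true(g %in% neighbors(ls, nb))
    }
  }
})

test_that("main_peak is the fitness maximum with lexicographic ties", {
  expect_identical(main_peak(landscape(c("0", "1"), c(1, 2))), "1")
  expect_identical(main_peak(cube_landscape(2, 1)), "00")
  set.seed(7)
  ls <- generate_noisy_additive(4, noise = noise_spec(kind = "none"),
                                peak = "1111")
  expect_identical(main_peak(ls), "1111")
})

test_that("write/read round-trips landscapes exactly", {
  set.seed(11)
  for (rep in 1:5) {
    ls <- random_landscape(4, p_keep = 0.7)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_landscape(ls, path)
    back <- read_landscape(path)
    expect_identical(back$genotypes, ls$genotypes)
    expect_identical(back$fitness, ls$fitness)  # bit-exact via %.17g
  }
  ls2 <- landscape(c("00", "01"), c(0.1, 0.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_landscape(ls2, path)
  expect_length(readLines(path), 3L)  # header + 2 rows
})

test_that("load_landscape handles the binary-library convention", {
  # 32-row table: 5 named substitutions as 0/1 columns plus a value column
  subs <- paste0("m", 1:5)
  grid <- expand.grid(rep(list(0:1), 5))[, 5:1]
  names(grid) <- subs
  grid$mic <- 2^(rowSums(grid[subs]) + 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(grid, path, sep = "\t", row.names = FALSE, quote = FALSE)
  ls <- load_landscape(path, load_spec(mode = "binary",
                                       substitution_cols = subs,
                                       value_col = "mic",
                                       transform = "log", normalize = TRUE))
  expect_identical(n_genotypes(ls), 32L)
  expect_identical(main_peak(ls), "11111")
  expect_equal(range(ls$fitness), c(0, 1))
})

test_that("log transform + normalisation maps decades onto {0, 1/2, 1}", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genotype\tfitness", "00\t10", "01\t100", "11\t1000"), path)
  ls <- load_landscape(path, load_spec(transform = "log", normalize = TRUE))
  expect_equal(unname(fitness_of(ls, c("00", "01", "11"))), c(0, 0.5, 1))
})

test_that("loader rejects bad tables and degrades single rows gracefully", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genotype\tfitness", "00\t1", "00\t2"), path)
  expect_error(load_landscape(path), "duplicate")
  writeLines(c("genotype\tfitness", "00\t1", "01\t-2"), path)
  expect_error(load_landscape(path, load_spec(transform = "log")), "row")
  writeLines(c("genotype\tfitness", "00\t42"), path)
  ls <- load_landscape(path, load_spec(normalize = TRUE))
  expect_identical(unname(ls$fitness), 0)  # degenerate range maps to 0
})

test_that("connected_component matches a BFS oracle", {
  full <- cube_landscape(3, stats::runif(8))
  cc <- connected_component(full, "000")
  expect_identical(cc$genotypes, full$genotypes)

  ls <- landscape(c("00", "01", "11", "33"), c(1, 2, 3, 4),
                  alphabet = c("0", "1", "3"))
  cc <- connected_component(ls, "00")
  expect_identical(cc$genotypes, c("00", "01", "11"))
  d <- bf_bfs_distance(ls, "00")
  expect_identical(sort(names(d)[!is.na(d)]), cc$genotypes)

  iso <- connected_component(landscape(c("00", "11"), c(1, 2)), "11")
  expect_identical(iso$genotypes, "11")
})

test_that("normalisation maps onto [0,1] with the extremes attained", {
  set.seed(3)
  ls <- normalize_landscape(random_landscape(4))
  expect_equal(min(ls$fitness), 0)
  expect_equal(max(ls$fitness), 1)
})
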