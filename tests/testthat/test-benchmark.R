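# benchmark harness, deviation statistics and result serialization

test_that("single-molecule single-guess sweep gives a degenerate zero MAD", {
  bench <- run_benchmark(molecules = "He", guesses = "HF", modes = "B",
                         config = qsgw_config(n_grid = 16), basis = "et-min")
  expect_equal(nrow(bench$results), 1L)
  stats <- deviation_stats(bench, mode = "B")
  expect_equal(stats$mad_ip, 0)
  expect_equal(stats$max_ea, 0)
})

test_that("injected identical runs give exactly zero deviations", {
  # duplicate one run across fake guesses
  row <- data.frame(molecule = "X", guess = c("PBE", "PBE0", "HF"),
                    mode = "B", converged = TRUE, iterations = 5L,
                    IP_eV = 12.345, EA_eV = -1.234, error = NA_character_)
  bench <- structure(list(results = row, runs = list(),
                          guesses = c("PBE", "PBE0", "HF"), modes = "B"),
                     class = "qsgw_benchmark")
  stats <- deviation_stats(bench)
  expect_equal(stats$mad_ip, 0)
  expect_equal(stats$mad_ea, 0)
  expect_equal(stats$max_ip, 0)
})

test_that("deviation statistics match a by-hand recomputation", {
  df <- data.frame(
    molecule = rep(c("A", "B"), each = 3),
    guess = rep(c("PBE", "PBE0", "HF"), 2), mode = "B",
    converged = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    iterations = 5L,
    IP_eV = c(10.000, 10.002, 10.001, 8.0, 8.1, 8.2),
    EA_eV = c(-1.000, -1.001, -1.003, 0.5, 0.4, 0.3),
    error = NA_character_)
  bench <- structure(list(results = df, runs = list(),
                          guesses = c("PBE", "PBE0", "HF"), modes = "B"),
                     class = "qsgw_benchmark")
  stats <- deviation_stats(bench)
  # molecule B is excluded (one non-converged run); A's pairwise deviations:
  # IP: |0.002|, |0.001|, |0.001| -> mean 4/3 meV, max 2 meV
  expect_equal(stats$excluded, "B")
  expect_equal(stats$mad_ip, mean(c(2, 1, 1)), tolerance = 1e-12)
  expect_equal(stats$max_ip, 2, tolerance = 1e-12)
  expect_equal(stats$mad_ea, mean(c(1, 3, 2)), tolerance = 1e-12)
  expect_equal(stats$max_ea, 3, tolerance = 1e-12)
})

test_that("mode statistics compare constructions over jointly converged runs", {
  df <- data.frame(
    molecule = rep(c("A", "B"), each = 2),
    guess = "PBE0", mode = rep(c("A", "B"), 2),
    converged = c(TRUE, TRUE, FALSE, TRUE), iterations = 5L,
    IP_eV = c(10.010, 10.000, 8.0, 8.1),
    EA_eV = c(-1.000, -1.020, 0.5, 0.4),
    error = NA_character_)
  bench <- structure(list(results = df, runs = list(), guesses = "PBE0",
                          modes = c("A", "B")), class = "qsgw_benchmark")
  stats <- mode_stats(bench, guess = "PBE0")
  expect_equal(stats$excluded, "B")
  expect_equal(stats$mean_dip, 10, tolerance = 1e-9)
  expect_equal(stats$mean_dea, 20, tolerance = 1e-9)
  expect_equal(stats$mean_all, 15, tolerance = 1e-9)
})

test_that("failed runs are recorded without aborting the sweep", {
  # a molecule whose basis has no Cl entry in et-min forces a caught error
  bench <- run_benchmark(molecules = c("He", "CH3Cl"), guesses = "HF",
                         modes = "B", config = qsgw_config(n_grid = 16),
                         basis = "et-min")
  expect_equal(nrow(bench$results), 2L)
  ok <- bench$results[bench$results$molecule == "He", ]
  bad <- bench$results[bench$results$molecule == "CH3Cl", ]
  expect_true(ok$converged)
  expect_false(bad$converged)
  expect_match(bad$error, "no definition")
})

test_that("benchmark sweeps are deterministic", {
  cfg <- qsgw_config(n_grid = 16)
  b1 <- run_benchmark(molecules = "He", guesses = "HF", modes = "B",
                      config = cfg, basis = "et-min")
  b2 <- run_benchmark(molecules = "He", guesses = "HF", modes = "B",
                      config = cfg, basis = "et-min")
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(b1$results, f1, digits = NA)
  jsonlite::write_json(b2$results, f2, digits = NA)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("results round-trip through JSON with schema validation", {
  r <- cached("qsgw|He|HF", run_qsgw(state = mf("He", "et-min", "HF"),
                                     config = qsgw_config(n_grid = 16)))
  f <- withr::local_tempfile(fileext = ".json")
  write_result(r, f)
  back <- read_result(f)
  expect_equal(back$IP_eV, r$IP, tolerance = 1e-12)
  expect_equal(back$EA_eV, r$EA, tolerance = 1e-12)
  expect_equal(back$qp_energies_eV, r$qp_energies, tolerance = 1e-12)
  expect_equal(back$iterations, r$iterations)
  expect_true(back$converged)
  # schema rejection
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema": "other-v9", "IP_eV": 1}', bad)
  expect_error(read_result(bad), "schema")
})

test_that("a hand-built result file parses to the expected fields", {
  f <- test_path("fixtures", "result-example.json")
  obj <- read_result(f)
  expect_equal(obj$IP_eV, 12.31)
  expect_equal(obj$n_occ, 5)
  expect_equal(obj$config$alpha, 0.35)
  expect_length(obj$qp_energies_eV, 7)
  expect_true(obj$converged)
})
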