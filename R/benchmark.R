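# Fixture molecule library, benchmark harness for the starting-point and
# potential-construction experiments, and JSON result serialization.

.fixture_names <- c("He", "H2", "H2O", "CH4", "NH3", "HF", "CO", "N2",
                    "C2H4", "CH3OH", "F2", "H2CO", "CH3Cl", "C2H6", "C3H8")

#' List fixture molecules
#'
#' Small closed-shell molecules with literature equilibrium geometries,
#' shipped as XYZ files with the package.
#'
#' @return character vector of fixture names
#' @export
fixture_molecules <- function() .fixture_names

#' Load a fixture molecule
#'
#' @param name one of [fixture_molecules()]
#' @return a `qsgw_molecule`
#' @export
fixture_molecule <- function(name) {
  if (!name %in% .fixture_names) stop("unknown fixture '", name, "'")
  path <- system.file("extdata", "geometries", paste0(name, ".xyz"),
                      package = "qsgwst", mustWork = TRUE)
  read_xyz(path)
}

#' Run the benchmark sweep
#'
#' Runs qsGW over the cross-product of fixture molecules, starting-point
#' functionals and potential-construction modes. Individual run failures are
#' recorded and never abort the sweep. The method has no stochastic
#' component, so a sweep is deterministic for a given configuration.
#'
#' @param molecules character vector of fixture names (or a named list of
#'   `qsgw_molecule` objects)
#' @param guesses starting-point functionals to sweep
#' @param modes potential constructions to sweep
#' @param config a [qsgw_config()]
#' @param basis,aux forwarded to [run_mean_field()]
#' @param verbose print progress lines
#' @return an object of class `qsgw_benchmark`: `$results` data frame (one
#'   row per run) and `$runs` list of `qsgw_result` objects
#' @export
run_benchmark <- function(molecules = fixture_molecules(),
                          guesses = c("PBE", "PBE0", "HF"), modes = "B",
                          config = qsgw_config(), basis = "et-dz",
                          aux = "auto", verbose = FALSE) {
  mols <- if (is.list(molecules)) molecules else
    setNames(lapply(molecules, fixture_molecule), molecules)
  rows <- list(); runs <- list()
  for (nm in names(mols)) {
    states <- list()
    for (g in guesses) {
      st <- tryCatch(run_mean_field(mols[[nm]], basis = basis, functional = g,
                                    aux = aux),
                     error = function(e) e)
      states[[g]] <- st
    }
    for (g in guesses) for (md in modes) {
      key <- paste(nm, g, md, sep = "/")
      if (verbose) message("benchmark: ", key)
      res <- if (inherits(states[[g]], "error")) states[[g]] else
        tryCatch({
          cfg <- config; cfg$mode <- md
          run_qsgw(state = states[[g]], config = cfg)
        }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[key]] <- data.frame(molecule = nm, guess = g, mode = md,
                                  converged = FALSE, iterations = NA_integer_,
                                  IP_eV = NA_real_, EA_eV = NA_real_,
                                  error = conditionMessage(res),
                                  stringsAsFactors = FALSE)
      } else {
        runs[[key]] <- res
        rows[[key]] <- data.frame(molecule = nm, guess = g, mode = md,
                                  converged = res$converged,
                                  iterations = res$iterations,
                                  IP_eV = res$IP, EA_eV = res$EA,
                                  error = NA_character_,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(results = do.call(rbind, c(rows, make.row.names = FALSE)),
                 runs = runs,
                 guesses = guesses, modes = modes, config = config,
                 basis = basis),
            class = "qsgw_benchmark")
}

#' Starting-point deviation statistics
#'
#' Mean and maximum absolute pairwise deviations of IPs and EAs across
#' starting points, computed over molecules for which every requested guess
#' converged (non-converged runs are listed separately).
#'
#' @param bench a [run_benchmark()] object
#' @param mode which potential mode to analyse
#' @return list with `mad_ip`, `mad_ea`, `max_ip`, `max_ea` (meV), the
#'   per-molecule deviation table, and the names of excluded molecules
#' @export
deviation_stats <- function(bench, mode = "B") {
  df <- bench$results[bench$results$mode == mode, ]
  guesses <- bench$guesses
  mols <- unique(df$molecule)
  dev_ip <- dev_ea <- numeric(0)
  per_mol <- list(); excluded <- character(0)
  if (length(guesses) < 2L)  # degenerate comparison
    return(list(mad_ip = 0, mad_ea = 0, max_ip = 0, max_ea = 0,
                per_molecule = list(), excluded = character(0)))
  pairs <- utils::combn(guesses, 2, simplify = FALSE)
  for (nm in mols) {
    d <- df[df$molecule == nm, ]
    if (!all(guesses %in% d$guess) ||
        !all(d$converged[match(guesses, d$guess)])) {
      excluded <- c(excluded, nm)
      next
    }
    ip <- setNames(d$IP_eV[match(guesses, d$guess)], guesses)
    ea <- setNames(d$EA_eV[match(guesses, d$guess)], guesses)
    dip <- vapply(pairs, function(pr) abs(ip[pr[1]] - ip[pr[2]]), 0)
    dea <- vapply(pairs, function(pr) abs(ea[pr[1]] - ea[pr[2]]), 0)
    dev_ip <- c(dev_ip, dip); dev_ea <- c(dev_ea, dea)
    per_mol[[nm]] <- c(max_ip_meV = max(dip) * 1000,
                       max_ea_meV = max(dea) * 1000)
  }
  if (!length(dev_ip))
    return(list(mad_ip = NA_real_, mad_ea = NA_real_, max_ip = NA_real_,
                max_ea = NA_real_, per_molecule = per_mol,
                excluded = excluded))
  list(mad_ip = mean(dev_ip) * 1000, mad_ea = mean(dev_ea) * 1000,
       max_ip = max(dev_ip) * 1000, max_ea = max(dev_ea) * 1000,
       per_molecule = per_mol, excluded = excluded)
}

#' Mode A vs mode B deviation statistics
#'
#' Average absolute IP/EA differences between the two potential
#' constructions over molecules where both converge.
#'
#' @param bench a benchmark containing runs with both modes for one guess
#' @param guess the starting point to compare at
#' @return list with `mean_dip`, `mean_dea`, `mean_all` (meV), per-molecule
#'   table and excluded molecules
#' @export
mode_stats <- function(bench, guess = "PBE0") {
  df <- bench$results[bench$results$guess == guess, ]
  mols <- unique(df$molecule)
  dip <- dea <- numeric(0)
  per_mol <- list(); excluded <- character(0)
  for (nm in mols) {
    a <- df[df$molecule == nm & df$mode == "A", ]
    b <- df[df$molecule == nm & df$mode == "B", ]
    if (nrow(a) != 1 || nrow(b) != 1 || !a$converged || !b$converged) {
      excluded <- c(excluded, nm)
      next
    }
    dip <- c(dip, abs(a$IP_eV - b$IP_eV))
    dea <- c(dea, abs(a$EA_eV - b$EA_eV))
    per_mol[[nm]] <- c(dip_meV = tail(dip, 1) * 1000,
                       dea_meV = tail(dea, 1) * 1000)
  }
  list(mean_dip = mean(dip) * 1000, mean_dea = mean(dea) * 1000,
       mean_all = mean(c(dip, dea)) * 1000,
       per_molecule = per_mol, excluded = excluded)
}

#' @export
print.qsgw_benchmark <- function(x, ...) {
  cat("<qsgw_benchmark>\n")
  print(x$results[, c("molecule", "guess", "mode", "converged", "iterations",
                      "IP_eV", "EA_eV")], row.names = FALSE)
  invisible(x)
}

.result_schema <- "qsgwst-result-v1"

#' Write a qsGW result to JSON
#'
#' @param res a `qsgw_result`
#' @param path output file
#' @export
write_result <- function(res, path) {
  obj <- list(schema = .result_schema,
              qp_energies_eV = res$qp_energies, IP_eV = res$IP,
              EA_eV = res$EA, iterations = res$iterations,
              nf_trace = res$nf_trace, converged = res$converged,
              mode = res$mode, guess = res$guess, basis = res$basis,
              n_occ = res$n_occ,
              config = unclass(res$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a qsGW result from JSON
#'
#' @param path JSON file written by [write_result()]
#' @return list with the stored fields
#' @export
read_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !identical(obj$schema, .result_schema))
    stop("unrecognized result schema: ", obj$schema %||% "<missing>")
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a
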