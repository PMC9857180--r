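## Pipeline stages behind the command-line script (inst/cli/magnetogrowth.R).
## Each stage writes its outputs plus a JSON run manifest recording the
## fully resolved configuration, seeds, package version, output files and a
## timestamp, so any output is re-derivable.

.writeManifest <- function(command, config, outputs, seed = NULL) {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    package = "magnetogrowth",
    version = as.character(utils::packageVersion("magnetogrowth")),
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- paste0(outputs[[1]], ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Pipeline stage: field map to CSV
#'
#' Builds a reduced-unit field map of the assembly described by a JSON
#' config (or a [MagnetAssembly-class]) and writes the documented CSV
#' dialect plus a run manifest (`<out>.manifest.json`).
#'
#' @param assembly a [MagnetAssembly-class] or path to a JSON config.
#' @param out output CSV path.
#' @param xlimMm,zlimMm grid ranges (mm).
#' @param nx,nz node counts.
#' @return the output path, invisibly.
#' @export
runFieldMap <- function(assembly, out, xlimMm = c(-46, 46),
                        zlimMm = c(5.2, 25), nx = 93, nz = 21) {
  if (is.character(assembly)) assembly <- readAssemblyConfig(assembly)
  map <- fieldMap(assembly, xlim = xlimMm * 1e-3, zlim = zlimMm * 1e-3,
                  nx = nx, nz = nz, reduced = TRUE)
  writeFieldMapCsv(map, out)
  .writeManifest("field-map",
                 list(label = assembly@label, xlim_mm = xlimMm,
                      zlim_mm = zlimMm, nx = nx, nz = nz, reduced = TRUE),
                 out)
  invisible(out)
}

#' Pipeline stage: chain force profile to CSV
#'
#' Evaluates the full-field chain force (and the near-seam asymptotic
#' comparison column) along x at a fixed height and writes
#' `x_mm, Fx_pN, Fz_pN, Fx_asym_pN, path` plus a manifest.
#'
#' @param assembly a [MagnetAssembly-class] or JSON config path (stripes
#'   must carry SI magnetization).
#' @param out output CSV path.
#' @param N,R_nm,Ms_kA_per_m chain parameters.
#' @param xMm x positions (mm).
#' @param zMm evaluation height (mm).
#' @return the output path, invisibly.
#' @export
runForceProfile <- function(assembly, out, N = 20, R_nm = 20,
                            Ms_kA_per_m = 412,
                            xMm = setdiff(seq(-10, 10, 0.25), 0), zMm = 5.2) {
  if (is.character(assembly)) assembly <- readAssemblyConfig(assembly)
  chain <- BMNChain(N = N, R = R_nm * 1e-9, Ms = Ms_kA_per_m * 1e3)
  prof <- forceProfile(assembly, chain, x = xMm * 1e-3, z = zMm * 1e-3)
  utils::write.csv(prof, out, row.names = FALSE, quote = FALSE)
  .writeManifest("force-profile",
                 list(label = assembly@label, N = N, R_nm = R_nm,
                      Ms_kA_per_m = Ms_kA_per_m, x_mm = range(xMm),
                      z_mm = zMm),
                 out)
  invisible(out)
}

#' Pipeline stage: simulate growth curves to CSV
#'
#' Simulates the four-condition experiment and writes the growth-curve CSV
#' dialect plus a manifest recording rates, noise and the base seed.
#'
#' @param out output CSV path.
#' @param rates named per-condition rates (1/min).
#' @param sigma lognormal noise scale.
#' @param baseSeed integer seed.
#' @param N0 initial concentration (clusters/mL).
#' @param times sampling grid (min).
#' @return the output path, invisibly.
#' @export
runGrowthSimulate <- function(out, rates = defaultConditionRates(),
                              sigma = 0.05, baseSeed = 1, N0 = 1e6,
                              times = seq(0, 1000, length.out = 11)) {
  set <- simulateConditionSet(rates = rates, N0 = N0, times = times,
                              sigma = sigma, baseSeed = baseSeed)
  writeGrowthCurvesCsv(set, out)
  .writeManifest("growth-simulate",
                 list(rates = as.list(rates), sigma = sigma, N0 = N0,
                      times_min = range(times), n_times = length(times)),
                 out, seed = baseSeed)
  invisible(out)
}

#' Pipeline stage: fit growth curves
#'
#' Reads a growth-curve CSV, fits each condition log-linearly inside the
#' window, and writes fit records as JSON plus a manifest.
#'
#' @param curvesCsv input CSV in the growth-curve dialect.
#' @param out output JSON path.
#' @param window fit window (min).
#' @return the fits (named list), invisibly.
#' @export
runGrowthFit <- function(curvesCsv, out, window = c(0, 1000)) {
  curves <- readGrowthCurvesCsv(curvesCsv)
  fits <- lapply(curves, fitLogLinear, window = window)
  writeFitsJson(fits, out)
  .writeManifest("growth-fit",
                 list(input = curvesCsv, window_min = window), out)
  invisible(fits)
}

#' Pipeline stage: compare conditions
#'
#' Fits every condition in a growth-curve CSV and writes the comparison
#' table (rate, stderr, doubling time, percent change vs reference,
#' interval-overlap flag) as CSV plus a manifest.
#'
#' @param curvesCsv input CSV in the growth-curve dialect.
#' @param out output CSV path.
#' @param reference reference condition label.
#' @param window fit window (min).
#' @return the comparison data.frame, invisibly.
#' @export
runGrowthCompare <- function(curvesCsv, out, reference = "ST",
                             window = c(0, 1000)) {
  curves <- readGrowthCurvesCsv(curvesCsv)
  fits <- lapply(curves, fitLogLinear, window = window)
  cmp <- compareConditions(fits, reference = reference)
  utils::write.csv(cmp, out, row.names = FALSE, quote = FALSE)
  .writeManifest("growth-compare",
                 list(input = curvesCsv, reference = reference,
                      window_min = window), out)
  invisible(cmp)
}

#' Pipeline stage: mitosis speed-up prediction
#'
#' Evaluates the speed-up model for the given mitotic fraction and force
#' ratio and writes the prediction as JSON plus a manifest.
#'
#' @param out output JSON path.
#' @param phi mitotic fraction (0, 1).
#' @param k force ratio >= 1.
#' @return the prediction data.frame, invisibly.
#' @export
runSpeedup <- function(out, phi = 0.10, k = 2) {
  pred <- predictSpeedup(phi, k = k)
  jsonlite::write_json(as.list(pred), out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .writeManifest("speedup", list(phi = phi, k = k), out)
  invisible(pred)
}
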