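## File interfaces. Boundary units match lab practice (mm, kA/m, T, pN,
## min); everything is converted to SI meters and A/m on the way in.

#' Read a magnet-assembly configuration
#'
#' JSON layout: `{"label": ..., "stripes": [{"a1_mm": ..., "a3_mm": ...,
#' "x0_mm": ..., "z0_mm": ..., "M_A_per_m" or "Br_T": ..., "sense": +/-1,
#' "axis": "z"|"x"}, ...]}`. `Br_T` is converted via M = Br / mu0.
#'
#' @param path JSON file path.
#' @return a [MagnetAssembly-class].
#' @examples
#' fp <- system.file("extdata", "focusing_pair.json", package = "magnetogrowth")
#' readAssemblyConfig(fp)
#' @export
readAssemblyConfig <- function(path) {
  if (!file.exists(path)) .stopValidation(sprintf("no such file: '%s'", path))
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(cfg$stripes) || !length(cfg$stripes))
    .stopValidation("config field 'stripes' is missing or empty")
  stripes <- lapply(cfg$stripes, function(s) {
    for (f in c("a1_mm", "a3_mm", "sense"))
      if (is.null(s[[f]]))
        .stopValidation(sprintf("stripe config field '%s' is missing", f))
    M <- if (!is.null(s$M_A_per_m)) s$M_A_per_m
         else if (!is.null(s$Br_T)) s$Br_T / .MU0
         else .stopValidation("stripe config needs 'M_A_per_m' or 'Br_T'")
    MagnetStripe(a1 = s$a1_mm * 1e-3, a3 = s$a3_mm * 1e-3,
                 x0 = if (is.null(s$x0_mm)) 0 else s$x0_mm * 1e-3,
                 z0 = if (is.null(s$z0_mm)) 0 else s$z0_mm * 1e-3,
                 M = M, sense = s$sense,
                 axis = if (is.null(s$axis)) "z" else s$axis)
  })
  MagnetAssembly(stripes, label = if (is.null(cfg$label)) "assembly" else cfg$label)
}

.FIELDMAP_HEADER <- c("x_mm", "z_mm", "Hx_over_M", "Hz_over_M",
                      "dHx_dx_per_mm", "dHz_dx_per_mm")

#' Write / read a field map as CSV
#'
#' Dialect: columns `x_mm, z_mm, Hx_over_M, Hz_over_M, dHx_dx_per_mm,
#' dHz_dx_per_mm` (reduced units; derivatives per mm). The reader rejects
#' files whose header differs from the documented dialect.
#'
#' @param map a [FieldMap-class] in reduced units.
#' @param path CSV path.
#' @return `writeFieldMapCsv`: the path, invisibly. `readFieldMapCsv`: a
#'   data.frame in the documented dialect.
#' @export
writeFieldMapCsv <- function(map, path) {
  stopifnot(is(map, "FieldMap"))
  if (!map@reduced)
    .stopValidation("the CSV dialect is defined for reduced-unit maps")
  s <- map@samples
  out <- data.frame(x_mm = s$x * 1e3, z_mm = s$z * 1e3,
                    Hx_over_M = s$Hx, Hz_over_M = s$Hz,
                    dHx_dx_per_mm = s$dHx_dx * 1e-3,
                    dHz_dx_per_mm = s$dHz_dx * 1e-3)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFieldMapCsv
#' @export
readFieldMapCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), .FIELDMAP_HEADER))
    .stopValidation(sprintf(
      "unexpected field-map header: got [%s], want [%s]",
      paste(names(df), collapse = ", "),
      paste(.FIELDMAP_HEADER, collapse = ", ")))
  df
}

.GROWTH_HEADER <- c("time_min", "count_per_ml", "condition")

#' Write / read growth curves as CSV
#'
#' Dialect: columns `time_min, count_per_ml, condition`, one row per
#' observation; curves are split by condition on reading. The reader
#' rejects unknown headers loudly.
#'
#' @param curves a [GrowthCurve-class] or list of them.
#' @param path CSV path.
#' @return `writeGrowthCurvesCsv`: the path, invisibly.
#'   `readGrowthCurvesCsv`: named list of [GrowthCurve-class].
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeGrowthCurvesCsv(simulateConditionSet(baseSeed = 1), p)
#' names(readGrowthCurvesCsv(p))
#' @export
writeGrowthCurvesCsv <- function(curves, path) {
  if (is(curves, "GrowthCurve")) curves <- list(curves)
  rows <- lapply(curves, function(gc) {
    stopifnot(is(gc, "GrowthCurve"))
    data.frame(time_min = gc@times, count_per_ml = gc@counts,
               condition = gc@condition)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname writeGrowthCurvesCsv
#' @export
readGrowthCurvesCsv <- function(path) {
  if (!file.exists(path)) .stopValidation(sprintf("no such file: '%s'", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), .GROWTH_HEADER))
    .stopValidation(sprintf(
      "unexpected growth-curve header: got [%s], want [%s]",
      paste(names(df), collapse = ", "),
      paste(.GROWTH_HEADER, collapse = ", ")))
  split_df <- split(df, df$condition)
  out <- lapply(split_df, function(d)
    GrowthCurve(d$time_min, d$count_per_ml, condition = d$condition[1]))
  out[unique(df$condition)]
}

#' Write growth fits as JSON records
#'
#' One record per fit: `{condition, a, r_per_min, stderr_r, pearson_r,
#' tau_min, window}`.
#'
#' @param fits a [GrowthFit-class] or list of them.
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
writeFitsJson <- function(fits, path) {
  if (is(fits, "GrowthFit")) fits <- list(fits)
  recs <- lapply(unname(fits), function(f) list(
    condition = f@condition, a = f@intercept, r_per_min = f@rate,
    stderr_r = f@stderrRate, pearson_r = f@pearsonR,
    tau_min = if (f@rate > 0) log(2) / f@rate else NA,
    window = f@window))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
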