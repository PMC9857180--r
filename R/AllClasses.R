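#' @import methods
NULL

## ---------------------------------------------------------------------------
## Magnet geometry
## ---------------------------------------------------------------------------

#' Uniformly magnetized stripe magnet
#'
#' A 2-D (infinitely long in y) permanent-magnet stripe of half-width `a1`
#' along the axis perpendicular to its magnetization and half-thickness `a3`
#' along the magnetization axis. The magnetization is `sense * M` along the
#' stripe's `axis` ("z", the default, or "x" for magnets magnetized in-plane
#' as in the incubator unit cell; the same closed-form solution is evaluated
#' in a frame rotated by 90 degrees).
#'
#' All lengths are SI meters in the assembly frame; `M` is in A/m.
#'
#' @slot a1 numeric(1), half-width (m), > 0.
#' @slot a3 numeric(1), half-thickness (m), > 0.
#' @slot x0,z0 numeric(1), stripe center in the assembly frame (m).
#' @slot M numeric(1), magnetization magnitude (A/m), >= 0.
#' @slot sense numeric(1), +1 or -1, magnetization direction along `axis`.
#' @slot axis character(1), "z" or "x".
#' @export
setClass("MagnetStripe",
  representation(a1 = "numeric", a3 = "numeric", x0 = "numeric",
                 z0 = "numeric", M = "numeric", sense = "numeric",
                 axis = "character"),
  prototype(x0 = 0, z0 = 0, M = 1, sense = 1, axis = "z"))

setValidity("MagnetStripe", function(object) {
  msg <- character()
  for (s in c("a1", "a3", "x0", "z0", "M", "sense"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  if (length(msg)) return(msg)
  if (object@a1 <= 0) msg <- c(msg, "'a1' must be > 0")
  if (object@a3 <= 0) msg <- c(msg, "'a3' must be > 0")
  if (object@M < 0) msg <- c(msg, "'M' must be >= 0")
  if (!object@sense %in% c(-1, 1)) msg <- c(msg, "'sense' must be +1 or -1")
  if (!identical(object@axis, "z") && !identical(object@axis, "x"))
    msg <- c(msg, "'axis' must be \"z\" or \"x\"")
  if (length(msg)) msg else TRUE
})

#' @param a1,a3,x0,z0,M,sense,axis see slot documentation.
#' @rdname MagnetStripe-class
#' @export
MagnetStripe <- function(a1, a3, x0 = 0, z0 = 0, M = 1, sense = 1, axis = "z") {
  new("MagnetStripe", a1 = a1, a3 = a3, x0 = x0, z0 = z0, M = M,
      sense = sense, axis = axis)
}

#' Assembly of stripe magnets
#'
#' An ordered collection of [MagnetStripe-class] objects whose fields
#' superpose linearly. Reduced-unit (H/M) evaluation assumes all stripes
#' share the same magnetization magnitude.
#'
#' @slot stripes list of MagnetStripe.
#' @slot label character(1).
#' @export
setClass("MagnetAssembly",
  representation(stripes = "list", label = "character"),
  prototype(label = "assembly"))

setValidity("MagnetAssembly", function(object) {
  if (length(object@stripes) < 1L) return("assembly needs at least one stripe")
  ok <- vapply(object@stripes, is, logical(1), class2 = "MagnetStripe")
  if (!all(ok)) return("all elements of 'stripes' must be MagnetStripe")
  TRUE
})

#' @param stripes list of [MagnetStripe-class].
#' @param label assembly label.
#' @rdname MagnetAssembly-class
#' @export
MagnetAssembly <- function(stripes, label = "assembly") {
  if (is(stripes, "MagnetStripe")) stripes <- list(stripes)
  new("MagnetAssembly", stripes = stripes, label = label)
}

#' Gridded field map
#'
#' Field components, modulus and x-derivatives of an assembly's field on a
#' rectangular grid. Values are reduced (H/M, derivatives in 1/m) when
#' `reduced` is TRUE, SI (A/m, A/m^2) otherwise.
#'
#' @slot samples data.frame with columns x, z, Hx, Hz, Hmod, dHx_dx, dHz_dx,
#'   interior (one row per node, z varying slowest).
#' @slot xGrid,zGrid numeric, strictly increasing node coordinates (m).
#' @slot reduced logical(1).
#' @slot label character(1), label of the generating assembly.
#' @export
setClass("FieldMap",
  representation(samples = "data.frame", xGrid = "numeric", zGrid = "numeric",
                 reduced = "logical", label = "character"))

setValidity("FieldMap", function(object) {
  msg <- character()
  need <- c("x", "z", "Hx", "Hz", "Hmod", "dHx_dx", "dHz_dx", "interior")
  if (!all(need %in% names(object@samples)))
    msg <- c(msg, paste("samples must have columns", paste(need, collapse = ", ")))
  if (length(object@xGrid) < 1L || is.unsorted(object@xGrid, strictly = TRUE))
    msg <- c(msg, "xGrid must be strictly increasing")
  if (length(object@zGrid) < 1L || is.unsorted(object@zGrid, strictly = TRUE))
    msg <- c(msg, "zGrid must be strictly increasing")
  if (!length(msg) &&
      nrow(object@samples) != length(object@xGrid) * length(object@zGrid))
    msg <- c(msg, "samples must have one row per grid node")
  if (!length(msg)) {
    bad <- with(object@samples, abs(Hmod - sqrt(Hx^2 + Hz^2)) >
                  1e-12 * pmax(Hmod, 1e-300))
    if (any(bad)) msg <- c(msg, "Hmod must equal sqrt(Hx^2 + Hz^2)")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Magnetic actors
## ---------------------------------------------------------------------------

#' Chain of biogenic magnetic nanoparticles
#'
#' `N` spherical particles of radius `R` with saturation magnetization `Ms`
#' (412 kA/m for magnetite). The chain volume V = N * 4*pi*R^3 / 3 is always
#' recomputed via [chainVolume()], never stored. `moment` is the unit vector
#' of the chain's dipole moment in the x-z plane (default +x).
#'
#' @slot N numeric(1), particle count, integer-valued >= 0.
#' @slot R numeric(1), particle radius (m), > 0.
#' @slot Ms numeric(1), saturation magnetization (A/m), >= 0.
#' @slot moment numeric(2), unit vector (x, z components).
#' @export
setClass("BMNChain",
  representation(N = "numeric", R = "numeric", Ms = "numeric",
                 moment = "numeric"),
  prototype(moment = c(1, 0)))

setValidity("BMNChain", function(object) {
  msg <- character()
  if (length(object@N) != 1L || object@N < 0 || object@N != round(object@N))
    msg <- c(msg, "'N' must be a single non-negative integer")
  if (length(object@R) != 1L || object@R <= 0) msg <- c(msg, "'R' must be > 0")
  if (length(object@Ms) != 1L || object@Ms < 0) msg <- c(msg, "'Ms' must be >= 0")
  if (length(object@moment) != 2L || !all(is.finite(object@moment)) ||
      abs(sqrt(sum(object@moment^2)) - 1) > 1e-8)
    msg <- c(msg, "'moment' must be a unit 2-vector (x, z)")
  if (length(msg)) msg else TRUE
})

#' @param N,R,Ms,moment see slot documentation; `moment` is normalized.
#' @rdname BMNChain-class
#' @export
BMNChain <- function(N, R, Ms = 412e3, moment = c(1, 0)) {
  n <- sqrt(sum(moment^2))
  if (n > 0) moment <- moment / n
  new("BMNChain", N = N, R = R, Ms = Ms, moment = moment)
}

#' Diamagnetic bacterial body
#'
#' A weakly magnetizable body of volume `Vb` and susceptibility `chiB` in a
#' medium of susceptibility `chiM`. The susceptibility contrast
#' `deltaChi = chiB - chiM` is derived, never stored; it is positive for a
#' bacterium that is less diamagnetic than its medium (the case argued for
#' nanoparticle-bearing cells), making the body force parallel to grad|B|.
#'
#' @slot Vb numeric(1), body volume (m^3), > 0.
#' @slot chiB,chiM numeric(1), dimensionless volume susceptibilities.
#' @export
setClass("DiamagneticBody",
  representation(Vb = "numeric", chiB = "numeric", chiM = "numeric"))

setValidity("DiamagneticBody", function(object) {
  msg <- character()
  if (length(object@Vb) != 1L || object@Vb <= 0) msg <- c(msg, "'Vb' must be > 0")
  if (!is.finite(object@chiB) || !is.finite(object@chiM))
    msg <- c(msg, "susceptibilities must be finite")
  if (length(msg)) msg else TRUE
})

#' @param Vb,chiB,chiM see slot documentation.
#' @rdname DiamagneticBody-class
#' @export
DiamagneticBody <- function(Vb, chiB, chiM) {
  new("DiamagneticBody", Vb = Vb, chiB = chiB, chiM = chiM)
}

## ---------------------------------------------------------------------------
## Growth kinetics
## ---------------------------------------------------------------------------

#' Bacterial growth curve
#'
#' Time-stamped cell-cluster concentrations for one culture condition.
#' Times are minutes (strictly increasing, >= 0), counts are clusters per mL
#' (> 0, so the log-transform used by the fitter exists).
#'
#' @slot times numeric, minutes.
#' @slot counts numeric, clusters/mL.
#' @slot condition character(1) label, e.g. "ST", "ST+Fe", "ST+MF", "ST+MF+Fe".
#' @export
setClass("GrowthCurve",
  representation(times = "numeric", counts = "numeric",
                 condition = "character"),
  prototype(condition = "ST"))

setValidity("GrowthCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@counts))
    msg <- c(msg, "'times' and 'counts' must have equal length")
  if (length(object@times) < 3L) msg <- c(msg, "need at least 3 points")
  if (length(object@times) && (any(object@times < 0) ||
      is.unsorted(object@times, strictly = TRUE)))
    msg <- c(msg, "'times' must be non-negative and strictly increasing")
  if (length(object@counts) && (!all(is.finite(object@counts)) ||
      any(object@counts <= 0)))
    msg <- c(msg, "'counts' must be finite and > 0")
  if (length(object@condition) != 1L) msg <- c(msg, "'condition' must be length 1")
  if (length(msg)) msg else TRUE
})

#' @param times,counts,condition see slot documentation.
#' @rdname GrowthCurve-class
#' @export
GrowthCurve <- function(times, counts, condition = "ST") {
  new("GrowthCurve", times = as.numeric(times), counts = as.numeric(counts),
      condition = condition)
}

#' Log-linear growth fit
#'
#' Ordinary least-squares fit of ln(counts) on time inside a fit window:
#' ln N(t) = a + r t. The doubling time tau = ln2 / r is always derived via
#' [doublingTime()], keeping r * tau = ln 2 exact.
#'
#' @slot intercept numeric(1), a (ln clusters/mL).
#' @slot rate numeric(1), r (1/min).
#' @slot stderrRate numeric(1), classical OLS standard error of r (1/min).
#' @slot pearsonR numeric(1), Pearson correlation of (t, ln N) in the window.
#' @slot window numeric(2), (t_lo, t_hi) minutes.
#' @slot nPoints integer(1), points used.
#' @slot condition character(1).
#' @export
setClass("GrowthFit",
  representation(intercept = "numeric", rate = "numeric",
                 stderrRate = "numeric", pearsonR = "numeric",
                 window = "numeric", nPoints = "integer",
                 condition = "character"))

setValidity("GrowthFit", function(object) {
  msg <- character()
  if (object@stderrRate < 0) msg <- c(msg, "'stderrRate' must be >= 0")
  if (is.finite(object@pearsonR) && abs(object@pearsonR) > 1 + 1e-12)
    msg <- c(msg, "'pearsonR' must lie in [-1, 1]")
  if (length(object@window) != 2L || object@window[1] > object@window[2])
    msg <- c(msg, "'window' must be (t_lo, t_hi) with t_lo <= t_hi")
  if (object@nPoints < 3L) msg <- c(msg, "'nPoints' must be >= 3")
  if (length(msg)) msg else TRUE
})

#' Mitosis-shortening speed-up model
#'
#' The mitotic (division) phase occupies a fraction `mitoticFraction` (phi) of
#' the cell cycle. An external force assisting division multiplies the total
#' division-driving force by `forceRatio` (k = F0/F >= 1); in Stokes flow the
#' characteristic separation velocity scales with force, so the mitotic phase
#' duration scales as 1/k. Derived quantities (cycle shortening, growth-rate
#' gain) are recomputed by [predictSpeedup()], never stored.
#'
#' @slot mitoticFraction numeric(1), 0 < phi < 1.
#' @slot forceRatio numeric(1), k >= 1.
#' @export
setClass("MitosisSpeedupModel",
  representation(mitoticFraction = "numeric", forceRatio = "numeric"))

setValidity("MitosisSpeedupModel", function(object) {
  msg <- character()
  if (!(object@mitoticFraction > 0 && object@mitoticFraction < 1))
    msg <- c(msg, "'mitoticFraction' must be in (0, 1)")
  if (object@forceRatio < 1) msg <- c(msg, "'forceRatio' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param mitoticFraction,forceRatio see slot documentation.
#' @rdname MitosisSpeedupModel-class
#' @export
MitosisSpeedupModel <- function(mitoticFraction, forceRatio) {
  new("MitosisSpeedupModel", mitoticFraction = mitoticFraction,
      forceRatio = forceRatio)
}
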