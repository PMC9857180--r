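## Closed-form 2-D magnetostatics of uniformly magnetized stripes.
##
## For a stripe of half-width a1 (x) and half-thickness a3 (z), magnetized
## along +z, the reduced field components in the stripe frame are
##
##   Hz/M = -2 [ atan((a1-x)/(a3-z)) + atan((a1+x)/(a3-z))
##             + atan((a1-x)/(a3+z)) + atan((a1+x)/(a3+z)) ]
##   Hx/M =  ln{ [((a1+x)^2+(a3-z)^2) ((a1-x)^2+(a3+z)^2)] /
##               [((a1-x)^2+(a3-z)^2) ((a1+x)^2+(a3+z)^2)] }
##
## (Gaussian-style 2-D convention: a charged line contributes 2*lambda/r;
## equivalent to the surface-magnetic-charge picture with sheets +/-M at
## z = +/-a3). Verified against a numerical line-integral oracle in the test
## suite. Values are finite everywhere except the four stripe corners, where
## the log argument degenerates.

.shapeH <- function(x, z, a1, a3) {
  hz <- -2 * (atan((a1 - x) / (a3 - z)) + atan((a1 + x) / (a3 - z)) +
              atan((a1 - x) / (a3 + z)) + atan((a1 + x) / (a3 + z)))
  p1 <- (a1 + x)^2 + (a3 - z)^2
  p2 <- (a1 - x)^2 + (a3 + z)^2
  p3 <- (a1 - x)^2 + (a3 - z)^2
  p4 <- (a1 + x)^2 + (a3 + z)^2
  list(hx = log(p1) + log(p2) - log(p3) - log(p4), hz = hz)
}

## analytic first derivatives of the shape functions (both in 1/length)
.shapeDH <- function(x, z, a1, a3) {
  p1 <- (a1 + x)^2 + (a3 - z)^2
  p2 <- (a1 - x)^2 + (a3 + z)^2
  p3 <- (a1 - x)^2 + (a3 - z)^2
  p4 <- (a1 + x)^2 + (a3 + z)^2
  d1 <- a3 - z
  d2 <- a3 + z
  list(
    dhx_dx = 2 * (a1 + x) / p1 - 2 * (a1 - x) / p2 +
             2 * (a1 - x) / p3 - 2 * (a1 + x) / p4,
    dhz_dx = -2 * (-d1 / p3 + d1 / p1 - d2 / p2 + d2 / p4),
    dhx_dz = -2 * d1 / p1 + 2 * d2 / p2 + 2 * d1 / p3 - 2 * d2 / p4,
    dhz_dz = -2 * ((a1 - x) / p3 + (a1 + x) / p1 -
                   (a1 - x) / p2 - (a1 + x) / p4))
}

## stripe frame: for axis "x" the solution is evaluated in a frame rotated
## 90 degrees (local_x = -(z - z0), local_z = x - x0) so the magnetization
## points along local +z; field vectors rotate back as (Hx, Hz) = (hz, -hx).
.toLocal <- function(stripe, x, z) {
  dx <- x - stripe@x0
  dz <- z - stripe@z0
  if (stripe@axis == "z") list(xl = dx, zl = dz) else list(xl = -dz, zl = dx)
}

.cornerHit <- function(stripe, x, z, tol = NULL) {
  loc <- .toLocal(stripe, x, z)
  if (is.null(tol)) tol <- 1e-12 * stripe@a1
  dmin <- pmin(
    sqrt((loc$xl - stripe@a1)^2 + (loc$zl - stripe@a3)^2),
    sqrt((loc$xl - stripe@a1)^2 + (loc$zl + stripe@a3)^2),
    sqrt((loc$xl + stripe@a1)^2 + (loc$zl - stripe@a3)^2),
    sqrt((loc$xl + stripe@a1)^2 + (loc$zl + stripe@a3)^2))
  dmin <= tol
}

.checkCorners <- function(assembly, x, z) {
  for (i in seq_along(assembly@stripes)) {
    if (any(.cornerHit(assembly@stripes[[i]], x, z)))
      .stopSingular(sprintf(
        "field evaluation at a corner of stripe %d of assembly '%s' is singular",
        i, assembly@label))
  }
}

#' Reduced field of a single stripe magnet
#'
#' Evaluates the closed-form field components of a uniformly magnetized 2-D
#' stripe at one or more points of the assembly frame, in reduced units H/M
#' (the stripe's `sense` multiplies the result; `M = 0` gives zero field).
#'
#' @param stripe a [MagnetStripe-class].
#' @param x,z point coordinates (m), equal-length vectors.
#' @return data.frame with columns `Hx`, `Hz` (reduced H/M).
#' @examples
#' s <- MagnetStripe(a1 = 0.023, a3 = 0.005)
#' stripeField(s, x = 0, z = 0.0052)
#' @export
stripeField <- function(stripe, x, z) {
  stopifnot(is(stripe, "MagnetStripe"), length(x) == length(z))
  if (any(.cornerHit(stripe, x, z)))
    .stopSingular("field evaluation at a stripe corner is singular")
  loc <- .toLocal(stripe, x, z)
  sh <- .shapeH(loc$xl, loc$zl, stripe@a1, stripe@a3)
  fac <- stripe@sense * (stripe@M > 0)
  if (stripe@axis == "z") {
    data.frame(Hx = fac * sh$hx, Hz = fac * sh$hz)
  } else {
    data.frame(Hx = fac * sh$hz, Hz = -fac * sh$hx)
  }
}

## per-stripe reduced weights: equal-M assemblies give 1; mixed magnitudes are
## expressed relative to the first non-zero M
.reducedWeights <- function(assembly) {
  Ms <- vapply(assembly@stripes, slot, numeric(1), name = "M")
  ref <- Ms[Ms > 0][1]
  if (is.na(ref)) return(numeric(length(Ms)))
  Ms / ref
}

#' Superposed field of a magnet assembly
#'
#' Linear superposition of the per-stripe closed forms. With
#' `reduced = TRUE` (default) components are H/M of the assembly's reference
#' magnetization; with `reduced = FALSE` they are SI A/m (each stripe
#' weighted by its own `M`).
#'
#' @param assembly a [MagnetAssembly-class].
#' @param x,z evaluation points (m).
#' @param reduced logical(1), reduced (H/M) vs SI units.
#' @return data.frame with columns `x`, `z`, `Hx`, `Hz`, `Hmod`, `interior`
#'   (TRUE where the point lies inside a stripe body, where the printed
#'   expressions are evaluated as-is but carry no validity claim).
#' @examples
#' fp <- focusingPair()
#' assemblyField(fp, x = c(-0.005, 0.005), z = c(0.0052, 0.0052))
#' @export
assemblyField <- function(assembly, x, z, reduced = TRUE) {
  stopifnot(is(assembly, "MagnetAssembly"), length(x) == length(z))
  .checkCorners(assembly, x, z)
  w <- if (reduced) .reducedWeights(assembly) else
    vapply(assembly@stripes, slot, numeric(1), name = "M")
  Hx <- Hz <- numeric(length(x))
  interior <- logical(length(x))
  for (i in seq_along(assembly@stripes)) {
    s <- assembly@stripes[[i]]
    loc <- .toLocal(s, x, z)
    sh <- .shapeH(loc$xl, loc$zl, s@a1, s@a3)
    if (s@axis == "z") {
      Hx <- Hx + w[i] * s@sense * sh$hx
      Hz <- Hz + w[i] * s@sense * sh$hz
    } else {
      Hx <- Hx + w[i] * s@sense * sh$hz
      Hz <- Hz - w[i] * s@sense * sh$hx
    }
    interior <- interior | (abs(loc$xl) < s@a1 & abs(loc$zl) < s@a3)
  }
  data.frame(x = x, z = z, Hx = Hx, Hz = Hz, Hmod = sqrt(Hx^2 + Hz^2),
             interior = interior)
}

#' x-derivatives of the assembly field
#'
#' Returns d(Hx)/dx and d(Hz)/dx at the given points, either from the exact
#' closed-form derivatives (`method = "analytic"`) or by central finite
#' differences with step `step` (`method = "finite_difference"`). Units are
#' 1/m (reduced) or A/m^2 (SI), matching `reduced`.
#'
#' @inheritParams assemblyField
#' @param method derivative method.
#' @param step finite-difference step (m); defaults to 1e-6 times the first
#'   stripe's half-width.
#' @return data.frame with columns `dHx_dx`, `dHz_dx`.
#' @examples
#' fp <- focusingPair()
#' fieldGradients(fp, x = 0.002, z = 0.0052)
#' @export
fieldGradients <- function(assembly, x, z,
                           method = c("analytic", "finite_difference"),
                           step = NULL, reduced = TRUE) {
  stopifnot(is(assembly, "MagnetAssembly"), length(x) == length(z))
  method <- match.arg(method)
  if (method == "finite_difference") {
    if (is.null(step)) step <- 1e-6 * assembly@stripes[[1]]@a1
    if (!is.numeric(step) || length(step) != 1L || step <= 0)
      .stopValidation("'step' must be a single positive number")
    fp <- assemblyField(assembly, x + step, z, reduced = reduced)
    fm <- assemblyField(assembly, x - step, z, reduced = reduced)
    return(data.frame(dHx_dx = (fp$Hx - fm$Hx) / (2 * step),
                      dHz_dx = (fp$Hz - fm$Hz) / (2 * step)))
  }
  .checkCorners(assembly, x, z)
  w <- if (reduced) .reducedWeights(assembly) else
    vapply(assembly@stripes, slot, numeric(1), name = "M")
  dHx <- dHz <- numeric(length(x))
  for (i in seq_along(assembly@stripes)) {
    s <- assembly@stripes[[i]]
    loc <- .toLocal(s, x, z)
    dh <- .shapeDH(loc$xl, loc$zl, s@a1, s@a3)
    if (s@axis == "z") {
      ## global x is local x
      dHx <- dHx + w[i] * s@sense * dh$dhx_dx
      dHz <- dHz + w[i] * s@sense * dh$dhz_dx
    } else {
      ## global (Hx, Hz) = (hz, -hx); global x advances local z
      dHx <- dHx + w[i] * s@sense * dh$dhz_dz
      dHz <- dHz - w[i] * s@sense * dh$dhx_dz
    }
  }
  data.frame(dHx_dx = dHx, dHz_dx = dHz)
}

#' Near-seam asymptotic field and gradient of an antiparallel pair
#'
#' Close to the seam of an antiparallel stripe pair (|x| << a1) the
#' horizontal field component follows 4*M*ln(a1/|x|) and its x-derivative
#' 4*M/x; the gradient magnitude grows without bound as x -> 0.
#'
#' Two sign conventions are supported. The default, `"field_map"`, matches
#' the full closed-form solution for the bundled focusing pair (Hx < 0 in
#' the central area, so dHx/dx > 0 for x > 0); `"printed"` flips both signs
#' (Hx = +4*M*ln(a1/|x|), dHx/dx = -4*M/x).
#'
#' @param x signed distance from the seam (m), non-zero.
#' @param a1 stripe half-width (m).
#' @param M magnetization (A/m); 1 for reduced units.
#' @param signConvention "field_map" or "printed".
#' @param window validity guard: require |x|/a1 < `window`.
#' @return data.frame with columns `Hx`, `dHx_dx`.
#' @examples
#' boundaryAsymptote(c(5e-4, 1e-3), a1 = 0.023)
#' @export
boundaryAsymptote <- function(x, a1, M = 1,
                              signConvention = c("field_map", "printed"),
                              window = 0.2) {
  signConvention <- match.arg(signConvention)
  if (any(x == 0))
    .stopSingular("the seam asymptote diverges at x = 0")
  if (any(abs(x) / a1 >= window))
    .stopValidation(sprintf(
      "asymptote valid only for |x|/a1 < %g (got max %.3g)",
      window, max(abs(x) / a1)))
  sgn <- if (signConvention == "field_map") -1 else 1
  data.frame(Hx = sgn * 4 * M * log(a1 / abs(x)),
             dHx_dx = -sgn * 4 * M / x)
}

#' Gridded field map of an assembly
#'
#' Evaluates field components, modulus and x-gradients on a rectangular
#' grid. Grid nodes that land exactly on a stripe corner are nudged in x by
#' 1e-9 * a1 (with a message). The default grid emulates the published map
#' plane 0.2 mm above the magnet top surface.
#'
#' @inheritParams assemblyField
#' @param xlim,zlim numeric(2) ranges (m).
#' @param nx,nz node counts (>= 1).
#' @return a [FieldMap-class].
#' @examples
#' fp <- focusingPair()
#' fm <- fieldMap(fp, xlim = c(-0.01, 0.01), zlim = c(0.0052, 0.0052),
#'                nx = 21, nz = 1)
#' head(as.data.frame(fm))
#' @export
fieldMap <- function(assembly, xlim, zlim, nx, nz, reduced = TRUE) {
  stopifnot(is(assembly, "MagnetAssembly"))
  if (nx < 1 || nz < 1) .stopValidation("grid must have at least one node")
  xg <- if (nx == 1) xlim[1] else seq(xlim[1], xlim[2], length.out = nx)
  zg <- if (nz == 1) zlim[1] else seq(zlim[1], zlim[2], length.out = nz)
  grid <- expand.grid(x = xg, z = zg, KEEP.OUT.ATTRS = FALSE)
  a1ref <- assembly@stripes[[1]]@a1
  for (s in assembly@stripes) {
    hit <- .cornerHit(s, grid$x, grid$z)
    if (any(hit)) {
      message(sprintf("nudging %d grid node(s) off a stripe corner by %.1e m",
                      sum(hit), 1e-9 * a1ref))
      grid$x[hit] <- grid$x[hit] + 1e-9 * a1ref
    }
  }
  f <- assemblyField(assembly, grid$x, grid$z, reduced = reduced)
  g <- fieldGradients(assembly, grid$x, grid$z, reduced = reduced)
  samples <- cbind(f[c("x", "z", "Hx", "Hz", "Hmod")], g,
                   interior = f$interior)
  new("FieldMap", samples = samples, xGrid = xg, zGrid = zg,
      reduced = reduced, label = assembly@label)
}

#' @describeIn FieldMap-class samples as a data.frame.
#' @param x a FieldMap.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "FieldMap", function(x, ...) x@samples)

setMethod("show", "FieldMap", function(object) {
  cat(sprintf("FieldMap '%s': %d x %d nodes (%s units)\n", object@label,
              length(object@xGrid), length(object@zGrid),
              if (object@reduced) "reduced H/M" else "SI"))
  cat(sprintf("  x: [%.4g, %.4g] m, z: [%.4g, %.4g] m\n",
              min(object@xGrid), max(object@xGrid),
              min(object@zGrid), max(object@zGrid)))
  cat(sprintf("  |H| in [%.4g, %.4g]; %d interior node(s)\n",
              min(object@samples$Hmod), max(object@samples$Hmod),
              sum(object@samples$interior)))
})

setMethod("show", "MagnetStripe", function(object) {
  cat(sprintf(
    "MagnetStripe: a1 = %g mm, a3 = %g mm, center (%g, %g) mm, M = %g A/m, %s%s\n",
    object@a1 * 1e3, object@a3 * 1e3, object@x0 * 1e3, object@z0 * 1e3,
    object@M, if (object@sense > 0) "+" else "-", object@axis))
})

setMethod("show", "MagnetAssembly", function(object) {
  cat(sprintf("MagnetAssembly '%s' with %d stripe(s)\n", object@label,
              length(object@stripes)))
  for (s in object@stripes) show(s)
})

#' Bundled magnet-assembly geometries
#'
#' `focusingPair()` builds the antiparallel side-by-side stripe pair used to
#' focus bacteria: two stripes of half-width `a1` = 23 mm and half-thickness
#' `a3` = 5 mm touching at x = 0, magnetized along z in opposite senses
#' (right +, left -, which puts Hx < 0 just above the seam). `incubatorCell()`
#' builds the cultivation-unit cell: the same solution rotated 90 degrees,
#' two stripes magnetized along x in opposite senses stacked along z.
#'
#' @param a1,a3 stripe half-dimensions (m).
#' @param M magnetization (A/m); the default corresponds to a remanence
#'   Br = mu0*M of about 1.2 T (NdFeB).
#' @return a [MagnetAssembly-class].
#' @examples
#' focusingPair()
#' @export
focusingPair <- function(a1 = 0.023, a3 = 0.005, M = 1.2 / .MU0) {
  MagnetAssembly(list(
    MagnetStripe(a1 = a1, a3 = a3, x0 = -a1, z0 = 0, M = M, sense = -1),
    MagnetStripe(a1 = a1, a3 = a3, x0 = +a1, z0 = 0, M = M, sense = +1)),
    label = "focusing_pair")
}

#' @rdname focusingPair
#' @export
incubatorCell <- function(a1 = 0.023, a3 = 0.005, M = 1.2 / .MU0) {
  MagnetAssembly(list(
    MagnetStripe(a1 = a1, a3 = a3, x0 = 0, z0 = -a1, M = M, sense = -1,
                 axis = "x"),
    MagnetStripe(a1 = a1, a3 = a3, x0 = 0, z0 = +a1, M = M, sense = +1,
                 axis = "x")),
    label = "incubator_cell")
}
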