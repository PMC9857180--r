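## Magnetic gradient forces, SI throughout. The magnetostatics module works
## in reduced units (H/M, 1/m); conversion to SI happens here and only here,
## via B_r = mu0 * M: an SI gradient is M times the reduced gradient.

#' Gradient force on a point dipole
#'
#' For a dipole moment p = (px, 0, 0) in the plane field H(x, z),
#' Fx = mu0 * px * dHx/dx and Fz = mu0 * px * dHz/dx: the force components
#' follow the signs of the x-gradients.
#'
#' @param px dipole moment x-component (A m^2).
#' @param dHx_dx,dHz_dx SI field gradients (A/m per m).
#' @param x,z optional evaluation position (m), recorded in the result.
#' @return data.frame with columns `Fx`, `Fz` (N), `x`, `z`, `path`.
#' @examples
#' dipoleForce(px = 1e-15, dHx_dx = 1e10, dHz_dx = 0)
#' @export
dipoleForce <- function(px, dHx_dx, dHz_dx, x = NA_real_, z = NA_real_) {
  if (!all(is.finite(px)) || !all(is.finite(dHx_dx)) || !all(is.finite(dHz_dx)))
    .stopValidation("dipoleForce needs finite 'px' and gradients")
  data.frame(Fx = .MU0 * px * dHx_dx, Fz = .MU0 * px * dHz_dx,
             x = x, z = z, path = "dipole")
}

#' @describeIn BMNChain-class chain volume V = N * 4*pi*R^3 / 3 (m^3),
#'   recomputed from the slots.
#' @param object a BMNChain.
#' @export
setMethod("chainVolume", "BMNChain",
          function(object) object@N * 4 * pi * object@R^3 / 3)

#' Gradient force on a nanoparticle chain
#'
#' The saturated-moment route: the chain's moment is p = Ms * V with
#' V = N * 4*pi*R^3 / 3, so Fx = mu0 * Ms * V * dHx/dx and
#' Fz = mu0 * Ms * V * dHz/dx. A chain moment tilted in the x-z plane is
#' projected using the exterior-field identities dHx/dz = dHz/dx and
#' dHz/dz = -dHx/dx (curl- and divergence-free H outside the magnets), so
#' only the x-gradients are required.
#'
#' @param chain a [BMNChain-class].
#' @param dHx_dx,dHz_dx SI field gradients (A/m per m).
#' @param x,z optional evaluation position (m).
#' @return data.frame as in [dipoleForce()] with `path = "chain"`.
#' @examples
#' ch <- BMNChain(N = 20, R = 20e-9)
#' chainForce(ch, dHx_dx = 1e10, dHz_dx = 0)
#' @export
chainForce <- function(chain, dHx_dx, dHz_dx, x = NA_real_, z = NA_real_) {
  stopifnot(is(chain, "BMNChain"))
  p <- chain@Ms * chainVolume(chain) * chain@moment
  Fx <- .MU0 * (p[1] * dHx_dx + p[2] * dHz_dx)
  Fz <- .MU0 * (p[1] * dHz_dx - p[2] * dHx_dx)
  data.frame(Fx = Fx, Fz = Fz, x = x, z = z, path = "chain")
}

#' Near-seam asymptotic chain force
#'
#' Combines the saturated chain moment with the 4*M/x seam-gradient
#' asymptote of an antiparallel pair:
#' Fx = 16*pi/(3*x) * N * R^3 * Br * Ms (newtons), which diverges as
#' x -> 0. With the default `"field_map"` sign convention Fx > 0 for x > 0
#' and Fx < 0 for x < 0 (the two chain halves are pulled apart).
#'
#' Direct SI evaluation of this expression at N = 20, R = 20 nm, x = 1 mm,
#' Br = 1 T, Ms = 412 kA/m gives 1.10 pN (see [seamForceEstimate()]); see
#' the methods vignette for a discussion of the published estimate at these
#' inputs.
#'
#' @param chain a [BMNChain-class].
#' @param x signed distance from the seam (m), non-zero.
#' @param Br remanent induction mu0*M at the magnet surface (T).
#' @param signConvention as in [boundaryAsymptote()].
#' @return data.frame with `Fx` (N), `Fz = NA`, `x`, `path =
#'   "chain_asymptotic"`.
#' @examples
#' ch <- BMNChain(N = 20, R = 20e-9)
#' chainForceAsymptotic(ch, x = 1e-3, Br = 1)
#' @export
chainForceAsymptotic <- function(chain, x, Br,
                                 signConvention = c("field_map", "printed")) {
  stopifnot(is(chain, "BMNChain"))
  signConvention <- match.arg(signConvention)
  if (any(x == 0)) .stopSingular("asymptotic chain force diverges at x = 0")
  sgn <- if (signConvention == "field_map") 1 else -1
  Fx <- sgn * 16 * pi / (3 * x) * chain@N * chain@R^3 * Br * chain@Ms
  data.frame(Fx = Fx, Fz = NA_real_, x = x, z = NA_real_,
             path = "chain_asymptotic")
}

#' Direct evaluation of the seam force at reference inputs
#'
#' Evaluates the asymptotic seam force for a stated parameter set and
#' returns the inputs alongside the force in newtons and piconewtons.
#' Defaults are the reference worked estimate: a 20-particle chain of
#' 20 nm magnetite particles (Ms = 412 kA/m) 1 mm from the seam of a
#' Br = 1 T pair, which evaluates to 1.104 pN.
#'
#' @param N,R chain particle count and radius (m).
#' @param x distance from the seam (m).
#' @param Br remanence (T).
#' @param Ms saturation magnetization (A/m).
#' @return data.frame with the inputs, `F_N` and `F_pN`.
#' @examples
#' seamForceEstimate()
#' @export
seamForceEstimate <- function(N = 20, R = 20e-9, x = 1e-3, Br = 1,
                              Ms = 412e3) {
  F <- 16 * pi / (3 * x) * N * R^3 * Br * Ms
  data.frame(N = N, R = R, x = x, Br = Br, Ms = Ms,
             F_N = F, F_pN = F * 1e12)
}

#' @describeIn DiamagneticBody-class susceptibility contrast
#'   chiB - chiM (dimensionless), recomputed from the slots.
#' @param object a DiamagneticBody.
#' @export
setMethod("deltaChi", "DiamagneticBody",
          function(object) object@chiB - object@chiM)

#' Gradient force on a weakly magnetizable body
#'
#' f = Vb * deltaChi * B * grad(B) / mu0. The force is parallel to grad|B|
#' when deltaChi > 0 (a body less diamagnetic than its medium is attracted
#' to the field maxima) and antiparallel when deltaChi < 0.
#'
#' @param body a [DiamagneticBody-class].
#' @param B field modulus (T), >= 0.
#' @param gradBx,gradBz gradient of the modulus (T/m).
#' @param x,z optional position (m).
#' @return data.frame as in [dipoleForce()] with `path = "body"`.
#' @examples
#' b <- DiamagneticBody(Vb = 1e-18, chiB = -8e-6, chiM = -9e-6)
#' bodyForce(b, B = 0.5, gradBx = 10, gradBz = 0)
#' @export
bodyForce <- function(body, B, gradBx, gradBz, x = NA_real_, z = NA_real_) {
  stopifnot(is(body, "DiamagneticBody"))
  if (any(B < 0)) .stopValidation("'B' must be >= 0")
  dchi <- deltaChi(body)
  data.frame(Fx = body@Vb * dchi * B * gradBx / .MU0,
             Fz = body@Vb * dchi * B * gradBz / .MU0,
             x = x, z = z, path = "body")
}

#' Stokes terminal velocity
#'
#' Drag closure for magnetophoresis estimates: a sphere of hydrodynamic
#' radius `radius` pulled by force `force` through a fluid of dynamic
#' viscosity `viscosity` reaches v = F / (6*pi*eta*a). Linear in the force,
#' which is why relative force changes translate directly into relative
#' drift-velocity (and phase-duration) changes.
#'
#' @param force applied force (N).
#' @param radius hydrodynamic radius (m), > 0.
#' @param viscosity dynamic viscosity (Pa s), > 0.
#' @return velocity (m/s).
#' @examples
#' terminalVelocity(1e-12, radius = 1e-6, viscosity = 1e-3)  # ~53 um/s
#' @export
terminalVelocity <- function(force, radius, viscosity) {
  if (radius <= 0 || viscosity <= 0)
    .stopValidation("'radius' and 'viscosity' must be > 0")
  force / (6 * pi * viscosity * radius)
}

#' Force profile of a chain across an assembly
#'
#' Evaluates the full-field chain force along a line of x positions at
#' height z, converting reduced gradients to SI via the stripes' M, and the
#' near-seam asymptotic force for comparison.
#'
#' @param assembly a [MagnetAssembly-class] (stripes carry M in A/m).
#' @param chain a [BMNChain-class].
#' @param x positions (m), non-zero for the asymptotic column.
#' @param z height (m).
#' @return data.frame with `x_mm`, `Fx_pN`, `Fz_pN`, `Fx_asym_pN`, `path`.
#' @export
forceProfile <- function(assembly, chain, x, z) {
  g <- fieldGradients(assembly, x, rep(z, length(x)), reduced = FALSE)
  full <- chainForce(chain, g$dHx_dx, g$dHz_dx, x = x, z = z)
  Br <- .MU0 * assembly@stripes[[1]]@M
  a1 <- assembly@stripes[[1]]@a1
  asym <- rep(NA_real_, length(x))
  ok <- x != 0 & abs(x) / a1 < 0.2
  if (any(ok))
    asym[ok] <- chainForceAsymptotic(chain, x[ok], Br)$Fx
  data.frame(x_mm = x * 1e3, Fx_pN = full$Fx * 1e12, Fz_pN = full$Fz * 1e12,
             Fx_asym_pN = asym * 1e12, path = "chain")
}

setMethod("show", "BMNChain", function(object) {
  cat(sprintf(
    "BMNChain: N = %d, R = %g nm, Ms = %g kA/m, V = %.3g m^3, moment (%.2f, %.2f)\n",
    as.integer(object@N), object@R * 1e9, object@Ms / 1e3,
    chainVolume(object), object@moment[1], object@moment[2]))
})

setMethod("show", "DiamagneticBody", function(object) {
  cat(sprintf(
    "DiamagneticBody: Vb = %.3g m^3, chiB = %g, chiM = %g, deltaChi = %g\n",
    object@Vb, object@chiB, object@chiM, deltaChi(object)))
})
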