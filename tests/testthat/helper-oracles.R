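# Independent oracles the implementation is checked against.

# Surface-magnetic-charge line-integral oracle for a centered stripe
# magnetized along +z: sheets of charge density +/-M at z = +/-a3 spanning
# x in [-a1, a1]; a charged line contributes 2*lambda/r (the 2-D convention
# of the closed forms). Reduced units (M = 1). Independent of the package's
# closed-form path.
surfaceChargeOracle <- function(x, z, a1, a3) {
  fx <- function(xp, z0, s) 2 * s * (x - xp) / ((x - xp)^2 + (z - z0)^2)
  fz <- function(xp, z0, s) 2 * s * (z - z0) / ((x - xp)^2 + (z - z0)^2)
  Hx <- stats::integrate(fx, -a1, a1, z0 = a3, s = 1, rel.tol = 1e-12)$value +
    stats::integrate(fx, -a1, a1, z0 = -a3, s = -1, rel.tol = 1e-12)$value
  Hz <- stats::integrate(fz, -a1, a1, z0 = a3, s = 1, rel.tol = 1e-12)$value +
    stats::integrate(fz, -a1, a1, z0 = -a3, s = -1, rel.tol = 1e-12)$value
  c(Hx = Hx, Hz = Hz)
}

# central-difference derivative of a scalar function of one coordinate
centralDiff <- function(f, x, h = 1e-8) (f(x + h) - f(x - h)) / (2 * h)

# the standard stripe geometry used across the field tests (m)
A1 <- 0.023
A3 <- 0.005
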