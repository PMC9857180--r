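test_that("dipole force follows the gradients linearly", {
  expect_equal(unlist(dipoleForce(0, 1e9, -2e9)[c("Fx", "Fz")]),
               c(Fx = 0, Fz = 0))
  f1 <- dipoleForce(2.5e-16, 1e9, -2e9)
  f2 <- dipoleForce(2.5e-16, -1e9, -2e9)
  expect_equal(f2$Fx, -f1$Fx)
  expect_equal(f2$Fz, f1$Fz)
  # random scaling: all paths linear in the moment argument
  set.seed(3)
  for (i in 1:10) {
    px <- runif(1, 1e-18, 1e-14); s <- runif(1, 0.1, 10)
    g <- runif(2, -1e10, 1e10)
    expect_equal(dipoleForce(s * px, g[1], g[2])$Fx,
                 s * dipoleForce(px, g[1], g[2])$Fx)
  }
})

test_that("chain force equals dipole force under p = Ms * V and scales with N", {
  ch <- BMNChain(N = 20, R = 20e-9, Ms = 412e3)
  expect_equal(chainVolume(ch), 20 * 4 * pi * (20e-9)^3 / 3)
  g <- c(3.2e9, -1.1e9)
  fc <- chainForce(ch, g[1], g[2])
  fd <- dipoleForce(ch@Ms * chainVolume(ch), g[1], g[2])
  expect_equal(fc$Fx, fd$Fx)
  expect_equal(fc$Fz, fd$Fz)
  # and at field-map points of the focusing pair (SI gradients)
  fp <- focusingPair()
  gsi <- fieldGradients(fp, c(-0.002, 0.0015), c(0.0061, 0.0052),
                        reduced = FALSE)
  fc2 <- chainForce(ch, gsi$dHx_dx, gsi$dHz_dx)
  fd2 <- dipoleForce(ch@Ms * chainVolume(ch), gsi$dHx_dx, gsi$dHz_dx)
  expect_equal(fc2$Fx, fd2$Fx)
  expect_equal(fc2$Fz, fd2$Fz)
  # N = 0 chain feels nothing; doubling N doubles the force
  expect_equal(chainForce(BMNChain(0, 20e-9), g[1], g[2])$Fx, 0)
  expect_equal(chainForce(BMNChain(40, 20e-9, 412e3), g[1], g[2])$Fx,
               2 * fc$Fx)
})

test_that("asymptotic chain force has the 1/x law and matches direct SI arithmetic", {
  ch <- BMNChain(N = 20, R = 20e-9, Ms = 412e3)
  f1 <- chainForceAsymptotic(ch, 1e-3, Br = 1)
  f10 <- chainForceAsymptotic(ch, 1e-2, Br = 1)
  expect_equal(f1$Fx / f10$Fx, 10)
  # dimensional-analysis oracle: [1/m][m^3][T][A/m] -> N, evaluated by hand
  # for N = 20, R = 20 nm, x = 1 mm, Br = 1 T, Ms = 412 kA/m:
  # 16*pi/3e-3 * 20 * 8e-24 * 1 * 4.12e5 = 1.1045e-12 N (1.10 pN)
  expect_equal(f1$Fx, 16 * pi / (3 * 1e-3) * 20 * (20e-9)^3 * 1 * 412e3)
  expect_equal(f1$Fx, 1.1045002e-12, tolerance = 1e-6)
  expect_equal(seamForceEstimate()$F_pN, 1.1045002, tolerance = 1e-6)
  # tenfold closer: the quoted-distance companion value
  expect_equal(seamForceEstimate(x = 1e-4)$F_pN, 11.045002, tolerance = 1e-6)
  expect_error(chainForceAsymptotic(ch, 0, Br = 1), class = "mgSingularError")
})

test_that("asymptotic force agrees with the full-gradient chain force near the seam", {
  fp <- focusingPair()
  ch <- BMNChain(N = 20, R = 20e-9, Ms = 412e3)
  Br <- vacuumPermeability() * fp@stripes[[1]]@M
  xs <- A1 * c(0.02, 0.01, 0.005, -0.005, -0.01, -0.02)
  g <- fieldGradients(fp, xs, rep(A3, 6), reduced = FALSE)
  full <- chainForce(ch, g$dHx_dx, g$dHz_dx)$Fx
  asym <- chainForceAsymptotic(ch, xs, Br)$Fx
  expect_equal(asym, full, tolerance = 0.02)
  # opposite signs in the two half-planes: the chain halves are pulled apart
  expect_true(all(sign(full) == sign(xs)))
})

test_that("forces at the stated parameters fall in the pN decade band", {
  fp <- focusingPair()          # Br = 1.2 T
  ch <- BMNChain(N = 20, R = 20e-9, Ms = 412e3)
  prof <- forceProfile(fp, ch, x = c(-1e-3, -1e-4, 1e-4, 1e-3), z = A3 + 2e-4)
  expect_true(all(abs(prof$Fx_pN) > 0.1 & abs(prof$Fx_pN) < 1000))
  expect_true(all(sign(prof$Fx_pN) == sign(prof$x_mm)))
})

test_that("body force is along the modulus gradient for positive contrast", {
  b <- DiamagneticBody(Vb = 1e-18, chiB = -8e-6, chiM = -9.05e-6)
  expect_equal(deltaChi(b), 1.05e-6)
  expect_equal(bodyForce(b, B = 0.5, gradBx = 10, gradBz = -4)$Fx,
               1e-18 * 1.05e-6 * 0.5 * 10 / vacuumPermeability())
  # deltaChi = 0 gives zero force
  b0 <- DiamagneticBody(Vb = 1e-18, chiB = -9e-6, chiM = -9e-6)
  expect_equal(bodyForce(b0, 0.5, 10, -4)$Fx, 0)
  # over the focusing-pair map: stepping along the force direction
  # increases |B| (attraction toward the field maxima)
  fp <- focusingPair()
  M <- fp@stripes[[1]]@M
  mu0 <- vacuumPermeability()
  Bmod <- function(x, z) mu0 * M * assemblyField(fp, x, z)$Hmod
  set.seed(5)
  h <- 1e-7
  for (i in 1:20) {
    x <- runif(1, -1.5, 1.5) * A1
    z <- runif(1, 1.1, 3) * A3
    gx <- centralDiff(function(u) Bmod(u, z), x)
    gz <- centralDiff(function(u) Bmod(x, u), z)
    f <- bodyForce(b, Bmod(x, z), gx, gz)
    step <- 1e-6 / sqrt(f$Fx^2 + f$Fz^2)
    expect_gt(Bmod(x + step * f$Fx, z + step * f$Fz), Bmod(x, z))
    # identity B*gradB = grad(B^2)/2, finite differences on B^2
    g2x <- centralDiff(function(u) Bmod(u, z)^2, x) / 2
    expect_equal(f$Fx, b@Vb * deltaChi(b) * g2x / mu0, tolerance = 1e-5)
    # antiparallel for negative contrast
    bneg <- DiamagneticBody(Vb = 1e-18, chiB = -9.5e-6, chiM = -9e-6)
    fneg <- bodyForce(bneg, Bmod(x, z), gx, gz)
    expect_lt(f$Fx * fneg$Fx + f$Fz * fneg$Fz, 0)
  }
})

test_that("Stokes terminal velocity is the linear drag closure", {
  expect_equal(terminalVelocity(0, 1e-6, 1e-3), 0)
  v1 <- terminalVelocity(1e-12, 1e-6, 1e-3)
  # hand-checked: 1 pN / (6*pi * 1 mPa*s * 1 um) = 53.05 um/s
  expect_equal(v1, 5.30516477e-5, tolerance = 1e-8)
  expect_equal(terminalVelocity(2e-12, 1e-6, 1e-3), 2 * v1)
  expect_error(terminalVelocity(1e-12, 0, 1e-3), class = "mgValidationError")
})

test_that("tilted chain moments use the exterior-field derivative identities", {
  fp <- focusingPair()
  x <- 0.004; z <- 0.0065
  g <- fieldGradients(fp, x, z, reduced = FALSE)
  chz <- BMNChain(N = 20, R = 20e-9, moment = c(0, 1))
  f <- chainForce(chz, g$dHx_dx, g$dHz_dx)
  # oracle: mu0 * (p . grad) H with all four derivatives by finite
  # differences on the SI field
  h <- 1e-8
  dHx_dz <- (assemblyField(fp, x, z + h, reduced = FALSE)$Hx -
             assemblyField(fp, x, z - h, reduced = FALSE)$Hx) / (2 * h)
  dHz_dz <- (assemblyField(fp, x, z + h, reduced = FALSE)$Hz -
             assemblyField(fp, x, z - h, reduced = FALSE)$Hz) / (2 * h)
  p <- chz@Ms * chainVolume(chz)
  expect_equal(f$Fx, vacuumPermeability() * p * dHx_dz, tolerance = 1e-5)
  expect_equal(f$Fz, vacuumPermeability() * p * dHz_dz, tolerance = 1e-5)
})
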