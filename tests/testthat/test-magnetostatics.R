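test_that("closed-form stripe field matches the surface-charge oracle", {
  s <- MagnetStripe(a1 = A1, a3 = A3)
  pts <- list(c(0, A3 + 2e-4),          # just above the top face
              c(0.013, A3 + 7e-4),
              c(-0.03, 0.012),
              c(0.005, -0.009))
  for (p in pts) {
    got <- stripeField(s, p[1], p[2])
    want <- surfaceChargeOracle(p[1], p[2], A1, A3)
    expect_equal(got$Hx, unname(want["Hx"]), tolerance = 1e-9)
    expect_equal(got$Hz, unname(want["Hz"]), tolerance = 1e-9)
  }
  # frozen oracle value at the published evaluation height
  expect_equal(stripeField(s, 0, A3 + 2e-4)$Hz, 1.63488717696,
               tolerance = 1e-9)
})

test_that("stripe field has the parity of the closed forms", {
  s <- MagnetStripe(a1 = A1, a3 = A3)
  set.seed(42)
  x <- runif(25, 0.1, 3) * A1
  z <- runif(25, 1.1, 4) * A3 * sample(c(-1, 1), 25, TRUE)
  fp <- stripeField(s, x, z)
  fm <- stripeField(s, -x, z)
  expect_equal(fm$Hz, fp$Hz, tolerance = 1e-12)
  expect_equal(fm$Hx, -fp$Hx, tolerance = 1e-12)
})

test_that("zero magnetization and sense behave as stated", {
  s0 <- MagnetStripe(a1 = A1, a3 = A3, M = 0)
  f <- stripeField(s0, 0.01, 0.02)
  expect_identical(c(f$Hx, f$Hz), c(0, 0))
  sm <- MagnetStripe(a1 = A1, a3 = A3, sense = -1)
  sp <- MagnetStripe(a1 = A1, a3 = A3, sense = +1)
  expect_equal(stripeField(sm, 0.01, 0.02)$Hz,
               -stripeField(sp, 0.01, 0.02)$Hz)
})

test_that("corner evaluation signals a singular error, near-corner does not", {
  s <- MagnetStripe(a1 = A1, a3 = A3)
  expect_error(stripeField(s, A1, A3), class = "mgSingularError")
  expect_error(assemblyField(focusingPair(), 0, A3), class = "mgSingularError")
  f <- stripeField(s, A1 + 1e-9, A3)
  expect_true(all(is.finite(c(f$Hx, f$Hz))))
})

test_that("assembly field is an exact order-independent superposition", {
  s1 <- MagnetStripe(a1 = A1, a3 = A3, x0 = -A1, sense = -1)
  s2 <- MagnetStripe(a1 = A1, a3 = A3, x0 = +A1, sense = +1)
  x <- c(-0.005, 0.002, 0.04); z <- c(0.006, 0.0052, -0.02)
  f12 <- assemblyField(MagnetAssembly(list(s1, s2)), x, z)
  f21 <- assemblyField(MagnetAssembly(list(s2, s1)), x, z)
  expect_identical(f12$Hx, f21$Hx)
  expect_identical(f12$Hz, f21$Hz)
  fs <- stripeField(s1, x, z)
  ft <- stripeField(s2, x, z)
  expect_equal(f12$Hx, fs$Hx + ft$Hx, tolerance = 1e-14)
  expect_equal(f12$Hz, fs$Hz + ft$Hz, tolerance = 1e-14)
  # two coincident stripes of opposite sense cancel exactly
  canc <- assemblyField(MagnetAssembly(list(
    MagnetStripe(A1, A3, sense = 1), MagnetStripe(A1, A3, sense = -1))),
    x, z)
  expect_equal(canc$Hmod, rep(0, 3))
  # a single-stripe assembly reproduces stripeField exactly
  f1 <- assemblyField(MagnetAssembly(s1), x, z)
  expect_equal(f1$Hx, fs$Hx)
  expect_equal(f1$Hz, fs$Hz)
})

test_that("antiparallel pair has Hx < 0 just above the seam region", {
  fp <- focusingPair()
  x <- seq(-0.01, 0.01, length.out = 41)
  f <- assemblyField(fp, x, rep(A3 + 2e-4, length(x)))
  expect_true(all(f$Hx < 0))
})

test_that("analytic gradients agree with central differences at random exterior points", {
  fp <- focusingPair()
  ic <- incubatorCell()
  set.seed(7)
  for (asm in list(fp, ic)) {
    n <- 100
    # exterior points: outside both stripe bodies
    x <- numeric(0); z <- numeric(0)
    while (length(x) < n) {
      cx <- runif(n, -4, 4) * A1
      cz <- runif(n, -4, 4) * A1
      ok <- !assemblyField(asm, cx, cz)$interior &
        abs(assemblyField(asm, cx, cz)$Hmod) > 1e-6
      x <- c(x, cx[ok]); z <- c(z, cz[ok])
    }
    x <- x[1:n]; z <- z[1:n]
    ga <- fieldGradients(asm, x, z, method = "analytic")
    gf <- fieldGradients(asm, x, z, method = "finite_difference",
                         step = 1e-6 * A1)
    expect_equal(ga$dHx_dx, gf$dHx_dx, tolerance = 1e-6)
    expect_equal(ga$dHz_dx, gf$dHz_dx, tolerance = 1e-6)
  }
  expect_error(fieldGradients(fp, 0.001, 0.006,
                              method = "finite_difference", step = 0),
               class = "mgValidationError")
})

test_that("dHx/dx changes sign across the seam and vanishes for M = 0", {
  fp <- focusingPair()
  z <- A3 + 2e-4
  gl <- fieldGradients(fp, -0.002, z)
  gr <- fieldGradients(fp, +0.002, z)
  expect_lt(gl$dHx_dx, 0)
  expect_gt(gr$dHx_dx, 0)
  dead <- MagnetAssembly(MagnetStripe(A1, A3, M = 0))
  g0 <- fieldGradients(dead, 0.002, z)
  expect_identical(c(g0$dHx_dx, g0$dHz_dx), c(0, 0))
})

test_that("exterior field is curl-free and decays along rays", {
  fp <- focusingPair()
  set.seed(11)
  h <- 1e-7
  for (i in 1:25) {
    x <- runif(1, -3, 3) * A1
    z <- sample(c(-1, 1), 1) * runif(1, 1.3, 4) * A3
    dHx_dz <- (assemblyField(fp, x, z + h)$Hx -
               assemblyField(fp, x, z - h)$Hx) / (2 * h)
    dHz_dx <- fieldGradients(fp, x, z)$dHz_dx
    expect_lt(abs(dHx_dz - dHz_dx), 1e-6 / A1)
  }
  # monotone decay beyond 10*a1 along rays from the assembly center
  for (theta in c(0.3, 1.0, 1.8, 2.6, 4.0, 5.5)) {
    r <- seq(10, 30, length.out = 21) * A1
    mod <- assemblyField(fp, r * cos(theta), r * sin(theta))$Hmod
    expect_true(all(diff(mod) < 0))
  }
})

test_that("seam asymptote has the stated structure and scaling", {
  # explicit 1/x form: tenfold closer means tenfold larger gradient
  a <- boundaryAsymptote(c(1e-3, 1e-4), a1 = A1)
  expect_equal(abs(a$dHx_dx[2]), 10 * abs(a$dHx_dx[1]))
  # ln(a1/a1) = 0 at the validity-window boundary argument
  expect_equal(boundaryAsymptote(0.1 * A1, a1 = A1, window = 1.0)$Hx[1],
               -4 * log(10), tolerance = 1e-12)
  expect_error(boundaryAsymptote(0, a1 = A1), class = "mgSingularError")
  expect_error(boundaryAsymptote(0.5 * A1, a1 = A1),
               class = "mgValidationError")
  # sign conventions are exact opposites
  af <- boundaryAsymptote(1e-3, A1, signConvention = "field_map")
  ap <- boundaryAsymptote(1e-3, A1, signConvention = "printed")
  expect_equal(af$Hx, -ap$Hx)
  expect_equal(af$dHx_dx, -ap$dHx_dx)
})

test_that("asymptote converges to the full field at the seam (convergence study)", {
  fp <- focusingPair()
  xs <- A1 * c(0.05, 0.02, 0.01, 0.005, 0.002)
  full <- abs(assemblyField(fp, xs, rep(A3, 5))$Hx)
  asym <- abs(boundaryAsymptote(xs, A1)$Hx)
  # the field asymptote differs from the full solution by a constant
  # logarithmic offset (far edges + bottom faces), so the ratio decreases
  # monotonically toward 1 while the difference is x-independent
  ratio <- asym / full
  expect_true(all(diff(ratio) < 0))
  expect_true(all(ratio > 1 & ratio < 1.45))
  offs <- asym - full
  expect_lt(max(offs) - min(offs), 0.02 * mean(offs))
  # the gradient asymptote converges fast: within 2% for |x|/a1 <= 0.02 at
  # the magnet top surface (measured <= 0.3%)
  gs <- fieldGradients(fp, xs, rep(A3, 5))$dHx_dx
  ga <- boundaryAsymptote(xs, A1)$dHx_dx
  expect_equal(ga[-1], gs[-1], tolerance = 0.02)
})

test_that("field maps carry complete samples and locate the gradient maximum at the seam", {
  fp <- focusingPair()
  map <- fieldMap(fp, xlim = c(-0.02, 0.02), zlim = c(A3 + 2e-4, 0.02),
                  nx = 41, nz = 6)
  df <- as.data.frame(map)
  expect_equal(nrow(df), 41 * 6)
  expect_true(all(is.finite(df$Hmod)))
  expect_equal(df$Hmod, sqrt(df$Hx^2 + df$Hz^2), tolerance = 1e-12)
  # d|H|/dx from the stored components and gradients; its maximum magnitude
  # sits at the nodes nearest the inter-magnet seam (x = 0)
  dmod <- with(df, (Hx * dHx_dx + Hz * dHz_dx) / Hmod)
  expect_lte(abs(df$x[which.max(abs(dmod))]), 0.001 + 1e-12)
  # Hz is odd-like and Hx single-signed (dip) near the center at map height
  row1 <- df[df$z == df$z[1] & abs(df$x) <= 0.01, ]
  expect_true(all(row1$Hx < 0))
  expect_equal(row1$Hz + rev(row1$Hz), rep(0, nrow(row1)), tolerance = 1e-9)
  # a one-point grid equals assemblyField + fieldGradients there
  m1 <- fieldMap(fp, xlim = c(0.003, 0.003), zlim = c(0.0061, 0.0061),
                 nx = 1, nz = 1)
  d1 <- as.data.frame(m1)
  expect_equal(d1$Hx, assemblyField(fp, 0.003, 0.0061)$Hx)
  expect_equal(d1$dHx_dx, fieldGradients(fp, 0.003, 0.0061)$dHx_dx)
  # empty / degenerate grids are rejected
  expect_error(fieldMap(fp, c(0, 0.01), c(0.006, 0.01), nx = 0, nz = 2),
               class = "mgValidationError")
  # exact corner nodes are nudged, with a message
  expect_message(
    fieldMap(fp, xlim = c(0, 0), zlim = c(A3, A3), nx = 1, nz = 1),
    "nudging")
})

test_that("rotated stripes reproduce the 90-degree-rotated solution", {
  sz <- MagnetStripe(A1, A3, sense = 1, axis = "z")
  sx <- MagnetStripe(A1, A3, sense = 1, axis = "x")
  # point (x, z) for the z-magnetized stripe maps to (z, -x) for the
  # x-magnetized one; components rotate with it
  x <- 0.011; z <- 0.017
  fz <- stripeField(sz, x, z)
  fx <- stripeField(sx, z, -x)
  expect_equal(fx$Hx, fz$Hz, tolerance = 1e-12)
  expect_equal(fx$Hz, -fz$Hx, tolerance = 1e-12)
})
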