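test_that("bare-pore conductance follows the pore + access formula", {
  expect_equal(bare_pore_conductance(pore_model(20, 20, 4.30)),
               4.30 / (4 * 20 / (pi * 400) + 1 / 20))
  expect_equal(round(bare_pore_conductance(pore_model(20, 20, 4.30)), 2),
               37.83)
  expect_equal(bare_pore_conductance(pore_model(sigma_bare = 0)), 0)
  # zero-length pore: pure access limit sigma_bare * d
  expect_equal(bare_pore_conductance(pore_model(20, 0, 4.30)), 4.30 * 20)
})

test_that("local conductivity decreases linearly and clamps at rho_crit", {
  m <- pore_model()
  expect_equal(local_conductivity(0, m), 4.30)
  expect_equal(local_conductivity(85, m), 0)
  expect_equal(local_conductivity(42.5, m), 2.15)
  expect_equal(local_conductivity(c(100, 500), m), c(0, 0))
})

test_that("region conductivity integrates radial profiles exactly", {
  m <- pore_model(diameter = 20)
  r <- seq(0.25, 9.75, by = 0.5)
  # zero density -> bare conductivity
  expect_equal(region_conductivity(tibble::tibble(r = r, rho = 0), m), 4.30)
  # constant rho_crit/2 -> half
  expect_equal(region_conductivity(tibble::tibble(r = r, rho = 42.5), m),
               2.15)
  # blocked inner quarter-radius: 1 - (1/4)^2 * ... = 0.75^... area fractions
  rho <- ifelse(r < 5, 85, 0)
  expect_equal(region_conductivity(tibble::tibble(r = r, rho = rho), m),
               4.30 * (1 - (5 / 10)^2))
  expect_error(region_conductivity(tibble::tibble(r = r, rho = -1), m),
               "Negative")
})

test_that("coated-pore and ring-on-pore equations reduce to the bare pore", {
  m <- pore_model()
  r <- seq(0.25, 9.75, by = 0.5)
  zero <- tibble::tibble(r = r, rho = rep(0, length(r)))
  g0 <- bare_pore_conductance(m)
  expect_equal(coated_pore_conductance(zero, zero, m)$G, g0,
               tolerance = 1e-14)
  expect_equal(ring_on_pore_conductance(zero, zero, m)$G, g0,
               tolerance = 1e-14)
})

test_that("coated-pore conductance matches its closed form", {
  m <- pore_model()
  r <- seq(0.25, 9.75, by = 0.5)
  # sigma_pore = sigma_bare / 2, sigma_access = sigma_bare
  res <- coated_pore_conductance(tibble::tibble(r = r, rho = 42.5),
                                 tibble::tibble(r = r, rho = 0), m)
  d <- 20; l <- 20
  expect_equal(res$G, 1 / (4 * l / (pi * d^2 * 2.15) + 1 / (d * 4.30)))
  # any nonzero density reduces G below the bare-pore value
  g0 <- bare_pore_conductance(m)
  expect_lt(res$G, g0)
})

test_that("ring-on-pore conductance matches the quadrature oracle", {
  m <- pore_model()
  r <- seq(0.25, 24.75, by = 0.5)
  gauss <- tibble::tibble(r = r, rho = 60 * exp(-r^2 / (2 * 8^2)))
  attr(gauss, "zwindow") <- c(-27, 7)
  acc <- tibble::tibble(r = r, rho = 30 * exp(-r^2 / (2 * 10^2)))
  attr(acc, "zwindow") <- c(-7, 33)
  res <- ring_on_pore_conductance(gauss, acc, m)
  sp <- oracle_region_sigma(gauss, m)
  sa <- oracle_region_sigma(acc, m)
  g_oracle <- 1 / (4 * 20 / (pi * 400 * sp) + 1 / (2 * 20 * sa) +
                     1 / (2 * 20 * 4.30))
  expect_equal(res$G, g_oracle, tolerance = 1e-6)
  # sigma_access -> sigma_bare recovers the top/bottom-symmetric form
  res2 <- ring_on_pore_conductance(gauss, tibble::tibble(r = r, rho = 0), m,
                                   check_windows = FALSE)
  sp2 <- res2$sigma_pore
  expect_equal(res2$G, 1 / (4 * 20 / (pi * 400 * sp2) + 1 / (20 * 4.30)))
})

test_that("mis-ordered density windows are rejected with a report", {
  m <- pore_model()
  r <- seq(0.25, 9.75, by = 0.5)
  p <- tibble::tibble(r = r, rho = 10); attr(p, "zwindow") <- c(-27, 7)
  a <- tibble::tibble(r = r, rho = 10); attr(a, "zwindow") <- c(-40, -30)
  expect_error(ring_on_pore_conductance(p, a, m), "below the pore window")
})

test_that("conductance is monotone non-increasing in the density", {
  m <- pore_model()
  r <- seq(0.25, 9.75, by = 0.5)
  base <- 40 * exp(-r / 6)
  gs <- vapply(seq(0, 2, by = 0.25), function(f) {
    p <- tibble::tibble(r = r, rho = f * base)
    coated_pore_conductance(p, p, m)$G
  }, numeric(1))
  expect_true(all(diff(gs) <= 1e-12))
})

test_that("relative conductance and blockade percentages", {
  expect_equal(relative_conductance(37.8, 37.8)$fraction, 1)
  expect_equal(relative_conductance(0, 37.8)$reduction_pct, 100)
  rc <- relative_conductance(32.9, 37.8)
  expect_equal(rc$fraction, 0.8704, tolerance = 1e-4)
  expect_equal(rc$reduction_pct, 12.96, tolerance = 1e-3)
  # tidy/glance surface
  m <- pore_model()
  r <- seq(0.25, 9.75, by = 0.5)
  res <- coated_pore_conductance(tibble::tibble(r = r, rho = 20),
                                 tibble::tibble(r = r, rho = 10), m)
  expect_s3_class(tidy(res), "tbl_df")
  gl <- glance(res)
  expect_equal(gl$G, res$G)
  expect_lt(gl$fraction, 1)
})
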