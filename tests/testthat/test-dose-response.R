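test_that("fourPL evaluates the log-logistic model at its landmarks", {
  expect_equal(fourPL(1e-7, 100, 0, 1, 1e-7), 50)
  expect_equal(fourPL(1e-12, 100, 0, 1, 1e-7), 100, tolerance = 1e-4)
  expect_equal(fourPL(1e-2, 100, 0, 1, 1e-7), 0, tolerance = 2e-3)
  # positive slope = decreasing response
  d <- 10^seq(-10, -5, length.out = 20)
  expect_true(all(diff(fourPL(d, 100, 0, 1.5, 1e-7)) < 0))
})

test_that("zPrime matches hand computation and its identities", {
  # SD = 0 on both sides gives exactly 1
  expect_equal(zPrime(c(5, 5, 5), c(100, 100, 100)), 1)
  # sample-SD hand computation: sd(c(100,100,90,110)) = sqrt(200/3)
  expect_equal(zPrime(c(0, 0, 0, 0), c(100, 100, 90, 110)),
               1 - 3 * sqrt(200 / 3) / 100)
  # printed and standard denominators agree when mean_pos = 0
  pos <- c(-2, 2, 1, -1); neg <- c(95, 105, 100, 102)
  expect_equal(zPrime(pos, neg, "printed"), zPrime(pos, neg, "standard"))
  # invariant under common rescaling of all control values (both modes)
  for (m in c("printed", "standard")) {
    expect_equal(zPrime(7 * c(1, 2, 3), 7 * c(90, 100, 110), m),
                 zPrime(c(1, 2, 3), c(90, 100, 110), m))
  }
})

test_that("zPrime rejects degenerate inputs", {
  expect_error(zPrime(1, c(1, 2)), "at least 2")
  expect_error(zPrime(c(-100, -100), c(100, 100), "printed"), "degenerate")
})

test_that("normalizeToVehicle scales to the per-plate vehicle mean", {
  p <- data.frame(plate = rep(c("A", "B"), each = 3),
                  role = c("neg", "neg", "sample", "neg", "neg", "sample"),
                  signal = c(2e6, 2e6, 1.1e6, 1e6, 1e6, 0))
  out <- normalizeToVehicle(p)
  expect_equal(out$response, c(100, 100, 55, 100, 100, 0))
  p$role[p$plate == "B"] <- "sample"
  expect_error(normalizeToVehicle(p), "B")
})

test_that("fit4PL recovers noiseless parameters within 1%", {
  d <- screenDoses()
  for (pars in list(c(100, 0, 1, 1e-7), c(105, 12, 0.8, 3e-8),
                    c(98, 5, 2, 5e-7))) {
    y <- fourPL(d, pars[1], pars[2], pars[3], pars[4])
    fit <- fit4PL(d, y)
    expect_true(isConverged(fit))
    expect_equal(unname(coef(fit)), pars, tolerance = 0.01)
    expect_gt(fitR2(fit), 0.999)
  }
})

test_that("fit4PL supports a fixed slope of 1", {
  d <- screenDoses()
  y <- fourPL(d, 100, 0, 1, 5e-8)
  fit <- fit4PL(d, y, fixedSlope = 1)
  expect_equal(fit@slope, 1)
  expect_equal(ec50(fit), 5e-8, tolerance = 0.01)
})

test_that("degenerate inputs give flat fits or errors", {
  d <- screenDoses()
  expect_error(fit4PL(d[1:3], c(1, 2, 3)), "4 distinct")
  flat <- fit4PL(d, rep(100, 11))
  expect_true(flat@flat)
  expect_true(isConverged(flat))
  expect_true(is.na(ec50(flat)))
  expect_true(is.na(pec50(flat)))
  expect_equal(fitAuc(flat), 100)
  expect_equal(fitR2(flat), 0)
})

test_that("a >10-fold potency shift is detected by refitting", {
  # monotherapy EC50 58 nM; combination shifts potency by x0.034
  d <- screenDoses()
  mono <- fit4PL(d, fourPL(d, 100, 0, 1, 58e-9))
  combo <- fit4PL(d, fourPL(d, 100, 0, 1, 58e-9 * 0.034))
  expect_equal(ec50(mono), 58e-9, tolerance = 0.01)
  expect_lt(ec50(combo), 2e-9)
  expect_gt(ec50(mono) / ec50(combo), 10)
})

test_that("curveAuc handles flat curves and log-symmetric midpoints", {
  d <- screenDoses()
  expect_equal(fitAuc(fit4PL(d, rep(100, 11))), 100)
  expect_equal(fitAuc(fit4PL(d, rep(0, 11))), 0)
  # ec50 at the geometric midpoint of a symmetric log range -> AUC 50
  fit <- fit4PL(d, fourPL(d, 100, 0, 1, sqrt(min(d) * max(d))))
  expect_equal(curveAuc(fit, min(d), max(d)), 50, tolerance = 0.1)
  expect_error(curveAuc(fit, 1e-6, 1e-7), "dmin < dmax")
})

test_that("trapezoid AUC matches adaptive quadrature", {
  set.seed(42)
  d <- screenDoses()
  for (i in 1:25) {
    top <- runif(1, 80, 110); bottom <- runif(1, -10, 40)
    slope <- runif(1, 0.3, 3); ec <- 10^runif(1, -9.5, -5.5)
    fit <- new("CurveFit", top = top, bottom = bottom, slope = slope,
               ec50 = ec, r2 = 1, auc = NA_real_, converged = TRUE,
               flat = FALSE, doseRange = range(d), n = 11L, sse = 0)
    oracle <- integrate(function(x)
      pmin(pmax(fourPL(10^x, top, bottom, slope, ec), 0), 100),
      log10(min(d)), log10(max(d)), rel.tol = 1e-10)$value /
      (log10(max(d)) - log10(min(d)))
    expect_equal(curveAuc(fit, min(d), max(d)), oracle, tolerance = 1e-3)
  }
})

test_that("pointwise-lower curves have lower AUC", {
  set.seed(7)
  d <- screenDoses()
  for (i in 1:20) {
    ec <- 10^runif(1, -9, -6); slope <- runif(1, 0.5, 2.5)
    hi <- fit4PL(d, fourPL(d, 100, 20, slope, ec))
    lo <- fit4PL(d, fourPL(d, 90, 5, slope, ec))
    expect_lt(fitAuc(lo), fitAuc(hi))
  }
})

test_that("parameter recovery stays accurate under 5% noise", {
  set.seed(13)
  d <- screenDoses()
  relErr <- replicate(60, {
    ec <- 10^runif(1, -8.5, -6.5)
    y <- fourPL(d, runif(1, 95, 105), runif(1, 0, 20), runif(1, 0.7, 2),
                ec) * exp(rnorm(11, 0, 0.05))
    abs(ec50(fit4PL(d, y)) - ec) / ec
  })
  expect_lt(median(relErr), 0.2)
})

test_that("efficacy rule uses strict thresholds with reason codes", {
  expect_true(classifyEfficacy(auc = 40, pec50 = 7.5, r2 = 0.95)$efficacious)
  res <- classifyEfficacy(auc = 85, pec50 = 7.5, r2 = 0.95)
  expect_false(res$efficacious)
  expect_equal(res$reasons, "auc")
  # strictly inside every boundary still passes
  expect_true(classifyEfficacy(auc = 79.9, pec50 = 6.01,
                               r2 = 0.801)$efficacious)
  # exactly on a boundary fails (strict inequalities)
  expect_false(classifyEfficacy(auc = 80, pec50 = 6.01, r2 = 0.9)$efficacious)
  res <- classifyEfficacy(auc = 90, pec50 = 5, r2 = 0.5)
  expect_setequal(res$reasons, c("auc", "pec50", "r2"))
})

test_that("plateQC reports one Z-prime row per plate", {
  p <- rbind(
    data.frame(plate = "A", role = rep(c("neg", "pos"), each = 4),
               signal = c(100, 102, 98, 100, 0, 1, 0, 1)),
    data.frame(plate = "B", role = rep(c("neg", "pos"), each = 4),
               signal = c(200, 204, 196, 200, 0, 2, 0, 2)))
  qc <- plateQC(p)
  expect_equal(nrow(qc), 2)
  # both plates are the same data up to scale -> identical Z-prime
  expect_equal(qc$z_prime[1], qc$z_prime[2])
})
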