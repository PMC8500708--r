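test_that("ISA forward model has the forced limiting behaviors", {
  # D=1, g=1 with M2 acetyl: all mass at M16
  p <- isa_forward(1, 1, c(0, 0, 1))
  expect_equal(length(p), 17L)
  expect_mid_equal(p, c(rep(0, 16), 1), tol = 1e-12)
  # g=0: no new synthesis regardless of D
  for (D in c(0, 0.4, 1))
    expect_mid_equal(isa_forward(D, 0, c(0, 0, 1)), c(1, rep(0, 16)),
                     tol = 1e-12)
  # D=0.5, g=1: even-mass binomial(8, 1/2), enumerable over 2^8 choices
  p <- isa_forward(0.5, 1, c(0, 0, 1))
  brute <- numeric(17)
  for (pattern in 0:(2^8 - 1)) {
    k <- sum(bitwAnd(bitwShiftR(pattern, 0:7), 1L))
    brute[2 * k + 1] <- brute[2 * k + 1] + 0.5^8
  }
  expect_mid_equal(p, brute, tol = 1e-12)
  expect_error(isa_forward(1.2, 0.5), "D")
  expect_error(isa_forward(0.5, -0.1), "g")
})

test_that("forward MPE identities hold", {
  # with g=1 and fully labeled acetyl, palmitate MPE equals D
  for (D in seq(0, 1, by = 0.2))
    expect_equal(mpe(isa_forward(D, 1, c(0, 0, 1))), D, tolerance = 1e-12)
  # monotone in D and in g
  mpes_D <- vapply(seq(0, 1, 0.1), function(D)
    mpe(isa_forward(D, 0.7, c(0, 0, 1))), numeric(1))
  expect_true(all(diff(mpes_D) >= 0))
  mpes_g <- vapply(seq(0, 1, 0.1), function(g)
    mpe(isa_forward(0.6, g, c(0, 1, 0))), numeric(1))
  expect_true(all(diff(mpes_g) >= 0))
})

test_that("noise-free round trip recovers D and g for M2 and M1 acetyl", {
  for (ac in list(c(0, 0, 1), c(0, 1, 0))) {
    for (truth in list(c(0.4, 0.6), c(0.15, 0.9), c(0.8, 0.3))) {
      sim <- isa_forward(truth[1], truth[2], ac)
      fit <- isa_fit(as.numeric(sim), acetyl_mid = ac)
      expect_equal(fit$D, truth[1], tolerance = 1e-6)
      expect_equal(fit$g, truth[2], tolerance = 1e-6)
    }
  }
})

test_that("stearate chain length is supported", {
  sim <- isa_forward(0.5, 0.8, c(0, 0, 1), chain_length = 9)
  expect_length(sim, 19L)
  fit <- isa_fit(as.numeric(sim), acetyl_mid = c(0, 0, 1), chain_length = 9)
  expect_equal(fit$D, 0.5, tolerance = 1e-6)
  expect_equal(fit$g, 0.8, tolerance = 1e-6)
})

test_that("all-M0 measurements pin g at zero and flag D", {
  fit <- isa_fit(c(1, rep(0, 16)))
  expect_equal(fit$g, 0)
  expect_true(is.na(fit$D))
  expect_match(fit$flags, "unidentifiable")
  ci <- isa_ci(fit)
  expect_match(ci$flags, "unidentifiable")
})

test_that("noisy estimates have small bias at the study noise level", {
  set.seed(57)
  D <- numeric(100); g <- numeric(100)
  for (i in 1:100) {
    ds <- synth_isa_dataset(0.3, 0.5, c(0, 0, 1), noise_sd = 0.003,
                            seed = 1000 + i)
    fit <- isa_fit(ds$values, ds$sd, acetyl_mid = c(0, 0, 1))
    D[i] <- fit$D; g[i] <- fit$g
  }
  expect_lt(abs(mean(D) - 0.3), 0.02)
  expect_lt(abs(mean(g) - 0.5), 0.02)
})

test_that("profile CIs shrink with noise and cover the point estimate", {
  sim <- isa_forward(0.35, 0.65, c(0, 0, 1))
  fit <- isa_fit(as.numeric(sim), sd = rep(1e-5, 17), acetyl_mid = c(0, 0, 1),
                 sd_floor = 1e-5)
  ci <- isa_ci(fit)
  expect_lt(ci$D[["upper"]] - ci$D[["lower"]], 1e-3)
  expect_lt(ci$g[["upper"]] - ci$g[["lower"]], 1e-3)
  expect_lte(ci$D[["lower"]], fit$D); expect_gte(ci$D[["upper"]], fit$D)
  # wider SDs widen the interval
  fit2 <- isa_fit(as.numeric(sim), sd = rep(0.01, 17),
                  acetyl_mid = c(0, 0, 1))
  ci2 <- isa_ci(fit2)
  expect_gt(ci2$D[["upper"]] - ci2$D[["lower"]],
            ci$D[["upper"]] - ci$D[["lower"]])
})

test_that("ISA profile CIs achieve near-nominal coverage", {
  set.seed(91)
  hits_D <- 0; n_rep <- 40
  for (i in 1:n_rep) {
    ds <- synth_isa_dataset(0.4, 0.6, c(0, 0, 1), noise_sd = 0.003,
                            seed = 2000 + i)
    fit <- isa_fit(ds$values, ds$sd, acetyl_mid = c(0, 0, 1))
    ci <- isa_ci(fit)
    if (ci$D[["lower"]] <= 0.4 && ci$D[["upper"]] >= 0.4)
      hits_D <- hits_D + 1
  }
  expect_gte(hits_D / n_rep, 0.8)   # binomial slack around 0.95 at n = 40
})

test_that("CI non-overlap predicate is simple interval arithmetic", {
  expect_true(ci_nonoverlap(c(0.2, 0.3), c(0.4, 0.5)))
  expect_true(ci_nonoverlap(c(0.4, 0.5), c(0.2, 0.3)))
  expect_false(ci_nonoverlap(c(0.2, 0.45), c(0.4, 0.5)))
})
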