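test_that("uninformative initialisation gives flat Beta(1,1) everywhere", {
  st <- betaState(fineDomain(1), "efficacy")
  expect_equal(dim(st$alpha), c(101L, 1L))
  expect_true(all(st$alpha == 1) && all(st$beta == 1))
  expect_equal(stateMedian(st, "efficacy"), rep(0.5, 101))
  expect_identical(st$n_obs, 0L)
  expect_error(betaState(fineDomain(1), "badchannel"))
})

test_that("expert priors place the beta mode at the expert prediction", {
  pr <- expertPrior(0.2, 3)
  expect_equal(pr$alpha0, 1.6)
  expect_equal(pr$beta0, 3.4)
  # mode (alpha - 1) / (alpha + beta - 2)
  expect_equal((pr$alpha0 - 1) / (pr$alpha0 + pr$beta0 - 2), 0.2)
  expect_equal(expertPrior(1, 20)$alpha0, 21)
  expect_equal(expertPrior(1, 20)$beta0, 1)
  # zero confidence reduces to the uninformative prior
  zero <- expertPrior(0.5, 0)
  expect_equal(c(zero$alpha0, zero$beta0), c(1, 1))
  # mode recovery across a parameter grid
  for (p in seq(0.05, 0.95, by = 0.15)) {
    for (cc in c(1, 3, 20)) {
      pr <- expertPrior(p, cc)
      dens_argmax <- optimize(function(x) dbeta(x, pr$alpha0, pr$beta0),
                              c(0, 1), maximum = TRUE, tol = 1e-9)$maximum
      expect_equal(dens_argmax, p, tolerance = 1e-6)
    }
  }
  expect_error(expertPrior(1.2, 3), "\\[0, 1\\]")
  expect_error(expertPrior(0.5, -1), "non-negative")
})

test_that("a single efficacious observation updates by kernel similarity", {
  dom <- half_similar_domain()
  st <- betaState(dom, "efficacy")
  st <- updateState(st, makeObservations(0, efficacy = 1), kernelSpec(0.2))
  # tested dose gains exactly 1; the 50%-similar dose gains 0.5
  expect_equal(unname(st$alpha[, "efficacy"]), c(2, 1.5))
  expect_equal(unname(st$beta[, "efficacy"]), c(1, 1))
  expect_identical(st$n_obs, 1L)
  # a non-response adds the same mass to beta instead
  st2 <- updateState(betaState(dom, "efficacy"),
                     makeObservations(0, efficacy = 0), kernelSpec(0.2))
  expect_equal(unname(st2$alpha[, "efficacy"]), c(1, 1))
  expect_equal(unname(st2$beta[, "efficacy"]), c(2, 1.5))
})

test_that("repeated observations at one dose reproduce simple counting", {
  # 5 responders + 1 non-responder at dose 0.7 with a near-degenerate kernel
  dom <- doseDomain(c(0.1, 0.7))
  st <- betaState(dom, "efficacy")
  obs <- makeObservations(rep(0.7, 6), efficacy = c(1, 1, 1, 1, 1, 0))
  st <- updateState(st, obs, kernelSpec(1e-6))
  expect_equal(unname(st$alpha[2, "efficacy"]), 6)
  expect_equal(unname(st$beta[2, "efficacy"]), 2)
  # the distant dose is untouched up to negligible mass
  expect_equal(unname(st$alpha[1, "efficacy"]), 1)
  # uncorrelated rule gives the same counts directly
  stu <- updateStateUncorrelated(betaState(dom, "efficacy"), obs)
  expect_equal(unname(stu$alpha[2, "efficacy"]), 6)
  expect_equal(unname(stu$beta[2, "efficacy"]), 2)
})

test_that("kernel mass is conserved across both channels", {
  set.seed(99)
  dom <- doseGrid(2, 5)
  spec <- kernelSpec(c(0.3, 0.3))
  st <- betaState(dom, c("efficacy", "toxicity"))
  n_obs <- 200
  obs <- makeObservations(matrix(runif(2 * n_obs), ncol = 2),
                          efficacy = rbinom(n_obs, 1, 0.6),
                          toxicity = rbinom(n_obs, 1, 0.3))
  st <- updateState(st, obs, spec)
  doses <- as.matrix(obs[, c("dose_1", "dose_2")])
  for (r in c("efficacy", "toxicity")) {
    expected <- rowSums(vapply(seq_len(n_obs), function(j) {
      kernelRow(doses[j, ], dom, spec)
    }, numeric(nDoses(dom))))
    gained <- (st$alpha[, r] + st$beta[, r]) - (st$alpha0[, r] + st$beta0[, r])
    expect_equal(unname(gained), expected, tolerance = 1e-9)
  }
  expect_identical(st$n_obs, 200L)
})

test_that("batch absorption is order-independent", {
  set.seed(7)
  dom <- doseDomain(seq(0, 1, by = 0.1))
  spec <- kernelSpec(0.2)
  obs <- makeObservations(runif(30), efficacy = rbinom(30, 1, 0.5))
  st1 <- updateState(betaState(dom, "efficacy"), obs, spec)
  st2 <- updateState(betaState(dom, "efficacy"),
                     obs[sample.int(30), ], spec)
  expect_equal(st1$alpha, st2$alpha)
  expect_equal(st1$beta, st2$beta)
})

test_that("vanishing kernel lengths reproduce the uncorrelated update", {
  set.seed(11)
  dom <- coarseDomain(1)
  idx <- sample.int(6, 40, replace = TRUE)
  obs <- makeObservations(dom$doses[idx, , drop = FALSE],
                          efficacy = rbinom(40, 1, 0.5))
  tiny <- updateState(betaState(dom, "efficacy"), obs, kernelSpec(1e-4))
  uncor <- updateStateUncorrelated(betaState(dom, "efficacy"), obs)
  expect_equal(tiny$alpha, uncor$alpha, tolerance = 1e-9)
  expect_equal(tiny$beta, uncor$beta, tolerance = 1e-9)
  # uncorrelated updates insist on domain membership
  expect_error(updateStateUncorrelated(betaState(dom, "efficacy"),
                                       makeObservations(0.31, efficacy = 1)),
               "domain")
})

test_that("observations must carry at least one recorded response", {
  expect_error(makeObservations(0.5), "at least one response")
  expect_error(makeObservations(0.5, efficacy = 2), "0, 1 or NA")
})

test_that("posterior medians are exact beta quantiles", {
  dom <- half_similar_domain()
  st <- betaState(dom, "efficacy")
  st <- updateState(st, makeObservations(0, efficacy = 1), kernelSpec(0.2))
  med <- stateMedian(st, "efficacy")
  # Beta(2,1) has CDF x^2, so its median is sqrt(0.5)
  expect_equal(med[[1]], sqrt(0.5))
  expect_equal(med[[2]], qbeta(0.5, 1.5, 1))
  # increasing alpha at fixed beta strictly increases the median
  alphas <- seq(1, 8, by = 0.5)
  meds <- qbeta(0.5, alphas, 2)
  expect_true(all(diff(meds) > 0))
})

test_that("posterior sampling is reproducible and distributionally sound", {
  dom <- doseDomain(seq(0, 1, by = 0.25))
  st <- betaState(dom, "efficacy")
  set.seed(5)
  a <- sampleProbs(st, "efficacy")
  set.seed(5)
  b <- sampleProbs(st, "efficacy")
  expect_identical(a, b)
  # flat-prior draws are uniform
  set.seed(6)
  draws <- replicate(2000, sampleProbs(st, "efficacy")[[1]])
  expect_gt(ks.test(draws, "punif")$p.value, 0.01)
  # concentrated state: Beta(1000, 1) mass sits above 0.99
  stc <- st
  stc$alpha[1, "efficacy"] <- 1000
  set.seed(7)
  high <- replicate(1000, sampleProbs(stc, "efficacy")[[1]])
  expect_true(all(high > 0.99))
})

test_that("credible intervals bracket the median and tighten with data", {
  dom <- doseDomain(c(0, 1))
  st <- betaState(dom, "efficacy")
  ci <- credibleInterval(st, 1, "efficacy", 0.95)
  expect_equal(unname(ci), c(0.025, 0.975))
  expect_error(credibleInterval(st, 1, "efficacy", 1.2), "between 0 and 1")
  set.seed(12)
  for (rep in 1:20) {
    a <- runif(1, 0.5, 20)
    b <- runif(1, 0.5, 20)
    st$alpha[1, "efficacy"] <- a
    st$beta[1, "efficacy"] <- b
    ci <- credibleInterval(st, 1, "efficacy")
    med <- stateMedian(st, "efficacy")[[1]]
    expect_true(ci[["lo"]] < med && med < ci[["hi"]])
  }
  # proportional scaling of both parameters shrinks the interval
  widths <- vapply(c(1, 2, 5, 10, 50), function(s) {
    st$alpha[1, "efficacy"] <- 3 * s
    st$beta[1, "efficacy"] <- 2 * s
    diff(credibleInterval(st, 1, "efficacy"))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("states and observation logs round-trip through CSV", {
  dom <- doseGrid(2, 3)
  st <- betaState(dom, c("efficacy", "toxicity"))
  set.seed(3)
  obs <- makeObservations(matrix(runif(10), ncol = 2),
                          efficacy = rbinom(5, 1, 0.5),
                          toxicity = c(0, 1, NA, 1, 0))
  st <- updateState(st, obs, kernelSpec(c(0.25, 0.25)))
  state_path <- withr::local_tempfile(fileext = ".csv")
  writeStateCsv(st, state_path)
  back <- readStateCsv(state_path)
  expect_equal(back$alpha, st$alpha)
  expect_equal(back$beta, st$beta)
  expect_equal(back$domain$doses, st$domain$doses)
  obs_path <- withr::local_tempfile(fileext = ".csv")
  writeObservationsCsv(obs, obs_path)
  expect_equal(readObservationsCsv(obs_path), obs)
})
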