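test_that("proportions normalize to 1.0 at the first time point", {
  h <- population_history(c(0, 10),
                          cbind(a = c(100, 150), b = c(100, 50)))
  P <- compute_proportions(h)$P
  expect_equal(unname(P), matrix(c(1, 1.5, 1, 0.5), 2, 2))

  hc <- population_history(c(0, 5, 9), matrix(200, 3, 3))
  expect_true(all(compute_proportions(hc)$P == 1))

  set.seed(2)
  hr <- toy_history(n = 9, J = 4)
  expect_equal(unname(compute_proportions(hr)$P[1, ]), rep(1, 4))
})

test_that("degenerate count layouts are rejected", {
  h <- population_history(c(0, 10), cbind(a = c(0, 10), b = c(10, 10)))
  expect_error(compute_proportions(h), "zero count at the first time point")
})

test_that("expansion rates are slopes per generation on uneven grids", {
  traj <- structure(list(P = cbind(a = c(1, 1, 1)), generations = c(0, 10, 20),
                         labels = "a"), class = "psm_trajectories")
  expect_equal(unname(compute_expansion_rates(traj)$r[, 1]), c(0, 0))

  traj2 <- structure(list(P = cbind(a = c(1, 1.5)), generations = c(0, 10),
                          labels = "a"), class = "psm_trajectories")
  expect_equal(unname(compute_expansion_rates(traj2)$r[1, 1]), 0.05)

  traj3 <- structure(list(P = cbind(a = c(1, 1.1, 1.4)),
                          generations = c(0, 5, 20), labels = "a"),
                     class = "psm_trajectories")
  expect_equal(unname(compute_expansion_rates(traj3)$r[, 1]), c(0.02, 0.02),
               tolerance = 1e-12)
})

test_that("neutral calibration pools slopes and flags zero variance", {
  cal <- calibrate_neutral(rates_from_slopes(c(-0.01, 0.01)))
  expect_equal(cal$mu_r, 0)
  expect_equal(cal$sigma_r, sqrt(2) * 0.01, tolerance = 1e-9)  # sample sd
  expect_equal(cal$n_neutral, 2)

  expect_error(calibrate_neutral(rates_from_slopes(c(0, 0, 0))),
               "zero variance")
  expect_error(calibrate_neutral(list()), "no neutral rate series")

  two <- calibrate_neutral(list(rates_from_slopes(c(-0.01, 0.01)),
                                rates_from_slopes(c(0.02, 0.0))))
  expect_equal(two$n_neutral, 4)
  expect_equal(two$mu_r, mean(c(-0.01, 0.01, 0.02, 0)))
})

test_that("classification matches hand-computed t-test calls", {
  cal <- table1_calibration()   # mu 0, sigma 0.018, n 64
  em <- classify_rates(rates_from_slopes(c(0, 0.01, 0.001, -0.01, -0.001)),
                       cal, alpha = 0.10, tails = 1)
  # T = r / (0.018/8): 0, 4.44, 0.44, -4.44, -0.44; t_{0.90,63} ~ 1.295
  expect_equal(unname(em$symbols[, 1]), c("Z", "P", "Z", "N", "Z"))
})

test_that("classifier agrees with a direct tail-probability oracle", {
  set.seed(7)
  cal <- table1_calibration()
  slopes <- stats::rnorm(1000, 0, 0.006)
  for (tails in c(1, 2)) {
    em <- classify_rates(rates_from_slopes(slopes), cal, alpha = 0.10,
                         tails = tails)
    T <- (slopes - cal$mu_r) / (cal$sigma_r / sqrt(cal$n_neutral))
    pval <- tails * stats::pt(abs(T), df = cal$n_neutral - 1,
                              lower.tail = FALSE)
    want <- ifelse(pval < 0.10, ifelse(T > 0, "P", "N"), "Z")
    expect_identical(unname(em$symbols[, 1]), want)
  }
})

test_that("gaussian mode uses normal critical values", {
  cal <- table1_calibration()
  # a T value between z_{0.90} = 1.2816 and t_{0.90,63} = 1.2951
  r <- 1.285 * cal$sigma_r / 8
  em_t <- classify_rates(rates_from_slopes(r), cal, alpha = 0.10, tails = 1)
  em_g <- classify_rates(rates_from_slopes(r), cal, alpha = 0.10, tails = 1,
                         dist = "gaussian")
  expect_identical(unname(em_t$symbols[1, 1]), "Z")
  expect_identical(unname(em_g$symbols[1, 1]), "P")
})

test_that("classification is antisymmetric around mu_r", {
  set.seed(8)
  cal <- neutral_calibration(0.003, 0.018, 64)
  slopes <- stats::rnorm(500, cal$mu_r, 0.005)
  em <- classify_rates(rates_from_slopes(slopes), cal)
  mirrored <- classify_rates(rates_from_slopes(2 * cal$mu_r - slopes), cal)
  flip <- c(P = "N", N = "P", Z = "Z")
  expect_identical(unname(mirrored$symbols[, 1]),
                   unname(flip[em$symbols[, 1]]))
})

test_that("raising alpha never turns a significant call into Z", {
  set.seed(9)
  cal <- table1_calibration()
  slopes <- stats::rnorm(400, 0, 0.004)
  alphas <- c(0.01, 0.05, 0.10, 0.20, 0.40)
  prev <- NULL
  for (a in alphas) {
    em <- classify_rates(rates_from_slopes(slopes), cal, alpha = a)
    sym <- em$symbols[, 1]
    expect_equal(sum(sym != "Z") + sum(sym == "Z"), length(slopes))
    if (!is.null(prev)) expect_true(all(sym[prev != "Z"] == prev[prev != "Z"]))
    prev <- sym
  }
})

test_that("parameter validation rejects bad alpha and tails", {
  cal <- table1_calibration()
  r <- rates_from_slopes(0.01)
  expect_error(classify_rates(r, cal, alpha = 0), "alpha")
  expect_error(classify_rates(r, cal, alpha = 1.2), "alpha")
  expect_error(classify_rates(r, cal, tails = 3), "tails")
})
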