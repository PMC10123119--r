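make_problem <- function(eta_unit = 25, noise_cv = 0, seed = 1, ...) {
  dat <- generate_synthetic_foldchanges(eta_unit = eta_unit,
                                        noise_cv = noise_cv, seed = seed)
  fit_problem(dat, ...)
}

test_that("predictions self-normalise and carry the experimental orderings", {
  prob <- make_problem()
  set.seed(17)
  for (i in 1:10) {
    theta <- c(eta_unit = 10^runif(1, 0, 1.5),
               lambda_TQ = runif(1, 5, 50),
               kappa_ratio = runif(1, 0.5, 2))
    yhat <- predict_conditions(theta, prob)
    expect_equal(unname(yhat[c("miTarget.Control", "monitor.Control")]),
                 c(1, 1))
    m <- yhat[paste("monitor", c("1TS3p", "1TS5p", "3TS3p", "3TS5p"),
                    sep = ".")]
    # monitor rises: Control < 1TS3' <= 1TS5' < 3TS3' <= 3TS5'
    expect_true(all(diff(c(1, m)) > 0))
    # target falls under every regulated condition
    tg <- yhat[paste("miTarget", c("1TS3p", "1TS5p", "3TS3p", "3TS5p"),
                     sep = ".")]
    expect_true(all(tg < 1))
  }
  expect_error(predict_conditions(c(eta_unit = 1e5), prob), "bounds")
})

test_that("the loss equals the printed regularised least-squares form", {
  # y generated at eta_unit = 10 so a matching theta zeroes the data term
  dat <- generate_synthetic_foldchanges(eta_unit = 10, noise_cv = 0)
  prob0 <- fit_problem(dat, free = "eta_unit", lambda = 0, theta_scale = 1)
  expect_equal(foldchange_loss(c(eta_unit = 10), prob0), 0, tolerance = 1e-24)
  # lambda ||theta||^2 arithmetic on the raw scale: 0.001 * 100 = 0.1
  prob1 <- fit_problem(dat, free = "eta_unit", lambda = 0.001,
                       theta_scale = 1)
  expect_equal(foldchange_loss(c(eta_unit = 10), prob1), 0.1,
               tolerance = 1e-12)
})

test_that("loss matches an element-wise recomputation from the closed forms", {
  prob <- make_problem(noise_cv = 0.1, seed = 4)
  conds <- design_conditions()
  set.seed(23)
  for (i in 1:50) {
    theta <- c(eta_unit = 10^runif(1, -2, 1.5),
               lambda_TQ = runif(1, 2, 90),
               kappa_ratio = 10^runif(1, -1, 1))
    # independent prediction via the printed steady-state equations
    p <- prob$params
    oy <- matrix(NA_real_, nrow(conds), 2)
    for (k in seq_len(nrow(conds))) {
      pk <- set_params(p, lambda_TQ = theta[["lambda_TQ"]],
                       kappa_T = theta[["kappa_ratio"]] * p$kappa_C,
                       sigma = ifelse(is.na(conds$sigma[k]), p$sigma,
                                      conds$sigma[k]),
                       eta_plus = conds$ts_count[k] * theta[["eta_unit"]])
      o <- oracle_steady_state(pk)
      oy[k, ] <- c(o$p_T, o$p_C)
    }
    yhat <- c(oy[, 1] / oy[1, 1], oy[, 2] / oy[1, 2])
    manual <- sum((prob$y - yhat)^2) +
      prob$lambda * sum((theta / prob$theta_scale)^2)
    expect_equal(foldchange_loss(theta, prob), manual, tolerance = 1e-12)
  }
})

test_that("loss is invariant to the row order of the data table", {
  dat <- generate_synthetic_foldchanges(noise_cv = 0.2, seed = 9)
  theta <- c(eta_unit = 0.3, lambda_TQ = 12, kappa_ratio = 1.4)
  l1 <- foldchange_loss(theta, fit_problem(dat))
  set.seed(1)
  l2 <- foldchange_loss(theta, fit_problem(dat[sample(nrow(dat)), ]))
  expect_identical(l1, l2)
})

test_that("the synthetic generator is seeded and hits the requested noise", {
  base <- generate_synthetic_foldchanges(noise_cv = 0)
  again <- generate_synthetic_foldchanges(noise_cv = 0)
  expect_identical(base, again)
  n1 <- generate_synthetic_foldchanges(noise_cv = 0.1, seed = 2)
  n1b <- generate_synthetic_foldchanges(noise_cv = 0.1, seed = 2)
  n2 <- generate_synthetic_foldchanges(noise_cv = 0.1, seed = 3)
  expect_identical(n1, n1b)
  expect_false(identical(n1, n2))
  expect_error(generate_synthetic_foldchanges(noise_cv = -0.1), "noise_cv")
  # Monte-Carlo calibration of the multiplicative noise level
  reps <- vapply(1:1000, function(s)
    generate_synthetic_foldchanges(noise_cv = 0.2, seed = s)$fold_change,
    numeric(10))
  cvs <- apply(reps, 1, function(x) stats::sd(x) / mean(x))
  expect_lt(max(abs(cvs - 0.2)) / 0.2, 0.15)
})

test_that("differential evolution recovers known parameters from clean data", {
  truth <- c(eta_unit = 25, lambda_TQ = 20, kappa_ratio = 1)
  dat <- generate_synthetic_foldchanges(eta_unit = truth[["eta_unit"]],
                                        noise_cv = 0)
  fit <- fit_foldchange(dat, seed = 5)
  expect_s3_class(fit, "foldchange_fit")
  expect_lt(max(rel_err(coef(fit), truth)), 0.1)
  # optimiser soundness: at least as good as the generating parameters
  expect_lte(fit$loss, foldchange_loss(truth, fit$problem))
  expect_equal(unname(fitted(fit)), unname(fit$problem$y), tolerance = 0.01)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(residuals(fit), fit$problem$y - fitted(fit))
})

test_that("local refinement cannot materially improve the DE optimum", {
  dat <- generate_synthetic_foldchanges(noise_cv = 0.05, seed = 19)
  fit <- fit_foldchange(dat, seed = 3)
  prob <- fit$problem
  refined <- stats::optim(coef(fit), function(v) {
    names(v) <- prob$free
    foldchange_loss(v, prob)
  }, method = "L-BFGS-B", lower = prob$lower, upper = prob$upper)
  expect_lte(refined$value, fit$loss)
  expect_gt(refined$value, fit$loss - 1e-6 * (1 + fit$loss))
})

test_that("stronger regularisation shrinks the fitted parameter vector", {
  dat <- generate_synthetic_foldchanges(noise_cv = 0)
  small <- fit_foldchange(dat, lambda = 0.001, seed = 11,
                          control = list(maxiter = 120))
  big <- fit_foldchange(dat, lambda = 1000, seed = 11,
                        control = list(maxiter = 120))
  norm_scaled <- function(f)
    sqrt(sum((coef(f) / f$problem$theta_scale)^2))
  expect_lt(norm_scaled(big), norm_scaled(small))
})

test_that("recovery error grows with the noise level", {
  truth <- c(eta_unit = 25, lambda_TQ = 20, kappa_ratio = 1)
  err_at <- function(cv) {
    errs <- vapply(1:3, function(s) {
      dat <- generate_synthetic_foldchanges(noise_cv = cv, seed = 100 + s)
      f <- fit_foldchange(dat, seed = s, control = list(maxiter = 120))
      sqrt(sum((coef(f) - truth)^2)) / sqrt(sum(truth^2))
    }, numeric(1))
    mean(errs)
  }
  e <- c(err_at(0), err_at(0.05), err_at(0.2))
  expect_true(all(diff(e) > 0))
})

test_that("the fitted model reproduces the orderings it was trained on", {
  dat <- generate_synthetic_foldchanges(eta_unit = 25, noise_cv = 0.05,
                                        seed = 31)
  fit <- fit_foldchange(dat, seed = 2)
  yhat <- fitted(fit)
  m <- yhat[paste("monitor", c("Control", "1TS3p", "1TS5p", "3TS3p", "3TS5p"),
                  sep = ".")]
  tg <- yhat[paste("miTarget", c("Control", "1TS3p", "1TS5p", "3TS3p",
                                 "3TS5p"), sep = ".")]
  expect_true(all(diff(m) > 0))             # monitor: up with TS count, 5' > 3'
  expect_true(all(tg[-1] < tg[1]))          # target: down in every condition
  expect_lt(tg[["miTarget.1TS5p"]], tg[["miTarget.1TS3p"]])
  expect_lt(tg[["miTarget.3TS5p"]], tg[["miTarget.3TS3p"]])
  expect_lt(tg[["miTarget.3TS3p"]], tg[["miTarget.1TS3p"]])
})
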