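# The recursive path model: ML estimates, implied covariance, chi-square,
# CFI / SRMR, and the satisfactory-fit rule.

sim_meta_model <- function(n, b_da = -0.5, b_la = 0.3, b_f = 0.4,
                           b_a = -0.2, b_x = -0.4, sd_e = 1) {
  da <- rnorm(n); la <- rnorm(n); ax <- rnorm(n)
  fdg <- b_da * da + b_la * la + rnorm(n, 0, sd_e)
  slope <- b_f * fdg + b_a * la + b_x * ax + rnorm(n, 0, sd_e)
  data.frame(distant_abeta = da, local_abeta = la, abeta_x_fdg = ax,
             local_fdg = fdg, cognitive_slope = slope)
}

test_that("a saturated model fits perfectly", {
  set.seed(14)
  tab <- sim_meta_model(200)
  sat <- sem_model(list(c("distant_abeta", "local_fdg"),
                        c("local_abeta", "local_fdg"),
                        c("abeta_x_fdg", "local_fdg"),
                        c("distant_abeta", "cognitive_slope"),
                        c("local_abeta", "cognitive_slope"),
                        c("abeta_x_fdg", "cognitive_slope"),
                        c("local_fdg", "cognitive_slope")))
  fit <- fit_sem(sat, tab)
  expect_equal(fit$df, 0)
  expect_lt(fit$chi_square, 1e-8)
  expect_equal(fit$cfi, 1)
  expect_lt(fit$srmr, 1e-8)
})

test_that("noiseless path data is identified exactly", {
  set.seed(15)
  x <- rnorm(100); z <- rnorm(100)
  y <- 2 * x - z           # zero residual
  tab <- data.frame(x = x, z = z, y = y)
  expect_warning(
    fit <- fit_sem(sem_model(list(c("x", "y"), c("z", "y"))), tab),
    "positive definite")
  expect_equal(unname(fit$estimates["x -> y"]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$estimates["z -> y"]), -1, tolerance = 1e-8)
})

test_that("path estimates equal per-equation OLS", {
  set.seed(16)
  tab <- sim_meta_model(150)
  fit <- fit_sem(sem_default_model(), tab)
  ref <- lm(local_fdg ~ distant_abeta + local_abeta, data = tab)
  expect_equal(unname(fit$estimates["distant_abeta -> local_fdg"]),
               unname(coef(ref)["distant_abeta"]), tolerance = 1e-8)
  ref2 <- lm(cognitive_slope ~ local_fdg + local_abeta + abeta_x_fdg,
             data = tab)
  expect_equal(unname(fit$estimates["abeta_x_fdg -> cognitive_slope"]),
               unname(coef(ref2)["abeta_x_fdg"]), tolerance = 1e-8)
})

test_that("chi-square, CFI and SRMR match a brute-force oracle", {
  set.seed(17)
  n <- 120
  x <- rnorm(n); y <- 0.8 * x + rnorm(n); z <- 0.5 * y + rnorm(n)
  tab <- data.frame(x = x, y = y, z = z)
  fit <- fit_sem(sem_model(list(c("x", "y"), c("y", "z"))), tab)

  # independent reconstruction from first principles
  S <- cov(tab)
  bxy <- cov(x, y) / var(x)
  byz <- cov(y, z) / var(y)
  psi_y <- sum((y - mean(y) - bxy * (x - mean(x)))^2) / (n - 1)
  psi_z <- sum((z - mean(z) - byz * (y - mean(y)))^2) / (n - 1)
  vx <- var(x)
  vy <- bxy^2 * vx + psi_y
  Sig <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  Sig["x", "x"] <- vx
  Sig["y", "y"] <- vy
  Sig["z", "z"] <- byz^2 * vy + psi_z
  Sig["x", "y"] <- Sig["y", "x"] <- bxy * vx
  Sig["y", "z"] <- Sig["z", "y"] <- byz * vy
  Sig["x", "z"] <- Sig["z", "x"] <- byz * bxy * vx
  Svars <- S[c("x", "y", "z"), c("x", "y", "z")]
  fml <- log(det(Sig)) + sum(diag(Svars %*% solve(Sig))) -
    log(det(Svars)) - 3
  chi <- (n - 1) * fml
  expect_equal(fit$chi_square, chi, tolerance = 1e-8)
  expect_equal(fit$df, 1)  # 6 moments - (2 paths + 1 exo var + 2 psi)

  chi0 <- (n - 1) * (-log(det(stats::cov2cor(Svars))))
  cfi <- 1 - max(chi - 1, 0) / max(chi0 - 3, chi - 1, 0)
  dd <- sqrt(diag(Svars))
  resid <- (Svars - Sig) / outer(dd, dd)
  srmr <- sqrt(mean(resid[upper.tri(resid, diag = TRUE)]^2))
  expect_equal(fit$cfi, cfi, tolerance = 1e-8)
  expect_equal(fit$srmr, srmr, tolerance = 1e-8)
  fi <- fit_indices(fit, tab)
  expect_equal(fi$cfi, fit$cfi, tolerance = 1e-10)
  expect_equal(fi$srmr, fit$srmr, tolerance = 1e-10)
})

test_that("the independence baseline itself scores CFI = 0", {
  set.seed(18)
  tab <- sim_meta_model(300)[, c("distant_abeta", "local_fdg",
                                 "cognitive_slope")]
  # a no-path, diagonal-covariance model over correlated data IS the
  # baseline; trick: one zero-weight path keeps the variables in the model
  m <- sem_model(list(c("distant_abeta", "local_fdg"),
                      c("distant_abeta", "cognitive_slope")),
                 exogenous_cov = "diagonal")
  # compare a heavily misspecified model against the baseline bound
  fit <- fit_sem(m, tab)
  expect_lt(fit$cfi, 1)
  expect_gte(fit$cfi, 0)
})

test_that("indices are invariant to variable rescaling", {
  set.seed(19)
  tab <- sim_meta_model(200)
  f1 <- fit_sem(sem_default_model(), tab)
  tab2 <- tab
  tab2$local_fdg <- tab2$local_fdg * 100
  tab2$cognitive_slope <- tab2$cognitive_slope / 7
  f2 <- fit_sem(sem_default_model(), tab2)
  expect_equal(f1$cfi, f2$cfi, tolerance = 1e-8)
  expect_equal(f1$srmr, f2$srmr, tolerance = 1e-8)
})

test_that("parameters of the meta-model are recovered", {
  set.seed(20)
  truth <- c("distant_abeta -> local_fdg" = -0.5,
             "local_abeta -> local_fdg" = 0.3,
             "local_fdg -> cognitive_slope" = 0.4,
             "local_abeta -> cognitive_slope" = -0.2,
             "abeta_x_fdg -> cognitive_slope" = -0.4)
  est <- rowMeans(replicate(10, {
    fit <- fit_sem(sem_default_model(), sim_meta_model(5000))
    fit$estimates[names(truth)]
  }))
  rel <- abs((est - truth) / truth)
  expect_true(all(rel < 0.05))
  # sign recovery across repeated moderate samples
  set.seed(21)
  hits <- replicate(200, {
    f <- fit_sem(sem_default_model(), sim_meta_model(250))
    (f$estimates["distant_abeta -> local_fdg"] < 0) &&
      (f$estimates["abeta_x_fdg -> cognitive_slope"] < 0)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("model specification rejects cycles", {
  expect_error(sem_model(list(c("a", "b"), c("b", "a"))), "acyclic")
})

test_that("the satisfactory-fit rule is strict on both indices", {
  expect_true(classify_fit(list(cfi = 0.966, srmr = 0.092)))
  expect_false(classify_fit(list(cfi = 0.95, srmr = 0.05)))
  expect_false(classify_fit(list(cfi = 0.99, srmr = 0.2)))
  expect_false(classify_fit(list(cfi = 0.96, srmr = 0.1)))
})

test_that("the design table builds products and residualises covariates", {
  co <- small_mci_cohort()
  tab <- build_design_table(co, covariate_adjustment = NULL)
  expect_equal(nrow(tab), nrow(co$subjects))
  expect_equal(tab$abeta_x_fdg,
               as.numeric(scale(tab$local_abeta)) *
                 as.numeric(scale(tab$local_fdg)))
  tabr <- build_design_table(co)
  Z <- cbind(co$subjects$age, co$subjects$sex, co$subjects$education)
  for (v in names(tabr)) {
    expect_lt(max(abs(crossprod(Z, tabr[[v]]))) /
                max(1, max(abs(Z))), 1e-6)
  }
  fit <- fit_sem(sem_default_model(), tabr)
  expect_true(fit$converged)
  expect_true(fit$estimates["distant_abeta -> local_fdg"] < 0)
})
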