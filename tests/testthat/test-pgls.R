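test_that("exact linear data give a perfect fit under any covariance", {
  tr <- random_tree(10, seed = 4)
  df <- tibble::tibble(species = tr$tip.label,
                       x = seq(0, 1, length.out = 10))
  df$y <- df$x
  fit <- quiet_pgls(df, y ~ x, tr, lambda = 1)
  expect_equal(unname(fit$coefficients), c(0, 1), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("GLS on a star tree reduces to OLS", {
  star <- read_newick(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  df <- tibble::tibble(species = star$tip.label,
                       x = c(0, 1, 2, 3, 4, 5),
                       y = c(0.1, 1.2, 1.9, 3.3, 3.8, 5.2))
  fit <- quiet_pgls(df, y ~ x, star, lambda = 1)
  ols <- stats::lm(y ~ x, df)
  expect_equal(unname(fit$coefficients), unname(stats::coef(ols)),
               tolerance = 1e-10)
})

test_that("coefficients match the dense-matrix GLS oracle", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)$C
  df <- tibble::tibble(species = c("A", "B", "C"), x = c(0, 1, 2),
                       y = c(0, 1, 1))
  fit <- quiet_pgls(df, y ~ x, tr, lambda = 1)
  X <- cbind(1, df$x)
  expect_equal(unname(fit$coefficients), dense_gls(X, df$y, C),
               tolerance = 1e-12)

  # larger random case, also at intermediate lambda
  tr2 <- random_tree(25, seed = 6)
  set.seed(1)
  df2 <- tibble::tibble(species = tr2$tip.label, x = rnorm(25),
                        y = rnorm(25))
  for (lam in c(0.3, 1)) {
    f <- quiet_pgls(df2, y ~ x, tr2, lambda = lam)
    C2 <- apply_lambda(phylo_covariance(tr2), lam)$C
    expect_equal(unname(f$coefficients),
                 dense_gls(cbind(1, df2$x), df2$y, C2), tolerance = 1e-10)
  }
})

test_that("GLS equals OLS on Cholesky-whitened data", {
  for (s in 1:3) {
    n <- c(20, 60, 120)[s]
    tr <- random_tree(n, seed = s)
    set.seed(s + 100)
    df <- tibble::tibble(species = tr$tip.label, x = rnorm(n), y = rnorm(n))
    lam <- c(0.2, 0.7, 1)[s]
    fit <- quiet_pgls(df, y ~ x, tr, lambda = lam)
    C <- apply_lambda(phylo_covariance(tr), lam)$C
    L <- t(chol(C))
    Xw <- solve(L, cbind(1, df$x))
    yw <- solve(L, df$y)
    wls <- stats::lm.fit(Xw, yw)
    expect_equal(unname(fit$coefficients), unname(wls$coefficients),
                 tolerance = 1e-8)
  }
})

test_that("lambda = 0 is OLS; lambda = 1 slope equals PIC through origin", {
  for (s in 1:3) {
    n <- c(15, 40, 80)[s]
    tr <- random_tree(n, seed = s + 20)
    set.seed(s + 200)
    x <- stats::setNames(simulate_predictor(tr, 1), tr$tip.label)
    y <- simulate_allometry(tr, x, 0.3, 0.7, 0.5, 1)
    df <- tibble::tibble(species = tr$tip.label, x = unname(x),
                         y = unname(y[tr$tip.label]))
    f0 <- quiet_pgls(df, y ~ x, tr, lambda = 0)
    ols <- stats::lm(y ~ x, df)
    expect_equal(unname(f0$coefficients), unname(stats::coef(ols)),
                 tolerance = 1e-8)
    f1 <- quiet_pgls(df, y ~ x, tr, lambda = 1)
    px <- ape::pic(x, tr)
    py <- ape::pic(y[tr$tip.label], tr)
    pic_slope <- unname(stats::coef(stats::lm(py ~ px - 1)))
    expect_equal(unname(f1$coefficients[2]), pic_slope, tolerance = 1e-8)
  }
})

test_that("ML lambda agrees with an exhaustive fine grid search", {
  sim <- small_sim()
  fit <- quiet_pgls(sim$species, log_ed ~ log_rm, sim$tree)
  md <- eyescale:::build_pgls_design(sim$species, log_ed ~ log_rm,
                                     sim$tree, "species")
  grid <- seq(0, 1, by = 0.001)
  ll <- vapply(grid, function(l) {
    eyescale:::profile_loglik(l, md$X, md$y, md$C)
  }, numeric(1))
  expect_lt(abs(fit$lambda - grid[which.max(ll)]), 0.01)
  # the optimum dominates the boundary values
  expect_gte(eyescale:::profile_loglik(fit$lambda, md$X, md$y, md$C),
             max(ll[c(1, length(ll))]) - 1e-8)
})

test_that("ML lambda and coefficients agree with nlme::gls + corPagel", {
  skip_if_not_installed("nlme")
  sim <- small_sim()
  df <- as.data.frame(sim$species)
  rownames(df) <- df$species
  ref <- nlme::gls(
    log_ed ~ log_rm, data = df,
    correlation = ape::corPagel(0.8, phy = sim$tree, form = ~species),
    method = "ML")
  fit <- quiet_pgls(sim$species, log_ed ~ log_rm, sim$tree)
  lam_ref <- as.numeric(ref$modelStruct$corStruct)
  expect_equal(fit$lambda, lam_ref, tolerance = 0.01)
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-4)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-3)
})

test_that("a star tree has a flat lambda likelihood, reported as 0", {
  star <- read_newick(text = "(A:1,B:1,C:1,D:1,E:1,F:1,G:1,H:1);")
  set.seed(3)
  df <- tibble::tibble(species = star$tip.label, x = rnorm(8), y = rnorm(8))
  fit <- quiet_pgls(df, y ~ x, star)
  expect_true(fit$flat_lambda)
  expect_equal(fit$lambda, 0)
})

test_that("Studentized residuals match OLS diagnostics for diagonal C", {
  star <- read_newick(
    text = paste0("(", paste0("t", 1:12, ":1", collapse = ","), ");"))
  set.seed(8)
  df <- tibble::tibble(species = star$tip.label, x = rnorm(12),
                       y = rnorm(12))
  fit <- quiet_pgls(df, y ~ x, star, lambda = 1)
  lm_fit <- stats::lm(y ~ x, df)
  expect_equal(unname(studentized_residuals(fit)[df$species]),
               unname(stats::rstudent(lm_fit)), tolerance = 1e-8)
})

test_that("a planted gross outlier is flagged and removed, drift small", {
  sim <- small_sim()
  df <- sim$species
  victim <- df$species[17]
  sd_res <- sqrt(sim$truth$sigma2)
  df$log_ed[df$species == victim] <-
    df$log_ed[df$species == victim] + 10 * sd_res
  fit <- quiet_pgls(df, log_ed ~ log_rm, sim$tree)
  st <- studentized_residuals(fit)
  expect_equal(names(which.max(abs(st))), victim)
  expect_gt(max(abs(st)), 3)

  rep_out <- suppressMessages(suppressWarnings(
    iterative_outlier_refit(df, log_ed ~ log_rm, sim$tree)))
  expect_true(victim %in% rep_out$removals$taxon)
  # slope moves toward the generative truth after removal
  b_true <- sim$truth$slope
  expect_lt(abs(rep_out$final_fit$coefficients[2] - b_true),
            abs(rep_out$initial_fit$coefficients[2] - b_true) + 1e-12)
  # drift stays within one (initial) standard error per removal ethos
  expect_lt(abs(rep_out$drift[2]), 3 * rep_out$initial_fit$se[2])
})

test_that("clean data yield no removals and an unchanged final fit", {
  tr <- random_tree(40, seed = 31)
  set.seed(31)
  x <- simulate_predictor(tr, 1)
  y <- simulate_allometry(tr, x, 0, 1, 0.05, 0.9)
  df <- tibble::tibble(species = tr$tip.label, x = unname(x),
                       y = unname(y[tr$tip.label]))
  st <- studentized_residuals(quiet_pgls(df, y ~ x, tr))
  expect_lt(max(abs(st)), 3)  # this fixture is clean by construction
  rep_out <- suppressMessages(
    iterative_outlier_refit(df, y ~ x, tr))
  expect_equal(nrow(rep_out$removals), 0)
  expect_equal(rep_out$final_fit$coefficients,
               rep_out$initial_fit$coefficients)
})

test_that("degenerate designs and covariances are rejected with clear errors", {
  tr <- random_tree(10, seed = 44)
  df <- tibble::tibble(species = tr$tip.label, x = rep(1, 10),
                       y = rnorm(10))
  expect_error(quiet_pgls(df, y ~ x, tr), "rank deficient")
  df2 <- tibble::tibble(species = c("nope1", "nope2"), x = 1:2, y = 1:2)
  expect_error(quiet_pgls(df2, y ~ x, tr), "no species shared")
})
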