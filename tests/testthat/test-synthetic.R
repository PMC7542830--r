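test_that("Yule simulator: tip counts, determinism, analytic mean depth", {
  expect_error(simulate_yule_tree(1), "at least 2")
  cherry <- simulate_yule_tree(2, seed = 1)
  expect_equal(ape::Ntip(cherry), 2)

  for (n in c(5, 17, 60)) {
    tr <- simulate_yule_tree(n, seed = n)
    expect_equal(ape::Ntip(tr), n)
    expect_true(ape::is.binary(tr))
    expect_true(ape::is.rooted(tr))
  }
  t1 <- simulate_yule_tree(12, seed = 99)
  t2 <- simulate_yule_tree(12, seed = 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  # E[depth] = sum_{k=2}^{n} 1/(k b); Monte-Carlo agreement
  n <- 8; b <- 1.5
  expected <- sum(1 / ((2:n) * b))
  set.seed(2024)
  depths <- replicate(400, {
    max(ape::node.depth.edgelength(simulate_yule_tree(n, b)))
  })
  se <- stats::sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 4 * se)
})

test_that("Brownian predictor has covariance sigma2 * C", {
  cherry <- read_newick(text = "(A:0.7,B:0.7);")
  sigma2 <- 0.4
  set.seed(5)
  d <- replicate(3000, {
    x <- simulate_predictor(cherry, sigma2)
    x["A"] - x["B"]
  })
  expect_equal(stats::var(d), 2 * sigma2 * 0.7, tolerance = 0.1)

  expect_equal(unname(simulate_predictor(cherry, 0)), c(0, 0))

  tr <- read_newick(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  C <- ape::vcv.phylo(tr)
  set.seed(6)
  draws <- t(replicate(3000, simulate_predictor(tr, 0.3)))
  emp <- stats::cov(draws)
  expect_equal(emp, 0.3 * C, tolerance = 0.12, ignore_attr = TRUE)
})

test_that("allometric response respects the generative model", {
  tr <- random_tree(20, seed = 3)
  x <- simulate_predictor(tr, 0.5, seed = 4)
  y0 <- simulate_allometry(tr, x, 0.4, 0.75, 0, 1, seed = 5)
  expect_equal(unname(y0[names(x)]), 0.4 + 0.75 * unname(x),
               tolerance = 1e-12)

  # lambda 0: whitened residuals are iid normal (Shapiro + no structure)
  star_n <- 120
  tr2 <- random_tree(star_n, seed = 6)
  x2 <- simulate_predictor(tr2, 0.3, seed = 7)
  y2 <- simulate_allometry(tr2, x2, 0, 1, 0.2, 0, seed = 8)
  resid <- y2 - x2[names(y2)]
  C0 <- eyescale:::lambda_transform(ape::vcv.phylo(tr2), 0)
  w <- backsolve(chol(C0), resid[rownames(C0)], transpose = TRUE)
  expect_gt(stats::shapiro.test(w)$p.value, 0.01)
})

test_that("state simulation: frequencies, offsets and clumping", {
  tr <- random_tree(220, seed = 12)
  s_iid <- simulate_states(tr, c(a = 0.5, b = 0.5), seed = 13)
  n_a <- sum(s_iid == "a")
  ci <- stats::qbinom(c(0.0005, 0.9995), 220, 0.5)
  expect_gte(n_a, ci[1]); expect_lte(n_a, ci[2])

  one <- simulate_states(tr, c(only = 1), seed = 14)
  y <- stats::setNames(rnorm(220), tr$tip.label)
  expect_equal(eyescale:::apply_state_offsets(y, one, c(only = 0)), y)
  expect_error(eyescale:::apply_state_offsets(y, one, c(other = 1)),
               "only")

  # Markov walk: deterministic per seed; sister tips share states more
  # often than frequency-matched iid draws would
  m1 <- simulate_states(tr, c(a = 0.5, b = 0.5), rate = 0.5, seed = 15)
  m2 <- simulate_states(tr, c(a = 0.5, b = 0.5), rate = 0.5, seed = 15)
  expect_identical(m1, m2)
  d <- tip_distances(tr)
  diag(d) <- Inf
  nearest <- apply(d, 1, which.min)
  agree <- mean(m1 == m1[nearest])
  expect_gt(agree, 0.6)
})

test_that("planted fossorial offset is recovered end to end", {
  cfg <- sim_config(n_species = 150, seed = 31)
  sim <- simulate_dataset(cfg)
  fit <- quiet_pgls(sim$species, log_ed ~ log_rm, sim$tree)
  gs <- group_summary(investment_scores(fit, sim$ecology), "adult_habitat")
  foss <- gs$mean_investment[gs$state == "fossorial"]
  expect_equal(foss, 0.65, tolerance = 0.25)
  # the two largest planted offsets surface at the top of the ranking
  expect_true("scansorial" %in% gs$state[1:2])
})

test_that("specimen noise model behaves at its limits", {
  cfg0 <- sim_config(n_species = 12, seed = 3, measurement_cv = 0,
                     preservation_shrinkage = 1, n_fresh = 4)
  sim0 <- simulate_dataset(cfg0)
  sp <- prepare_species_table(sim0$specimens)
  ord <- match(sp$species, sim0$species$species)
  expect_equal(sp$ed_mm, sim0$species$ed_mm[ord], tolerance = 1e-10)
  expect_equal(sp$mass_g, sim0$species$mass_g[ord], tolerance = 1e-10)
  expect_equal(sp$rm^3, sp$mass_g, tolerance = 1e-10)

  # species means converge to truth as specimen count grows
  cfg_many <- sim_config(n_species = 25, seed = 8, specimens_min = 40,
                         specimens_max = 40, preservation_shrinkage = 1)
  sim_many <- simulate_dataset(cfg_many)
  spm <- prepare_species_table(sim_many$specimens)
  err_many <- stats::median(abs(
    log10(spm$ed_mm) -
      sim_many$species$log_ed[match(spm$species, sim_many$species$species)]))
  cfg_few <- sim_config(n_species = 25, seed = 8, specimens_min = 1,
                        specimens_max = 2, preservation_shrinkage = 1)
  sim_few <- simulate_dataset(cfg_few)
  spf <- prepare_species_table(sim_few$specimens)
  err_few <- stats::median(abs(
    log10(spf$ed_mm) -
      sim_few$species$log_ed[match(spf$species, sim_few$species$species)]))
  expect_lt(err_many, err_few)
})

test_that("preservation shrinkage shows up as a log-scale intercept shift", {
  cfg <- sim_config(n_species = 40, seed = 5, measurement_cv = 0.01,
                    preservation_shrinkage = 0.95, n_fresh = 40)
  sim <- simulate_dataset(cfg)
  fresh <- prepare_species_table(sim$specimens, conditions = "fresh")
  pres <- prepare_species_table(sim$specimens, conditions = "preserved")
  common <- intersect(fresh$species, pres$species)
  df <- tibble::tibble(
    f = log10(fresh$ed_mm[match(common, fresh$species)]),
    p = log10(pres$ed_mm[match(common, pres$species)]))
  fit <- ols_fit(df, p ~ f)
  expect_equal(unname(fit$coefficients[2]), 1, tolerance = 0.05)
  expect_lt(abs(unname(fit$coefficients[1]) - log10(0.95)), 0.006)
})

test_that("datasets are reproducible and round-trip through files", {
  cfg <- sim_config(n_species = 20, seed = 17)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$species, d2$species)
  expect_identical(d1$specimens, d2$specimens)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_equal(d1$truth$slope, 0.82)
  expect_equal(d1$truth$lambda, 0.96)

  dir <- withr::local_tempdir()
  write_dataset(d1, dir)
  tr <- read_newick(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, d1$species$species)
  traits <- readr::read_csv(file.path(dir, "traits.csv"),
                            show_col_types = FALSE)
  expect_equal(nrow(traits), nrow(d1$specimens))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$slope, 0.82)
})
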