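test_that("noise variance follows the heritability identity", {
  expect_equal(noise_variance(0.5, 2.0), 2.0)
  expect_equal(noise_variance(0.95, 1.0), 1 / 19)
  expect_equal(noise_variance(0.7, 7.0), 3.0)
  expect_error(noise_variance(0, 1), "in \\(0, 1\\)")
  expect_error(noise_variance(1, 1), "in \\(0, 1\\)")
})

test_that("noise draws are mean-centred with the requested variance and skew", {
  set.seed(10)
  n <- 1e5
  g <- draw_noise("gaussian", sigma2 = 4, n = n)
  se_var <- 4 * sqrt(2 / (n - 1))             # SE of a variance estimate
  expect_lt(abs(stats::var(g) - 4), 3 * se_var)
  expect_lt(abs(mean(g)), 3 * 2 / sqrt(n))
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  gam1 <- draw_noise("gamma", sigma2 = 4, gamma_shape = 1, n = n)
  gam4 <- draw_noise("gamma", sigma2 = 4, gamma_shape = 4, n = n)
  expect_lt(abs(mean(gam1)), 0.1)
  expect_lt(abs(stats::var(gam1) - 4), 4 * 3 * sqrt(2 / (n - 1)) * 3)
  expect_gt(skew(gam4), 0)
  expect_gt(skew(gam1), skew(gam4))            # smaller shape, stronger skew
  expect_error(draw_noise("gaussian", sigma2 = -1, n = 5), "positive")
})

test_that("effect sizes hit their target variance fractions", {
  expect_equal(effect_size(0.5, 1, 1), 1.0)
  expect_equal(effect_size(0.3, 1, 1), sqrt(3 / 7))
  expect_equal(effect_size(0.3, 4, 1), 2 * sqrt(3 / 7), tolerance = 1e-12)
  expect_error(effect_size(0.3, 1, 0), "zero variance")
  # simulation oracle: the realized fraction of beta*x in total variance ~ c
  set.seed(11)
  n <- 5e4
  bg <- rnorm(n, 0, 2)                      # stands in for u + eps
  x <- sample(c(0, 2), n, replace = TRUE)
  for (cc in c(0.3, 0.5)) {
    b <- effect_size(cc, stats::var(bg), stats::var(x))
    y <- b * x + bg
    expect_equal(stats::var(b * x) / stats::var(y), cc, tolerance = 0.02)
  }
})

test_that("background sampling gives distinct indices and the stated effect scale", {
  G <- generate_genotypes(100, 2000, seed = 3)
  set.seed(5)
  bg <- sample_background(G, n_background = 1000, sd = 0.1)
  expect_length(unique(bg$background_indices), 1000)
  expect_equal(bg$u, as.numeric(G$values[, bg$background_indices] %*% bg$gamma))
  expect_error(sample_background(G, n_background = 3000), "exceeds")
  # sd = 0 -> u identically zero
  bg0 <- sample_background(G, n_background = 50, sd = 0)
  expect_equal(bg0$u, rep(0, 100))
  # Monte-Carlo: pooled gamma draws have sd ~ 0.1
  set.seed(6)
  pooled <- unlist(replicate(10, sample_background(G, 1000, 0.1)$gamma,
                             simplify = FALSE))
  se_sd <- 0.1 / sqrt(2 * (length(pooled) - 1))
  expect_lt(abs(stats::sd(pooled) - 0.1), 3 * se_sd)
})

test_that("simulated phenotypes are calibrated and reproducible", {
  G <- generate_genotypes(600, 2000, seed = 8)
  cfg <- sim_config("C_scaled", 500, 1, 0.3, heritability = 0.95)
  sp1 <- simulate_phenotype(cfg, G, seed = 4)
  sp2 <- simulate_phenotype(cfg, G, seed = 4)
  expect_identical(sp1$y, sp2$y)
  expect_identical(sp1$truth$beta, sp2$truth$beta)
  sp3 <- simulate_phenotype(cfg, G, seed = 5)
  expect_false(identical(sp1$y, sp3$y))

  tr <- sp1$truth
  h_real <- stats::var(tr$u) / (stats::var(tr$u) + stats::var(tr$epsilon))
  expect_lt(abs(h_real - 0.95), 0.02)
  rv <- realized_variance_components(sp1)
  expect_lt(abs(rv$fraction[rv$component == "causal_1"] - 0.3), 0.05)
  expect_lt(abs(sum(rv$fraction) - 1), 0.05)
  expect_length(intersect(tr$background_indices, tr$causal_indices), 0)
  expect_length(tr$background_indices, 1000)
})

test_that("a configuration without fixed effects gives y = u + eps exactly", {
  G <- generate_genotypes(100, 500, seed = 9)
  cfg <- sim_config("null", 100, 0, numeric(0), n_background = 200)
  sp <- simulate_phenotype(cfg, G, seed = 1)
  expect_equal(unname(sp$y), sp$truth$u + sp$truth$epsilon)
  expect_length(sp$truth$beta, 0)
})

test_that("the interaction term realizes its target fraction", {
  G <- generate_genotypes(600, 2000, seed = 12)
  cfg <- sim_config("E_scaled", 500, 2, c(0.05, 0.05),
                    interaction = list(fraction = 0.2), heritability = 0.95)
  fr <- vapply(1:5, function(s) {
    sp <- simulate_phenotype(cfg, G, seed = s)
    rv <- realized_variance_components(sp)
    rv$fraction[rv$component == "interaction"]
  }, 0)
  # the product term covaries with its marginal terms, which inflates
  # Var(y) and pulls the realized share below the nominal target; the mean
  # stays within the calibration band
  expect_lt(abs(mean(fr) - 0.2), 0.05)
})

test_that("multiple additive effects jointly realize their summed share", {
  G <- generate_genotypes(600, 2000, seed = 16)
  cfg <- builtin_configs()[["I_h0.95"]]
  cfg$n_samples <- 500
  tot <- vapply(1:5, function(s) {
    sp <- simulate_phenotype(cfg, G, seed = s)
    rv <- realized_variance_components(sp)
    sum(rv$fraction[startsWith(rv$component, "causal_")])
  }, 0)
  expect_lt(abs(mean(tot) - 0.30), 0.05)
})

test_that("gamma-noise phenotypes are right-skewed, stronger for smaller shape", {
  G <- generate_genotypes(600, 1500, seed = 13)
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  mean_skew <- function(shape) {
    mean(vapply(1:3, function(s) {
      cfg <- sim_config("skew", 500, 1, 0.3, noise_family = "gamma",
                        gamma_shape = shape, heritability = 0.7)
      sp <- simulate_phenotype(cfg, G, seed = s)
      skew(sp$truth$epsilon)
    }, 0))
  }
  weak <- mean_skew(4); strong <- mean_skew(1)
  expect_gt(weak, 0)
  expect_gt(strong, weak)
})

test_that("the built-in grid reproduces the twelve configurations times three heritabilities", {
  grid <- builtin_configs()
  expect_length(grid, 36)
  expect_equal(grid[["A_h0.7"]]$n_samples, 100)
  expect_equal(grid[["A_h0.7"]]$n_causal, 1)
  expect_equal(grid[["D_h0.95"]]$n_samples, 2000)
  expect_equal(grid[["E_h0.85"]]$interaction$fraction, 0.2)
  expect_equal(grid[["F_h0.95"]]$interaction$fraction, 0.28)
  expect_equal(grid[["G_h0.95"]]$gamma_shape, 4)
  expect_equal(grid[["H_h0.95"]]$gamma_shape, 1)
  expect_equal(grid[["L_h0.95"]]$n_causal, 100)
  expect_setequal(unique(vapply(grid, function(g) g$heritability, 0)),
                  c(0.7, 0.85, 0.95))
})

test_that("sampled-percentage fractions are positive with the stated expectation", {
  # configuration L: 100 fractions from N(0.3, 0.1^2)/100, truncated positive
  G <- generate_genotypes(300, 1500, seed = 14)
  cfg <- builtin_configs()[["L_h0.95"]]
  cfg$n_samples <- 300
  sums <- vapply(1:5, function(s) {
    sp <- simulate_phenotype(cfg, G, seed = s)
    fr <- sp$truth$target_fractions
    expect_length(fr, 100)
    expect_true(all(fr > 0))
    sum(fr)
  }, 0)
  expect_equal(mean(sums), 0.3, tolerance = 0.05)
})

test_that("ground truth round-trips through the JSON sidecar", {
  G <- generate_genotypes(100, 400, seed = 15)
  cfg <- sim_config("rt", 80, 2, c(0.1, 0.2), n_background = 150)
  sp <- simulate_phenotype(cfg, G, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sp, path)
  back <- read_truth_json(path)
  expect_equal(back$causal_markers, sp$truth$causal_markers)
  expect_equal(back$beta, sp$truth$beta)
  expect_equal(back$gamma, sp$truth$gamma)
  expect_equal(back$seed, sp$seed)
  expect_equal(back$config$heritability, 0.95)
})
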