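test_that("Yule trees are ultrametric with unit depth and seed-stable", {
  tr <- simulate_yule_tree(50, seed = 3)
  expect_equal(ape::Ntip(tr), 50L)
  expect_lt(max(abs(tip_depths(tr) - 1)), 1e-9)

  expect_identical(ape::write.tree(simulate_yule_tree(12, seed = 9)),
                   ape::write.tree(simulate_yule_tree(12, seed = 9)))

  tr2 <- simulate_yule_tree(2, seed = 1)
  expect_equal(ape::Ntip(tr2), 2L)
  expect_lt(max(abs(tip_depths(tr2) - 1)), 1e-9)

  expect_error(simulate_yule_tree(1), ">= 2")
})

test_that("joint covariance has the planted block structure and PSD boundary", {
  cfg0 <- sim_config(p = 3, q = 2, coupling_rank = 0)
  expect_equal(build_joint_covariance(cfg0), diag(1, 5))

  cfg1 <- sim_config(p = 1, q = 1, coupling_strength = 0.5,
                     u_star = 1, v_star = 1)
  expect_equal(build_joint_covariance(cfg1),
               matrix(c(1, 0.5, 0.5, 1), 2, 2))

  # at c = sigma^2 the matrix touches the PSD boundary
  cfgb <- sim_config(p = 3, q = 2, coupling_strength = 1, bm_rate = 1)
  ev <- eigen(build_joint_covariance(cfgb), symmetric = TRUE,
              only.values = TRUE)$values
  expect_lt(abs(min(ev)), 1e-9)

  expect_error(
    build_joint_covariance(sim_config(coupling_strength = 1.2, bm_rate = 1)),
    "maximal admissible")
})

test_that("Brownian simulation matches its matrix-normal law", {
  tr <- tiny_tree()
  # zero trait covariance: every species sits at the root state
  Z <- simulate_species_traits_bm(tr, matrix(0, 2, 2), seed = 1)
  expect_equal(max(abs(Z)), 0)

  # star tree, identity trait covariance: species are independent, so
  # cross-species and cross-trait covariances vanish (Monte Carlo)
  st <- star_tree(4)
  reps <- 2000
  a11 <- b11 <- a12 <- numeric(reps)
  for (i in seq_len(reps)) {
    M <- simulate_species_traits_bm(st, diag(1, 2), seed = 10000 + i)
    a11[i] <- M[1, 1]; b11[i] <- M[2, 1]; a12[i] <- M[1, 2]
  }
  se <- 1 / sqrt(reps)
  expect_lt(abs(cov(a11, b11)), 3 * se)   # across species
  expect_lt(abs(cov(a11, a12)), 3 * se)   # across traits
  expect_lt(abs(mean(a11)), 3 * se)
  expect_lt(abs(var(a11) - 1), 5 * se)

  # planted rank-1 coupling surfaces as the first left singular vector
  # of the empirical cross-covariance
  cfg <- sim_config(n_species = 32, p = 3, q = 2, coupling_strength = 0.9)
  Sigma <- build_joint_covariance(cfg)
  st32 <- star_tree(32)
  coss <- vapply(seq_len(300), function(i) {
    M <- simulate_species_traits_bm(st32, Sigma, seed = 20000 + i)
    R <- cov(M[, 1:3], M[, 4:5])
    abs_cos(svd(R)$u[, 1], cfg$u_star)
  }, numeric(1))
  expect_gte(mean(coss), 0.9)
})

test_that("specimen simulation plants sex effects, clines and MCAR gaps", {
  means <- matrix(rnorm(12), 4, 3,
                  dimnames = list(paste0("sp", 1:4), paste0("m", 1:3)))

  cfg0 <- sim_config(n_species = 4, p = 3, q = 2, specimens_per_species = 4,
                     individual_sd = 0, missing_rate = 0, seed = 2)
  tab <- simulate_specimens(means, cfg0)
  expect_equal(unname(tab$measurements),
               unname(means[tab$meta$species, ]))

  # seed determinism: identical config, identical bytes
  tab_b <- simulate_specimens(means, cfg0)
  expect_identical(tab, tab_b)

  # MCAR count within a 99.9% binomial band (43 x 63 cells at 10%)
  means_big <- matrix(rnorm(43 * 63), 43, 63,
                      dimnames = list(paste0("sp", 1:43), paste0("m", 1:63)))
  cfg_m <- sim_config(n_species = 43, p = 63, q = 2,
                      specimens_per_species = 1, missing_rate = 0.1, seed = 7)
  tab_m <- simulate_specimens(means_big, cfg_m)
  n_missing <- sum(is.na(tab_m$measurements))
  expect_gte(n_missing, qbinom(0.0005, 43 * 63, 0.1))
  expect_lte(n_missing, qbinom(0.9995, 43 * 63, 0.1))

  # additive sex effect recovered from sex-mean difference
  cfg_s <- sim_config(n_species = 4, p = 3, q = 2, specimens_per_species = 200,
                      sex_effect = c(1, 0, 0), individual_sd = 0.2, seed = 3)
  tab_s <- simulate_specimens(means, cfg_s)
  male <- tab_s$meta$sex == "male"
  diff1 <- mean(tab_s$measurements[male, 1]) -
    mean(tab_s$measurements[!male, 1])
  expect_lt(abs(diff1 - 1), 0.05)

  expect_error(sim_config(missing_rate = 1), "missing_rate")
})

test_that("a full synthetic study is internally aligned and reproducible", {
  cfg <- sim_config(seed = 11, missing_rate = 0.05)
  s1 <- simulate_ecogeo_study(cfg)
  s2 <- simulate_ecogeo_study(cfg)
  expect_identical(ape::write.tree(s1$dataset$tree),
                   ape::write.tree(s2$dataset$tree))
  expect_identical(s1$dataset$X, s2$dataset$X)
  expect_identical(s1$specimens$measurements, s2$specimens$measurements)
  expect_equal(rownames(s1$dataset$X), s1$dataset$tree$tip.label)
  expect_equal(sort(unique(s1$specimens$meta$species)),
               sort(s1$dataset$species))
})
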