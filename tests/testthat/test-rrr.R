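rand_coords <- function(n, seed, lat_range = c(0, 10), lon_range = c(100, 110)) {
  set.seed(seed)
  cbind(latitude = runif(n, lat_range[1], lat_range[2]),
        longitude = runif(n, lon_range[1], lon_range[2]))
}

test_that("partial regression coefficients match the per-trait linear model", {
  G <- rand_coords(12, seed = 2)
  x_exact <- 2 * G[, 1] + 0 * G[, 2] + 7
  B <- pgls_coefficients(cbind(t1 = x_exact), G)
  expect_equal(unname(B[1, ]), c(2, 0), tolerance = 1e-10)

  B0 <- pgls_coefficients(cbind(t1 = rep(3, 12)), G)
  expect_equal(unname(B0[1, ]), c(0, 0), tolerance = 1e-12)

  set.seed(3)
  X <- matrix(rnorm(36), 12, 3)
  B2 <- pgls_coefficients(X, G)
  for (j in 1:3) {
    ref <- coef(lm(X[, j] ~ G[, 1] + G[, 2]))[2:3]
    expect_equal(unname(B2[j, ]), unname(ref), tolerance = 1e-9)
  }

  # GLS with C = I equals OLS
  B3 <- pgls_coefficients(X, G, diag(12))
  expect_equal(B3, B2, tolerance = 1e-10)

  Gbad <- cbind(latitude = 1:12, longitude = 2 * (1:12) + 5)
  expect_error(pgls_coefficients(X, Gbad), "collinear")
})

test_that("a unit latitudinal cline is recovered exactly", {
  G <- rand_coords(10, seed = 4)
  f <- fit_rrr(cbind(t1 = G[, 1]), G)
  expect_equal(f$d[1], 1, tolerance = 1e-10)
  expect_equal(unname(f$w[, 1]), c(1, 0), tolerance = 1e-10)
  expect_equal(f$effect[1], 1)

  # isotropic gradient: two traits tracking latitude and longitude
  f2 <- fit_rrr(cbind(a = G[, 1], b = G[, 2]), G)
  expect_equal(f2$d, c(1, 1), tolerance = 1e-9)
  expect_equal(crossprod(f2$w), diag(1, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the first singular value bounds every directional slope", {
  G <- rand_coords(11, seed = 6)
  set.seed(7)
  X <- matrix(rnorm(55), 11, 5)
  f <- fit_rrr(X, G)
  # independent coefficient oracle via lm()
  B <- t(vapply(1:5, function(j) coef(lm(X[, j] ~ G[, 1] + G[, 2]))[2:3],
                numeric(2)))
  set.seed(8)
  U <- matrix(rnorm(5 * 10000), 5); U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  slopes <- sqrt(colSums((t(B) %*% U)^2))
  expect_true(all(slopes <= f$d[1] + 1e-9))
  expect_equal(sqrt(sum((t(B) %*% f$u[, 1])^2)), f$d[1], tolerance = 1e-9)
  expect_equal(sum(f$effect), 1, tolerance = 1e-12)
})

test_that("a noise-free planted cline is recovered to machine precision", {
  beta <- c(0.3, 0.1)
  dir_p <- unit_vector_for_test <- c(3, -1, 2, 0, 1) / sqrt(15)
  means <- matrix(0, 4, 5, dimnames = list(paste0("sp", 1:4),
                                           paste0("m", 1:5)))
  cfg <- sim_config(n_species = 4, p = 5, q = 2, specimens_per_species = 6,
                    individual_sd = 0, missing_rate = 0, cline_slope = beta,
                    cline_direction = dir_p, seed = 9)
  tab <- simulate_specimens(means, cfg)
  G <- cbind(latitude = tab$meta$latitude, longitude = tab$meta$longitude)
  f <- fit_rrr(tab$measurements, G)
  expect_equal(f$d[1], sqrt(sum(beta^2)), tolerance = 1e-9)
  expect_gte(abs_cos(f$w[, 1], beta), 1 - 1e-9)
  expect_gte(abs_cos(f$u[, 1], dir_p), 1 - 1e-9)
  expect_lt(f$d[2], 1e-9)
})

test_that("rotating the coordinate frame rotates the geographic loadings", {
  G <- rand_coords(15, seed = 10)
  set.seed(11)
  X <- matrix(rnorm(60), 15, 4)
  f <- fit_rrr(X, G)
  th <- 0.6
  Q <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  GQ <- G %*% Q
  colnames(GQ) <- colnames(G)
  fq <- fit_rrr(X, GQ)
  expect_equal(fq$d, f$d, tolerance = 1e-9)
  for (k in 1:2) {
    expect_gte(abs_cos(fq$w[, k], t(Q) %*% f$w[, k]), 1 - 1e-9)
    expect_gte(abs_cos(fq$u[, k], f$u[, k]), 1 - 1e-9)
  }
})

test_that("RRR finds the steep cline where PLS chases the long range axis", {
  # elongated sampling range along longitude; the true cline is almost
  # perpendicular (latitudinal), with only a whiff of longitudinal slope
  set.seed(12)
  n <- 60
  G <- cbind(latitude = runif(n, 0, 4), longitude = runif(n, 0, 40))
  beta <- c(1, 0.1)
  dir_p <- unit_vector <- c(1, 1, 1) / sqrt(3)
  X <- outer(drop(G %*% beta), dir_p) +
    matrix(rnorm(n * 3, sd = 0.05), n, 3)
  f_rrr <- fit_rrr(X, G)
  expect_gte(abs_cos(f_rrr$w[, 1], c(1, 0)), 0.95)
  f_pls <- fit_2bpls(X, G)
  # PLS geographic loading aligns with the long (longitude) axis instead
  expect_gt(abs(f_pls$v[2, 1]), abs(f_pls$v[1, 1]))
})

test_that("a unit star phylogeny reproduces the ordinary RRR", {
  G <- rand_coords(9, seed = 13)
  set.seed(14)
  X <- matrix(rnorm(45), 9, 5)
  C <- tree_to_covariance(star_tree(9))
  f0 <- fit_rrr(X, G)
  f1 <- fit_rrr(X, G, C)
  for (field in c("B", "d", "u", "w", "r", "effect")) {
    expect_equal(f1[[field]], f0[[field]], tolerance = 1e-8)
  }
})

test_that("the RRR permutation test detects a strong cline and not noise", {
  G <- rand_coords(20, seed = 15)
  dir_p <- c(1, 0, 0, 0)
  X <- outer(G[, 1], dir_p) + matrix(rnorm(80, sd = 0.05), 20, 4)
  pt <- rrr_permutation_test(X, G, n_perm = 199, seed = 16)
  expect_lte(pt$p, 0.01)
  set.seed(17)
  Xnull <- matrix(rnorm(80), 20, 4)
  pt0 <- rrr_permutation_test(Xnull, G, n_perm = 199, seed = 18)
  expect_gt(pt0$p, 0.01)
})
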