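test_that("specimen tables parse, flag missing cells, and validate", {
  path <- write_specimen_csv(small_specimen_df())
  tab <- read_specimen_table(path)
  expect_s3_class(tab, "specimen_table")
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(sum(is.na(tab$measurements)), 1L)
  expect_equal(unname(tab$measurements[1, "m1"]), 10.5)

  df <- small_specimen_df()
  df$m1[2] <- -1.2
  expect_error(read_specimen_table(write_specimen_csv(df)), "onpositive")

  df2 <- small_specimen_df()
  names(df2)[names(df2) == "species"] <- "taxon"
  expect_error(read_specimen_table(write_specimen_csv(df2)),
               "missing required column: species")
  tab2 <- read_specimen_table(write_specimen_csv(df2),
                              specimen_schema(species = "taxon"))
  expect_equal(tab2$meta$species, rep("Macaca_test", 3))

  df3 <- small_specimen_df()
  df3$sex[1] <- "hembra"
  expect_error(read_specimen_table(write_specimen_csv(df3)), "unknown sex")

  df4 <- small_specimen_df()
  df4$longitude[2] <- NA
  expect_error(read_specimen_table(write_specimen_csv(df4)),
               "present together")
})

test_that("tab-delimited input and explicit measurement schema work", {
  df <- small_specimen_df()
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, na = "")
  tab <- read_specimen_table(path, specimen_schema(measurements = c("m1", "m2")))
  expect_equal(colnames(tab$measurements), c("m1", "m2"))
  expect_error(
    read_specimen_table(path, specimen_schema(measurements = c("m1", "zz"))),
    "zz")
})

test_that("Newick reading preserves structure and rejects malformed input", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(unname(tip_depths(tr)[c("A", "B", "C")]), c(2, 2, 2))

  star <- parse_newick("(A:1,B:1,C:1);")
  expect_equal(ape::Ntip(star), 3L)
  expect_equal(unname(tip_depths(star)), c(1, 1, 1))

  expect_error(parse_newick("((A:1,B:1):1,C:2)"), "semicolon")
  expect_error(parse_newick("(A,B,C);"), "branch length")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate")

  path <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  expect_equal(read_newick_tree(path)$tip.label, tr$tip.label)
})

test_that("align_dataset intersects species, drops extras, follows the tree order", {
  set.seed(42)
  tree <- simulate_yule_tree(12, seed = 5)
  sp <- tree$tip.label
  morph <- data.frame(species = sp, tr1 = rnorm(12), tr2 = rnorm(12))
  env <- data.frame(species = c(sp, "extra_sp"), e1 = rnorm(13))
  geo <- data.frame(species = sp, latitude = runif(12, -5, 25),
                    longitude = runif(12, 95, 125))

  expect_warning(ds <- align_dataset(morph, env, geo, tree), "extra_sp")
  expect_equal(length(ds$species), 12L)

  # exclusion of a geographic outlier, as when one species is omitted
  # from a spatial analysis
  expect_warning(ds11 <- align_dataset(morph, env, geo, tree,
                                       drop_species = sp[1]), sp[1])
  expect_equal(length(ds11$species), 11L)
  expect_false(sp[1] %in% ds11$species)

  # order independence: permuting input rows changes nothing
  perm <- sample(12)
  expect_warning(ds_perm <- align_dataset(morph[perm, ], env, geo[rev(seq_len(12)), ], tree))
  expect_identical(ds_perm$species, ds$species)
  expect_equal(ds_perm$X, ds$X)
  expect_equal(ds_perm$G, ds$G)

  # fewer than 3 shared species is refused
  expect_error(
    suppressWarnings(align_dataset(morph[1:2, ], env, geo, tree)),
    "fewer than 3")
  expect_error(align_dataset(rbind(morph, morph[1, ]), env, geo, tree),
               "duplicate")
})

test_that("result JSON round-trips all fields to 1e-12", {
  b <- seeded_blocks(8, 3, 2, seed = 11)
  fit <- fit_2bpls(b$X, b$Y)
  path <- tempfile(fileext = ".json")
  write_results(fit, path)
  back <- read_results(path)
  expect_s3_class(back, "pls2b")
  for (f in c("u", "v", "d", "scores_x", "scores_y", "r", "effect")) {
    expect_equal(back[[f]], fit[[f]], tolerance = 1e-12, ignore_attr = FALSE)
  }
  expect_equal(back$phylogenetic, FALSE)

  G <- cbind(latitude = runif(8, 0, 10), longitude = runif(8, 0, 10))
  rr <- fit_rrr(b$X, G)
  write_results(rr, path)
  rr2 <- read_results(path)
  expect_equal(rr2$d, rr$d, tolerance = 1e-12)
  expect_true(all(diff(rr2$d) <= 1e-15))
  expect_equal(rr2$B, rr$B, tolerance = 1e-12)

  mt <- structure(list(r = 0.07, p = 0.4, n_perm = 10000L, n = 28L),
                  class = "mantel_result")
  write_results(mt, path)
  mt2 <- read_results(path)
  expect_equal(mt2$r, 0.07)
  expect_equal(mt2$p, 0.4)
  expect_equal(mt2$n_perm, 10000)
})
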