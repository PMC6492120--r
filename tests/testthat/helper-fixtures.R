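# Shared fixtures: tiny trees, seeded blocks, and a CSV writer for
# specimen-table tests. Everything is generated in code.

tiny_tree <- function() parse_newick("((A:1,B:1):1,C:2);")

star_tree <- function(n, t = 1, labels = NULL) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(t, nrow(tr$edge))
  tr$tip.label <- labels %||% paste0("s", seq_len(n))
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seeded_blocks <- function(n, p, q, seed = 1) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p))),
       Y = matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("y", 1:q))))
}

write_specimen_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

small_specimen_df <- function() {
  data.frame(specimen_id = c("a1", "a2", "a3"),
             species = "Macaca_test",
             sex = c("female", "male", "female"),
             age_class = "adult", provenance = "wild",
             latitude = c(1, 2, 3), longitude = c(101, 102, 103),
             m1 = c(10.5, 11.0, 10.8), m2 = c(5.2, NA, 5.4))
}

# angle-free alignment measure between two directions
abs_cos <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
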