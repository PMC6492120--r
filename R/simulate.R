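#' Configuration for the synthetic ecogeographic study generator
#'
#' Collects every knob of the generator: tree size, block dimensions,
#' the planted rank-1 cross-block coupling, the Brownian-motion rate,
#' specimen-level sex effects, individual noise, spatial clines,
#' isolation-by-distance drift and MCAR missingness. The defaults
#' emulate, at reduced dimension, a genus-level craniodental study: a
#' dozen species on a time-scaled tree of unit depth, a morphology
#' block coupled to an environment block through one shared axis,
#' and a handful of specimens of both sexes per species.
#'
#' @param n_species number of species (tips), >= 3.
#' @param p morphology dimension.
#' @param q environment dimension.
#' @param coupling_rank 0 (independent blocks) or 1 (planted coupling).
#' @param coupling_strength cross-block covariance `c` along the planted
#'   axis pair; must satisfy `c <= bm_rate` for a valid covariance.
#' @param u_star,v_star planted unit directions in trait / environment
#'   space; defaults are deterministic equal-weight unit vectors.
#' @param bm_rate Brownian-motion rate `sigma^2` per unit branch length
#'   (each trait dimension).
#' @param specimens_per_species specimens sampled per species; with
#'   >= 2 both sexes are present in every species.
#' @param sex_effect length-p additive male-minus-female effect
#'   (default zero).
#' @param individual_sd standard deviation of individual Gaussian noise.
#' @param missing_rate MCAR cell-deletion probability in [0, 1).
#' @param cline_slope length-2 vector `beta`: per-degree (latitude,
#'   longitude) slope of the planted cline.
#' @param cline_direction unit length-p trait combination carrying the
#'   cline (default: first basis vector).
#' @param ibd_strength standard deviation of the spatially correlated
#'   drift field added per trait (0 disables isolation by distance).
#' @param ibd_range_km range of the exponential spatial covariance of
#'   the drift field.
#' @param bbox locality bounding box, `c(lat_min, lat_max, lon_min,
#'   lon_max)` in decimal degrees.
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 12L, p = 6L, q = 4L,
                       coupling_rank = 1L, coupling_strength = 0.9,
                       u_star = NULL, v_star = NULL, bm_rate = 1,
                       specimens_per_species = 6L,
                       sex_effect = NULL, individual_sd = 0.1,
                       missing_rate = 0, cline_slope = c(0, 0),
                       cline_direction = NULL,
                       ibd_strength = 0, ibd_range_km = 1000,
                       bbox = c(-5, 25, 95, 125), seed = 1L) {
  if (n_species < 3) stop("n_species must be >= 3")
  if (!coupling_rank %in% c(0L, 1L)) stop("coupling_rank must be 0 or 1")
  if (coupling_strength < 0 || bm_rate <= 0 || individual_sd < 0 ||
      ibd_strength < 0 || ibd_range_km <= 0) {
    stop("rates and standard deviations must be nonnegative")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (length(cline_slope) != 2) stop("cline_slope must have length 2")
  if (length(bbox) != 4 || bbox[1] >= bbox[2] || bbox[3] >= bbox[4]) {
    stop("bbox must be c(lat_min, lat_max, lon_min, lon_max)")
  }
  u_star <- unit_vector(u_star %||% rep(1, p))
  v_star <- unit_vector(v_star %||% rep(1, q))
  if (length(u_star) != p || length(v_star) != q) {
    stop("u_star / v_star dimensions must match p / q")
  }
  sex_effect <- sex_effect %||% rep(0, p)
  if (length(sex_effect) != p) stop("sex_effect must have length p")
  cline_direction <- unit_vector(cline_direction %||% c(1, rep(0, p - 1)))
  if (length(cline_direction) != p) stop("cline_direction must have length p")
  structure(list(n_species = as.integer(n_species), p = as.integer(p),
                 q = as.integer(q), coupling_rank = as.integer(coupling_rank),
                 coupling_strength = coupling_strength, u_star = u_star,
                 v_star = v_star, bm_rate = bm_rate,
                 specimens_per_species = as.integer(specimens_per_species),
                 sex_effect = sex_effect, individual_sd = individual_sd,
                 missing_rate = missing_rate, cline_slope = cline_slope,
                 cline_direction = cline_direction,
                 ibd_strength = ibd_strength, ibd_range_km = ibd_range_km,
                 bbox = bbox, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pure-birth (Yule) tree of unit depth
#'
#' Generates an ultrametric tree under a pure-birth process and rescales
#' all branch lengths so the root-to-tip depth equals 1 — the simplest
#' stand-in for a time-scaled molecular phylogeny.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed RNG seed.
#' @return an ultrametric [ape::phylo] tree with tip labels `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Joint trait-environment covariance with planted low-rank coupling
#'
#' Builds the (p+q) x (p+q) column covariance of the Brownian process:
#' `sigma^2 I` within each block and a rank-1 cross block
#' `c u* v*'` when coupling is on. The matrix is positive semidefinite
#' exactly when `c <= sigma^2` (its extreme eigenvalues are
#' `sigma^2 +/- c`).
#'
#' @param cfg a [sim_config()].
#' @return symmetric PSD (p+q) x (p+q) matrix.
#' @export
build_joint_covariance <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$p; q <- cfg$q; s2 <- cfg$bm_rate
  cc <- if (cfg$coupling_rank == 1L) cfg$coupling_strength else 0
  if (cc > s2 + 1e-12) {
    stop(sprintf("coupling_strength %.4g makes the joint covariance indefinite; maximal admissible value is bm_rate = %.4g",
                 cc, s2))
  }
  Sigma <- diag(s2, p + q)
  if (cc > 0) {
    Sxy <- cc * tcrossprod(cfg$u_star, cfg$v_star)
    Sigma[seq_len(p), p + seq_len(q)] <- Sxy
    Sigma[p + seq_len(q), seq_len(p)] <- t(Sxy)
  }
  Sigma
}

#' Simulate species trait values under Brownian motion on a tree
#'
#' Draws one matrix-normal sample with row covariance `C` (the
#' Brownian-motion covariance of the tree) and column covariance
#' `Sigma`, via the square roots `C^(1/2) Z Sigma^(1/2)` with `Z`
#' standard normal — exact under Brownian motion with a zero root
#' state.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param Sigma trait column covariance (PSD).
#' @param seed RNG seed.
#' @return n_tips x ncol(Sigma) matrix with species rownames.
#' @export
simulate_species_traits_bm <- function(tree, Sigma, seed = 1L) {
  validate_phylo_tree(tree)
  Sigma <- as_numeric_matrix(Sigma, "Sigma")
  n <- ape::Ntip(tree)
  if (n < 3) stop("tree must have at least 3 tips")
  d <- ncol(Sigma)
  C <- tree_to_covariance(tree)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * d), n, d)
  out <- psd_sqrt(C) %*% Z %*% psd_sqrt(Sigma)
  rownames(out) <- tree$tip.label
  out
}

# Gaussian random field over localities: exponential covariance in
# geodesic distance, unit marginal variance.
.ibd_field <- function(coords, range_km, n_fields) {
  D <- geodesic_distance_matrix(coords)
  K <- exp(-D / range_km)
  psd_sqrt(K) %*% matrix(stats::rnorm(nrow(coords) * n_fields),
                         nrow(coords), n_fields)
}

#' Simulate specimen-level measurements around species means
#'
#' Each specimen is its species mean, plus the additive sex effect for
#' males, plus the planted spatial cline `(beta . (lat, lon))` along
#' `cline_direction`, plus (optionally) a spatially correlated
#' isolation-by-distance drift field, plus independent Gaussian noise.
#' Localities are uniform in the bounding box; sexes alternate within
#' species so both are present whenever at least two specimens are
#' sampled; cells are deleted completely at random at `missing_rate`.
#'
#' Note the generated values live on the scale of the species means
#' passed in (the generator plants additive structure); to feed them
#' through a log-scale pipeline, exponentiate the means beforehand or
#' treat the simulated values as already log-scale with
#' `on_log_scale = FALSE` downstream.
#'
#' @param species_means n x p matrix with species rownames.
#' @param cfg a [sim_config()]; fields `specimens_per_species`,
#'   `sex_effect`, `individual_sd`, `missing_rate`, `cline_slope`,
#'   `cline_direction`, `ibd_strength`, `ibd_range_km`, `bbox`, `seed`
#'   are used.
#' @return a [specimen_table] (measurements may contain `NA`; values
#'   are not constrained positive — they are analysis-scale traits).
#' @export
simulate_specimens <- function(species_means, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  species_means <- as_numeric_matrix(species_means, "species_means")
  if (is.null(rownames(species_means))) {
    rownames(species_means) <- sprintf("t%d", seq_len(nrow(species_means)))
  }
  if (ncol(species_means) != cfg$p) stop("species_means must have p columns")
  k <- cfg$specimens_per_species
  if (k < 1) stop("specimens_per_species must be >= 1")
  n_sp <- nrow(species_means)
  m <- n_sp * k
  set.seed(cfg$seed)
  species <- rep(rownames(species_means), each = k)
  sex <- rep(rep_len(c("female", "male"), k), times = n_sp)
  lat <- stats::runif(m, cfg$bbox[1], cfg$bbox[2])
  lon <- stats::runif(m, cfg$bbox[3], cfg$bbox[4])
  vals <- species_means[species, , drop = FALSE]
  vals <- vals + outer(as.numeric(sex == "male"), cfg$sex_effect)
  cline <- drop(cbind(lat, lon) %*% cfg$cline_slope)
  vals <- vals + outer(cline, cfg$cline_direction)
  if (cfg$ibd_strength > 0) {
    vals <- vals + cfg$ibd_strength *
      .ibd_field(cbind(lat, lon), cfg$ibd_range_km, cfg$p)
  }
  vals <- vals + matrix(stats::rnorm(m * cfg$p, sd = cfg$individual_sd),
                        m, cfg$p)
  if (cfg$missing_rate > 0) {
    drop_mask <- matrix(stats::runif(m * cfg$p) < cfg$missing_rate, m, cfg$p)
    vals[drop_mask] <- NA_real_
  }
  colnames(vals) <- colnames(species_means) %||%
    sprintf("trait%02d", seq_len(cfg$p))
  rownames(vals) <- NULL
  meta <- data.frame(specimen_id = sprintf("%s_%02d", species,
                                           rep(seq_len(k), times = n_sp)),
                     species = species, sex = sex,
                     age_class = "adult", provenance = "wild",
                     latitude = lat, longitude = lon,
                     stringsAsFactors = FALSE)
  specimen_table(meta, vals, check_positive = FALSE)
}

#' Simulate a complete synthetic ecogeographic study
#'
#' One call producing everything the pipeline consumes, with known
#' ground truth: a unit-depth Yule tree, species-level morphology and
#' environment blocks evolved under Brownian motion with the planted
#' cross-block coupling, species range-centroid coordinates uniform in
#' the bounding box, and a specimen-level table around the species
#' means. Sub-seeds are derived from `cfg$seed` by fixed small offsets
#' so each stage is independently reproducible.
#'
#' @param cfg a [sim_config()].
#' @return list with `dataset` (a [species_dataset]), `specimens`
#'   (a [specimen_table]) and `truth` (planted `u_star`, `v_star`,
#'   `cline_slope`, `cline_direction`).
#' @export
simulate_ecogeo_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- simulate_yule_tree(cfg$n_species, seed = cfg$seed)
  Sigma <- build_joint_covariance(cfg)
  XY <- simulate_species_traits_bm(tree, Sigma, seed = cfg$seed + 1L)
  X <- XY[, seq_len(cfg$p), drop = FALSE]
  Y <- XY[, cfg$p + seq_len(cfg$q), drop = FALSE]
  colnames(X) <- sprintf("trait%02d", seq_len(cfg$p))
  colnames(Y) <- sprintf("env%02d", seq_len(cfg$q))
  set.seed(cfg$seed + 2L)
  G <- cbind(latitude = stats::runif(cfg$n_species, cfg$bbox[1], cfg$bbox[2]),
             longitude = stats::runif(cfg$n_species, cfg$bbox[3], cfg$bbox[4]))
  rownames(G) <- tree$tip.label
  spec_cfg <- cfg
  spec_cfg$seed <- cfg$seed + 3L
  specimens <- simulate_specimens(X, spec_cfg)
  list(dataset = species_dataset(tree$tip.label, X, Y, G, tree),
       specimens = specimens,
       truth = list(u_star = cfg$u_star, v_star = cfg$v_star,
                    cline_slope = cfg$cline_slope,
                    cline_direction = cfg$cline_direction))
}

#' Simulate localities with isolation-by-distance phenotypic drift
#'
#' Stand-alone generator for Mantel-test studies: `m` localities
#' uniform in a bounding box and a p-trait matrix equal to a spatially
#' correlated Gaussian field (exponential covariance in geodesic
#' distance, standard deviation `ibd_strength`) plus independent noise.
#' With `ibd_strength = 0` phenotype and geography are independent.
#'
#' @param m number of localities.
#' @param p number of traits.
#' @param ibd_strength drift field standard deviation.
#' @param ibd_range_km exponential covariance range.
#' @param noise_sd independent noise standard deviation.
#' @param bbox `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param seed RNG seed.
#' @return list with `coords` (m x 2) and `X` (m x p).
#' @export
simulate_ibd_localities <- function(m = 40L, p = 4L, ibd_strength = 1,
                                    ibd_range_km = 1000, noise_sd = 0.3,
                                    bbox = c(-5, 25, 95, 125), seed = 1L) {
  set.seed(seed)
  coords <- cbind(latitude = stats::runif(m, bbox[1], bbox[2]),
                  longitude = stats::runif(m, bbox[3], bbox[4]))
  X <- matrix(stats::rnorm(m * p, sd = noise_sd), m, p)
  if (ibd_strength > 0) {
    X <- X + ibd_strength * .ibd_field(coords, ibd_range_km, p)
  }
  list(coords = coords, X = X)
}
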