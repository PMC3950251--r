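#' Synthetic segment clouds with known hull volumes
#'
#' Samples points uniformly on the surface of a parametric shape (what a
#' scanner sees), optionally jittered with isotropic Gaussian noise, and
#' returns the cloud together with its ground-truth hull volume:
#' * `ellipsoid_surface`: semi-axes `size = c(a, b, c)`, truth `4*pi*a*b*c/3`;
#' * `box`: side lengths `size = c(lx, ly, lz)`, the 8 corners are always
#'   included so the truth `lx*ly*lz` is exact even at `n_points = 8`;
#' * `cylinder`: `radius`, `length`, lateral surface plus end caps, truth
#'   `pi * r^2 * L`;
#' * `curved_tube`: a tube of `radius` whose centreline of length `length`
#'   is bent along a circular arc of `arc_angle_deg` (0 = straight). The
#'   hull of a bent tube has no simple closed form, so the truth is a
#'   reference hull of a dense deterministic surface grid
#'   (`reference_points`, default 1e6).
#'
#' @param kind shape family.
#' @param n_points number of surface points (>= 4).
#' @param seed integer RNG seed; generation is a pure function of it.
#' @param size numeric(3): semi-axes (ellipsoid) or side lengths (box).
#' @param radius,length tube/cylinder dimensions (m).
#' @param arc_angle_deg arc angle of the curved tube centreline, in
#'   \[0, 180\].
#' @param noise_sd isotropic Gaussian jitter sd in metres (0 = none).
#' @param reference_points grid size for the curved-tube reference hull.
#' @return List with `cloud` (a [pointcloud]) and `truth` (list with
#'   `analytic_volume` and the echoed generator parameters).
#' @examples
#' sph <- generate_segment_cloud("ellipsoid_surface", n_points = 2000,
#'                               seed = 1, size = c(1, 1, 1))
#' compute_hull(sph$cloud)$volume / sph$truth$analytic_volume
#' @export
generate_segment_cloud <- function(kind = c("ellipsoid_surface", "cylinder",
                                            "curved_tube", "box"),
                                   n_points, seed,
                                   size = c(1, 1, 1),
                                   radius = 0.1, length = 1,
                                   arc_angle_deg = 90,
                                   noise_sd = 0,
                                   reference_points = 1e6) {
  kind <- match.arg(kind)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 4L) stop("n_points must be >= 4")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (kind %in% c("ellipsoid_surface", "box")) {
    if (length(size) != 3L || any(size <= 0)) stop("size must be 3 positive values")
  } else {
    if (radius <= 0 || length <= 0) stop("radius and length must be > 0")
  }
  if (kind == "curved_tube" &&
      (arc_angle_deg < 0 || arc_angle_deg > 180))
    stop("arc_angle_deg must be in [0, 180]")

  pts <- withr::with_seed(as.integer(seed), {
    p <- switch(kind,
      ellipsoid_surface = .sample_ellipsoid(n_points, size),
      box = .sample_box(n_points, size),
      cylinder = .sample_tube(n_points, radius, length, 0),
      curved_tube = .sample_tube(n_points, radius, length, arc_angle_deg))
    if (noise_sd > 0) p <- p + matrix(rnorm(3 * nrow(p), sd = noise_sd),
                                      ncol = 3)
    p
  })
  truth_vol <- switch(kind,
    ellipsoid_surface = 4 * pi * prod(size) / 3,
    box = prod(size),
    cylinder = pi * radius^2 * length,
    curved_tube = .tube_reference_volume(radius, length, arc_angle_deg,
                                         reference_points))
  list(cloud = pointcloud(pts, label = kind),
       truth = list(analytic_volume = truth_vol, kind = kind, size = size,
                    radius = radius, length = length,
                    arc_angle_deg = arc_angle_deg, n_points = n_points,
                    noise_sd = noise_sd, seed = seed))
}

# uniform on the ellipsoid surface by rejection from the sphere
# parameterisation, weighting by the surface-area Jacobian
.sample_ellipsoid <- function(n, axes) {
  a <- axes[1]; b <- axes[2]; c <- axes[3]
  wmax <- max(b * c, a * c, a * b)
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 64L)
    u <- matrix(rnorm(3 * m), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    w <- sqrt((u[, 1] * b * c)^2 + (u[, 2] * a * c)^2 + (u[, 3] * a * b)^2)
    keep <- runif(m) < w / wmax
    out <- rbind(out, cbind(a * u[keep, 1], b * u[keep, 2], c * u[keep, 3]))
  }
  out[seq_len(n), , drop = FALSE]
}

.sample_box <- function(n, sides) {
  corners <- as.matrix(expand.grid(c(0, sides[1]), c(0, sides[2]),
                                   c(0, sides[3])))
  dimnames(corners) <- NULL
  if (n <= 8L) return(corners[seq_len(max(n, 8L)), , drop = FALSE])
  m <- n - 8L
  areas <- c(sides[2] * sides[3], sides[1] * sides[3], sides[1] * sides[2])
  face_axis <- sample.int(3L, m, replace = TRUE, prob = areas)
  side <- sample(c(0, 1), m, replace = TRUE)
  p <- cbind(runif(m, 0, sides[1]), runif(m, 0, sides[2]),
             runif(m, 0, sides[3]))
  p[cbind(seq_len(m), face_axis)] <- side[seq_len(m)] * sides[face_axis]
  rbind(corners, p)
}

# tube around a circular-arc centreline in the xz plane; arc 0 = straight
# cylinder along x. Surface = lateral tube plus the two end caps, sampled
# by area.
.sample_tube <- function(n, r, L, arc_deg) {
  lat_area <- 2 * pi * r * L
  cap_area <- 2 * pi * r^2
  n_cap <- round(n * cap_area / (lat_area + cap_area))
  n_lat <- n - n_cap
  s <- runif(n_lat, 0, L)                  # arclength along the centreline
  phi <- runif(n_lat, 0, 2 * pi)           # angle around the tube
  rho_cap <- r * sqrt(runif(n_cap))
  phi_cap <- runif(n_cap, 0, 2 * pi)
  s_cap <- sample(c(0, L), n_cap, replace = TRUE)
  s_all <- c(s, s_cap)
  rho_all <- c(rep(r, n_lat), rho_cap)
  phi_all <- c(phi, phi_cap)
  .tube_embed(s_all, rho_all, phi_all, r, L, arc_deg)
}

.tube_embed <- function(s, rho, phi, r, L, arc_deg) {
  if (arc_deg == 0) {
    return(cbind(s, rho * cos(phi), rho * sin(phi)))
  }
  theta <- arc_deg * pi / 180
  R <- L / theta                           # centreline arc radius
  ang <- s / R
  # centreline on a circle of radius R in the xz plane, centred at (0,0,R)
  # local frame: normal points towards the arc centre, binormal is y
  cx <- R * sin(ang)
  cz <- R * (1 - cos(ang))
  # frame along the centreline: tangent (cos ang, 0, sin ang),
  # normal (-sin ang, 0, cos ang), binormal (0, 1, 0)
  x <- cx + rho * sin(phi) * (-sin(ang))
  y <- rho * cos(phi)
  z <- cz + rho * sin(phi) * cos(ang)
  cbind(x, y, z)
}

.tube_reference_cache <- new.env(parent = emptyenv())

.tube_reference_volume <- function(r, L, arc_deg, n_ref) {
  key <- paste(r, L, arc_deg, n_ref, sep = "|")
  hit <- .tube_reference_cache[[key]]
  if (!is.null(hit)) return(hit)
  # deterministic grid: rings along the centreline plus dense end caps
  n_ring <- max(16L, round(sqrt(n_ref / (L / (2 * pi * r)))))
  n_len <- max(8L, ceiling(n_ref / n_ring))
  s <- rep(seq(0, L, length.out = n_len), each = n_ring)
  phi <- rep(seq(0, 2 * pi, length.out = n_ring + 1L)[-1L], times = n_len)
  pts <- .tube_embed(s, rep(r, length(s)), phi, r, L, arc_deg)
  vol <- compute_hull(pointcloud(pts, label = "tube_reference"))$volume
  .tube_reference_cache[[key]] <- vol
  vol
}

#' Synthetic articulated skeleton templates
#'
#' Assembles a skeleton model from parametric segments with known truth
#' volumes, for end-to-end testing of the hulling pipeline. Two templates
#' are provided, their proportions being documented constants (relative to
#' the trunk length `scale`), not biological claims:
#' * `quadruped`: ellipsoid trunk and skull, a curved-tube neck (60 deg
#'   arc), four two-part cylindrical limbs;
#' * `biped_bird`: ellipsoid trunk and skull, a strongly curved neck
#'   (120 deg arc), two three-part cylindrical legs.
#'
#' Doubling `scale` scales every linear dimension by 2 and every truth
#' volume by 8.
#'
#' @param template `"quadruped"` or `"biped_bird"`.
#' @param scale trunk length in metres (> 0).
#' @param seed integer RNG seed.
#' @param n_points_trunk,n_points_other per-segment surface point counts.
#' @param reference_points grid size for curved-tube reference volumes.
#' @return List with `skeleton` (a [skeleton_model()]) and `truth`
#'   (data.frame `segment`, `volume`; `total` in the attribute is the sum).
#' @export
generate_skeleton <- function(template = c("quadruped", "biped_bird"),
                              scale = 1, seed = 1,
                              n_points_trunk = 6000L,
                              n_points_other = 3000L,
                              reference_points = 2e5) {
  template <- match.arg(template)
  if (scale <= 0) stop("scale must be > 0")
  t <- scale
  spec <- if (template == "quadruped") {
    list(
      trunk = list(kind = "ellipsoid_surface", size = t * c(0.50, 0.20, 0.28)),
      skull = list(kind = "ellipsoid_surface", size = t * c(0.16, 0.09, 0.10)),
      neck = list(kind = "curved_tube", radius = 0.08 * t, length = 0.45 * t,
                  arc_angle_deg = 60),
      fore_upper_L = list(kind = "cylinder", radius = 0.05 * t, length = 0.35 * t),
      fore_lower_L = list(kind = "cylinder", radius = 0.035 * t, length = 0.32 * t),
      fore_upper_R = list(kind = "cylinder", radius = 0.05 * t, length = 0.35 * t),
      fore_lower_R = list(kind = "cylinder", radius = 0.035 * t, length = 0.32 * t),
      hind_thigh_L = list(kind = "cylinder", radius = 0.06 * t, length = 0.38 * t),
      hind_shank_L = list(kind = "cylinder", radius = 0.04 * t, length = 0.34 * t),
      hind_thigh_R = list(kind = "cylinder", radius = 0.06 * t, length = 0.38 * t),
      hind_shank_R = list(kind = "cylinder", radius = 0.04 * t, length = 0.34 * t))
  } else {
    list(
      trunk = list(kind = "ellipsoid_surface", size = t * c(0.50, 0.24, 0.30)),
      skull = list(kind = "ellipsoid_surface", size = t * c(0.12, 0.06, 0.06)),
      neck = list(kind = "curved_tube", radius = 0.05 * t, length = 0.70 * t,
                  arc_angle_deg = 120),
      thigh_L = list(kind = "cylinder", radius = 0.05 * t, length = 0.30 * t),
      shank_L = list(kind = "cylinder", radius = 0.035 * t, length = 0.40 * t),
      tarsometatarsus_L = list(kind = "cylinder", radius = 0.02 * t, length = 0.30 * t),
      thigh_R = list(kind = "cylinder", radius = 0.05 * t, length = 0.30 * t),
      shank_R = list(kind = "cylinder", radius = 0.035 * t, length = 0.40 * t),
      tarsometatarsus_R = list(kind = "cylinder", radius = 0.02 * t, length = 0.30 * t))
  }
  segs <- vector("list", length(spec))
  truth <- numeric(length(spec))
  offsets <- withr::with_seed(as.integer(seed) + 1L,
                              matrix(runif(3 * length(spec), -2 * t, 2 * t),
                                     ncol = 3))
  for (i in seq_along(spec)) {
    sp <- spec[[i]]
    nm <- names(spec)[i]
    np <- if (nm == "trunk") n_points_trunk else n_points_other
    g <- do.call(generate_segment_cloud,
                 c(list(n_points = np, seed = as.integer(seed) + i,
                        reference_points = reference_points), sp))
    # hull volume is translation invariant, so segment placement is free
    pts <- sweep(g$cloud$points, 2, offsets[i, ], "+")
    segs[[i]] <- segment(nm, pointcloud(pts, label = nm))
    truth[i] <- g$truth$analytic_volume
  }
  tr <- data.frame(segment = names(spec), volume = truth)
  attr(tr, "total") <- sum(truth)
  list(skeleton = skeleton_model(segs, specimen = template), truth = tr)
}

#' Synthetic allometric calibration datasets
#'
#' Draws volumes log-uniformly on `vol_range` and masses from the power law
#' `M = 10^(a + b * log10(V) + e)`, `e ~ Normal(0, sigma^2)` on the log10
#' scale — the generative model the calibration regressions assume.
#'
#' @param a,b intercept (log10 kg at 1 m^3) and slope.
#' @param sigma residual sd on the log10 scale (>= 0).
#' @param n number of records (>= 3).
#' @param vol_range volume range in m^3, `0 < min < max`.
#' @param seed integer RNG seed.
#' @param group group label for the generated rows.
#' @return A `calibration_dataset` with synthetic species names.
#' @export
generate_allometric_dataset <- function(a, b, sigma, n,
                                        vol_range = c(1e-3, 1), seed = 1,
                                        group = "synthetic") {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("n must be >= 3")
  if (sigma < 0) stop("sigma must be >= 0")
  if (length(vol_range) != 2L || vol_range[1] <= 0 ||
      vol_range[2] <= vol_range[1])
    stop("vol_range must satisfy 0 < min < max")
  withr::with_seed(as.integer(seed), {
    lv <- runif(n, log10(vol_range[1]), log10(vol_range[2]))
    eps <- rnorm(n, 0, sigma)
    as_calibration_dataset(data.frame(
      species = sprintf("sp_%03d", seq_len(n)),
      accession = "", sex = "unknown", group = group,
      vol_CH_m3 = 10^lv,
      M_b_kg = 10^(a + b * lv + eps),
      mass_source = "simulated"), label = "synthetic allometric dataset")
  })
}

#' Trees with phylogenetically structured residuals
#'
#' Simulates a Yule (pure-birth) tree rescaled to unit height and a
#' calibration dataset whose log10-mass residuals around a fixed allometric
#' line are multivariate Gaussian with covariance `sigma^2 * C`, where `C`
#' is the identity (`star`), the Brownian-motion matrix (`BM`) or its
#' Ornstein-Uhlenbeck transform (`OU` with parameter `d`). This is the
#' parameter-recovery testbed for the PGLS/OU machinery.
#'
#' @param n_taxa number of tips (>= 5).
#' @param model `"star"`, `"BM"` or `"OU"`.
#' @param sigma residual scale (log10 units).
#' @param seed integer RNG seed.
#' @param d OU parameter, required when `model = "OU"`.
#' @param a,b coefficients of the underlying allometric line.
#' @param vol_range volume range (m^3) for the log-uniform volumes.
#' @return List with `tree` (`ape::phylo`, ultrametric height 1) and
#'   `dataset` (a `calibration_dataset` whose species are the tip labels).
#' @export
generate_tree_and_residuals <- function(n_taxa, model = c("star", "BM", "OU"),
                                        sigma = 0.07, seed = 1, d = NULL,
                                        a = 3, b = 1,
                                        vol_range = c(1e-3, 1)) {
  model <- match.arg(model)
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 5L) stop("n_taxa must be >= 5")
  if (model == "OU") {
    if (is.null(d)) stop("model = 'OU' requires d")
    if (d < 0 || d > 1) stop("d must be in [0, 1]")
  }
  withr::with_seed(as.integer(seed), {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
    C <- switch(model,
      star = diag(n_taxa),
      BM = bm_covariance(tree)$matrix,
      OU = ou_transform(bm_covariance(tree), d)$matrix)
    z <- rnorm(n_taxa)
    eps <- sigma * drop(t(chol(C + diag(1e-12, n_taxa))) %*% z)
    lv <- runif(n_taxa, log10(vol_range[1]), log10(vol_range[2]))
    ds <- as_calibration_dataset(data.frame(
      species = tree$tip.label,
      accession = "", sex = "unknown", group = "synthetic",
      vol_CH_m3 = 10^lv,
      M_b_kg = 10^(a + b * lv + eps),
      mass_source = "simulated"), label = paste("synthetic", model))
    list(tree = tree, dataset = ds)
  })
}
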