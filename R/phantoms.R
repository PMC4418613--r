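# Digital tumor phantoms: rasterized spheres/ellipsoids with optional
# Gaussian radial lobes. They stand in for manually segmented tumors so
# the geometry and the downstream statistics can be exercised end to end.

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# counter-based sub-seed so adding one phantom does not shift the others
sub_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + as.double(counter) * 104729) %%
               2147483629)
}

#' Generate a digital tumor phantom
#'
#' Rasterizes a sphere or ellipsoid (voxel center inside the surface means
#' foreground) on an auto-sized grid with a background margin. The
#' `"lobulated"` kind modulates the base radius with `n_lobes` Gaussian
#' bumps at seeded random directions, each of height
#' `amplitude * base radius` and angular width `lobe_width` radians: the
#' radial surface becomes `r(u) = r_base(u) * (1 + sum_j amplitude *
#' exp(-ang(u, u_j)^2 / (2 lobe_width^2)))`. Because the surface stays
#' star-shaped about the center, the object is always one 26-connected
#' component. `amplitude = 0` reduces exactly to the base shape.
#'
#' @param kind `"sphere"`, `"ellipsoid"` or `"lobulated"`.
#' @param radius sphere radius in voxels (>= 2).
#' @param semi_axes length-3 semi-axes in voxels for ellipsoid/lobulated
#'   kinds; defaults to `rep(radius, 3)`.
#' @param n_lobes number of Gaussian bumps (lobulated kind).
#' @param amplitude bump height as a fraction of the local base radius,
#'   in `[0, 1]`.
#' @param lobe_width angular standard deviation of each bump, radians.
#' @param spacing voxel spacing attached to the result, mm.
#' @param seed integer seed for the bump directions; same seed and spec
#'   give an identical mask.
#' @param margin background margin in voxels (>= 2).
#' @return a [voxel_mask()].
#' @examples
#' make_phantom(kind = "lobulated", radius = 8, n_lobes = 5,
#'              amplitude = 0.4, seed = 7)
#' @export
make_phantom <- function(kind = c("sphere", "ellipsoid", "lobulated"),
                         radius = 10, semi_axes = NULL, n_lobes = 4L,
                         amplitude = 0, lobe_width = 0.5,
                         spacing = c(1, 1, 1), seed = NULL, margin = 2L) {
  kind <- match.arg(kind)
  if (is.null(semi_axes)) semi_axes <- rep(radius, 3)
  semi_axes <- as.numeric(semi_axes)
  stopifnot(length(semi_axes) == 3L, amplitude >= 0, amplitude <= 1,
            margin >= 2L, n_lobes >= 0L)
  if (min(semi_axes) < 2)
    stop("phantom too small: all semi-axes must be >= 2 voxels", call. = FALSE)
  if (kind == "sphere") semi_axes <- rep(radius, 3)
  if (kind != "lobulated") amplitude <- 0
  reach <- semi_axes * (1 + amplitude)
  half <- ceiling(reach) + margin
  dims <- 2L * as.integer(half) + 1L
  c0 <- half + 1L
  x <- array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dims) - c0[1]
  y <- array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
             dims) - c0[2]
  z <- array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims) - c0[3]
  rho <- sqrt((x / semi_axes[1])^2 + (y / semi_axes[2])^2 +
                (z / semi_axes[3])^2)
  mult <- 1
  if (kind == "lobulated" && amplitude > 0 && n_lobes > 0) {
    dirs <- with_seed(seed, {
      v <- matrix(stats::rnorm(3 * n_lobes), ncol = 3)
      v / sqrt(rowSums(v^2))
    })
    r <- sqrt(x^2 + y^2 + z^2)
    r[r == 0] <- 1
    mult <- array(1, dims)
    for (j in seq_len(n_lobes)) {
      cosang <- (x * dirs[j, 1] + y * dirs[j, 2] + z * dirs[j, 3]) / r
      ang <- acos(pmin(pmax(cosang, -1), 1))
      mult <- mult + amplitude * exp(-ang^2 / (2 * lobe_width^2))
    }
  }
  voxel_mask(array(as.integer(rho <= mult), dims), spacing)
}

#' Generate a pair of masks emulating two readers
#'
#' The second mask is the first with a seeded boundary perturbation that
#' mimics how two radiologists disagree: over- or under-inclusion of whole
#' boundary regions rather than independent voxel noise. A smooth random
#' angular field (Gaussian bumps with random signs at seeded directions)
#' is evaluated at every boundary voxel; where the field is positive,
#' background voxels touching the surface are dilated with per-voxel
#' probability proportional to `rater_noise` and the field strength, and
#' where it is negative, surface voxels are eroded likewise. Spatial
#' smoothness of the field keeps the perturbed surface coherent, the way
#' a second reader's contour is. If the perturbation disconnects the
#' object the draw is retried with a new sub-seed (at most 10 attempts).
#'
#' @param ... arguments passed to [make_phantom()].
#' @param rater_noise non-negative perturbation scale (approximate
#'   boundary displacement in voxels); 0 gives identical masks.
#' @param seed integer seed (also forwarded to the base phantom).
#' @return list of two [voxel_mask()] objects.
#' @export
make_phantom_pair <- function(..., rater_noise = 1, seed = NULL) {
  stopifnot(rater_noise >= 0)
  base <- make_phantom(..., seed = seed)
  if (rater_noise == 0) return(list(base, base))
  p <- min(1, 0.6 * rater_noise)
  d <- dim(base$grid)
  pad <- array(0L, d + 2L)
  pad[1:d[1] + 1L, 1:d[2] + 1L, 1:d[3] + 1L] <- base$grid
  nb <- array(0L, d)
  shifts <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                  c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (s in seq_len(6))
    nb <- nb + pad[1:d[1] + 1L + shifts[s, 1],
                   1:d[2] + 1L + shifts[s, 2],
                   1:d[3] + 1L + shifts[s, 3]]
  fg <- base$grid == 1L
  surface <- which(fg & nb < 6L)
  halo <- which(!fg & nb > 0L)
  idx <- arrayInd(c(surface, halo), d)
  centroid <- colMeans(arrayInd(which(fg), d))
  rel <- sweep(idx, 2, centroid)
  rn <- sqrt(rowSums(rel^2)); rn[rn == 0] <- 1
  u <- rel / rn
  for (attempt in 1:10) {
    g2 <- with_seed(sub_seed(if (is.null(seed)) 0L else seed, attempt), {
      dirs <- matrix(stats::rnorm(3 * 6), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      signs <- sample(c(-1, 1), 6, replace = TRUE)
      field <- rep(0, nrow(u))
      for (j in 1:6) {
        ang <- acos(pmin(pmax(u %*% dirs[j, ], -1), 1))
        field <- field + signs[j] * exp(-ang^2 / (2 * 0.4^2))
      }
      n_surf <- length(surface)
      p_vox <- p * pmin(1, abs(field))
      g <- base$grid
      er <- field[seq_len(n_surf)] < 0 &
        stats::runif(n_surf) < p_vox[seq_len(n_surf)]
      di <- field[-seq_len(n_surf)] > 0 &
        stats::runif(length(halo)) < p_vox[-seq_len(n_surf)]
      g[surface[er]] <- 0L
      g[halo[di]] <- 1L
      g
    })
    if (sum(g2) == 0L) next
    m2 <- voxel_mask(g2, base$spacing, base$origin)
    if (max(label_components(m2$grid)) == 1L) return(list(base, m2))
  }
  warning("perturbed mask stayed disconnected after 10 attempts; ",
          "keeping largest component", call. = FALSE)
  list(base, suppressWarnings(largest_component(m2)))
}

#' Simulate a two-class phantom cohort
#'
#' Generates `n_enc` low-lobulation ("encapsulated") and `n_inv`
#' high-lobulation ("invasive") phantoms whose amplitude difference is
#' `lobulation_gap`. Radii and mild ellipsoidal anisotropy are drawn per
#' subject; with a sizeable gap, discrete compactness separates the two
#' classes, mirroring the smooth-versus-lobulated contour contrast between
#' encapsulated and invasive tumors.
#'
#' @param n_enc,n_inv class sizes.
#' @param lobulation_gap amplitude difference between classes, in `[0, 1]`.
#' @param seed master integer seed; per-phantom sub-seeds are counter-based.
#' @param radius_range range of base radii in voxels.
#' @param base_amplitude lobulation amplitude of the encapsulated class.
#' @param n_lobes number of lobes per phantom; many narrow lobes roughen
#'   the surface, which is what depresses discrete compactness.
#' @param lobe_width angular width of each lobe in radians.
#' @return list with `masks` (list of [voxel_mask()]), `labels`
#'   (0 = encapsulated, 1 = invasive) and `subject_id`.
#' @export
simulate_phantom_cohort <- function(n_enc = 20L, n_inv = 20L,
                                    lobulation_gap = 0.4, seed = 1L,
                                    radius_range = c(7, 11),
                                    base_amplitude = 0.05, n_lobes = 10L,
                                    lobe_width = 0.25) {
  stopifnot(n_enc >= 1L, n_inv >= 1L,
            lobulation_gap >= 0, lobulation_gap <= 1)
  n <- n_enc + n_inv
  labels <- rep(c(0L, 1L), c(n_enc, n_inv))
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    si <- sub_seed(seed, i)
    geom <- with_seed(si, list(
      radius = stats::runif(1, radius_range[1], radius_range[2]),
      aniso = stats::runif(3, 0.85, 1.15)
    ))
    amp <- base_amplitude + if (labels[i] == 1L) lobulation_gap else 0
    masks[[i]] <- make_phantom(
      kind = "lobulated", radius = geom$radius,
      semi_axes = geom$radius * geom$aniso,
      n_lobes = n_lobes, amplitude = min(amp, 1), lobe_width = lobe_width,
      seed = sub_seed(seed, i + n))
  }
  list(masks = masks, labels = labels,
       subject_id = sprintf("P%03d", seq_len(n)))
}
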