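#' Rendering specification for a synthetic pinned plate
#'
#' Describes the pinning geometry and imaging model used by [render_plate()]
#' and [simulate_screen()]. Defaults emulate a 384-pin (16 x 24) array
#' photographed with a commodity camera: neutral agar background with a gentle
#' linear gradient and radial vignette, i.i.d. sensor noise, and colonies
#' rendered as bright discs whose red pigment accumulates linearly with
#' incubation time and diffuses outward as a Gaussian halo.
#'
#' @param rows,cols Grid dimensions. Standard formats are 96 (8 x 12),
#'   384 (16 x 24) and 1536 (32 x 48); other products are allowed with a
#'   warning.
#' @param pin_spacing Pin-to-pin distance in pixels.
#' @param margin Margin between the outermost pin centre and the image edge
#'   (in addition to the maximum colony radius), in pixels.
#' @param colony_radius_mean,colony_radius_sd Colony radius distribution
#'   (pixels).
#' @param position_jitter_sd Standard deviation of the isotropic Gaussian
#'   jitter of each colony centre around its pin position (pixels).
#' @param background_level Mean agar intensity on a 0-1 scale.
#' @param background_gradient Linear intensity change per pixel along x.
#' @param vignette_strength Peak relative darkening at the image corners (0-1).
#' @param noise_sd Standard deviation of i.i.d. Gaussian sensor noise per
#'   channel (0-1 intensity scale).
#' @param halo_diffusion_sigma_per_hour Growth rate of the halo's Gaussian
#'   width: at elapsed time `t` hours the halo decays with sigma =
#'   `halo_diffusion_sigma_per_hour * t` pixels beyond the colony rim.
#' @param seed Integer master seed; all randomness in rendering flows from it
#'   through per-plate substreams, so identical specs reproduce images
#'   bit-for-bit.
#'
#' @return An object of class `plate_spec` (a validated list).
#' @export
plate_spec <- function(rows = 16L, cols = 24L,
                       pin_spacing = 20, margin = 16,
                       colony_radius_mean = 6, colony_radius_sd = 0.5,
                       position_jitter_sd = 1,
                       background_level = 0.55,
                       background_gradient = 2e-4,
                       vignette_strength = 0.08,
                       noise_sd = 0.01,
                       halo_diffusion_sigma_per_hour = 0.2,
                       seed = 1L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) abort("`rows` and `cols` must be >= 1")
  if (!(rows * cols) %in% c(96L, 384L, 1536L)) {
    warn(sprintf("non-standard plate format: %d x %d = %d positions (standard: 96, 384, 1536)",
                 rows, cols, rows * cols))
  }
  for (nm in c("pin_spacing", "margin", "colony_radius_mean", "colony_radius_sd",
               "position_jitter_sd", "background_level", "background_gradient",
               "vignette_strength", "noise_sd", "halo_diffusion_sigma_per_hour")) {
    stop_if_not_scalar_number(get(nm), nm, min = 0)
  }
  spec <- structure(list(
    rows = rows, cols = cols, pin_spacing = pin_spacing, margin = margin,
    colony_radius_mean = colony_radius_mean, colony_radius_sd = colony_radius_sd,
    position_jitter_sd = position_jitter_sd,
    background_level = background_level,
    background_gradient = background_gradient,
    vignette_strength = vignette_strength,
    noise_sd = noise_sd,
    halo_diffusion_sigma_per_hour = halo_diffusion_sigma_per_hour,
    seed = as.integer(seed)
  ), class = "plate_spec")
  spec
}

# Maximum radius budgeted in the canvas; image dimensions are deterministic
# in the spec alone (not in the realised radii).
spec_max_radius <- function(spec) {
  ceiling(spec$colony_radius_mean + 4 * spec$colony_radius_sd)
}

#' Image dimensions implied by a plate specification
#'
#' Height and width are `2 * margin + pin_spacing * (dim - 1) + 2 * rmax`
#' per axis, where `rmax` is the largest radius budgeted by the spec.
#'
#' @param spec A [plate_spec()].
#' @return Named integer vector `c(height =, width =)`.
#' @export
plate_dims <- function(spec) {
  rmax <- spec_max_radius(spec)
  c(height = as.integer(2 * spec$margin + spec$pin_spacing * (spec$rows - 1) + 2 * rmax),
    width  = as.integer(2 * spec$margin + spec$pin_spacing * (spec$cols - 1) + 2 * rmax))
}

# Analytic (unjittered) pin-centre coordinates, 1-based pixel coordinates,
# row index -> y (first array dimension), col index -> x.
pin_centers <- function(spec) {
  rmax <- spec_max_radius(spec)
  off <- spec$margin + rmax
  list(y = off + spec$pin_spacing * seq(0L, spec$rows - 1L),
       x = off + spec$pin_spacing * seq(0L, spec$cols - 1L))
}

#' @export
print.plate_spec <- function(x, ...) {
  d <- plate_dims(x)
  cat(sprintf("<plate_spec> %d x %d (%d positions), %d x %d px, spacing %g px, seed %d\n",
              x$rows, x$cols, x$rows * x$cols, d["height"], d["width"],
              x$pin_spacing, x$seed))
  invisible(x)
}

#' Simulation specification for genetic-interaction colony sizes
#'
#' Generative model for double-mutant colony sizes on pinned plates:
#' `size(gene, rep) = base_size * gene_fitness[gene] * interaction[gene] *
#' exp(N(0, plate_effect_sd^2)) * exp(N(0, noise_sd^2))`, where the plate
#' effect is shared by all colonies on a replicate plate. Under this model the
#' expected growth score of a neutral gene (all multipliers 1) is 1.
#'
#' @param base_size Reference colony size (pixels^2 or arbitrary size units);
#'   must be positive.
#' @param gene_fitness Named numeric vector of per-gene fitness multipliers
#'   (default 1 for genes not named).
#' @param interaction Named numeric vector of per-gene interaction multipliers
#'   (1 = neutral, > 1 suppressive, < 1 negative).
#' @param plate_effect_sd,noise_sd Log-scale standard deviations of the shared
#'   plate effect and the per-colony noise.
#' @param replicates Number of replicate plates per gene.
#' @param seed Integer master seed.
#' @return An object of class `gi_sim_spec`.
#' @export
gi_sim_spec <- function(base_size = 400,
                        gene_fitness = numeric(),
                        interaction = numeric(),
                        plate_effect_sd = 0.2,
                        noise_sd = 0.1,
                        replicates = 4L,
                        seed = 1L) {
  if (!is.numeric(base_size) || length(base_size) != 1L || base_size <= 0) {
    abort("`base_size` must be a single positive number")
  }
  if (length(gene_fitness) && any(gene_fitness <= 0)) abort("all `gene_fitness` multipliers must be > 0")
  if (length(interaction) && any(interaction <= 0)) abort("all `interaction` multipliers must be > 0")
  stop_if_not_scalar_number(plate_effect_sd, "plate_effect_sd", min = 0)
  stop_if_not_scalar_number(noise_sd, "noise_sd", min = 0)
  structure(list(
    base_size = base_size,
    gene_fitness = gene_fitness,
    interaction = interaction,
    plate_effect_sd = plate_effect_sd,
    noise_sd = noise_sd,
    replicates = as.integer(replicates),
    seed = as.integer(seed)
  ), class = "gi_sim_spec")
}
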