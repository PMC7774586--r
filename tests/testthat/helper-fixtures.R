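# Shared fixtures, built once per test run. Phantom geometry computations are
# cached because several test files exercise the same canonical phantoms.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# canonical noise-free phantoms with their laminar geometry
slab_case <- function() fixture("slab", function() {
  ph <- make_phantom(phantom_spec("slab", noise_sd = 0))
  geo <- suppressMessages(laminar_geometry(ph$labels))
  list(ph = ph, geo = geo)
})

shell_case <- function() fixture("shell", function() {
  ph <- make_phantom(phantom_spec("shell", noise_sd = 0))
  geo <- suppressMessages(laminar_geometry(ph$labels))
  list(ph = ph, geo = geo)
})

folded_case <- function() fixture("folded", function() {
  ph <- make_phantom(phantom_spec("folded", noise_sd = 0))
  geo <- suppressMessages(laminar_geometry(ph$labels))
  list(ph = ph, geo = geo)
})

# 16-ROI atlas metadata (4 lobes x 2 hemispheres x 2), for table-level
# simulations
meta16 <- function() {
  g <- expand.grid(hemi = c("lh", "rh"),
                   lobe = c("frontal", "parietal", "temporal", "occipital"),
                   i = 1:2, stringsAsFactors = FALSE)
  data.frame(roi_id = paste(g$hemi, g$lobe, g$i, sep = "_"),
             name = paste(g$lobe, g$i),
             hemisphere = ifelse(g$hemi == "lh", "left", "right"),
             lobe = g$lobe, stringsAsFactors = FALSE)
}

# cohort spec used by the calibration / power simulations
calib_cohort <- function(seed, n = 20, effect = NULL) {
  cohort_spec(n_per_group = c(control = n, CHR = n, `CHR-negative` = n),
              effect_by_lobe = effect,
              random_intercept_sd = 0.3, residual_sd = 0.5, seed = seed)
}

# world radius of every voxel of a volume grid
voxel_radius <- function(vg) {
  w <- laminargm:::grid_world(vg)
  sqrt(w$x^2 + w$y^2 + w$z^2)
}
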