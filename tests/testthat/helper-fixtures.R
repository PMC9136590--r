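# Small plates (256 px, radius 100) keep unit tests fast; acceptance
# checks run at the full default scale.
small_spec <- function(seed = 1L,
                       worms_per_quadrant = c(6L, 2L, 6L, 2L),
                       worm_area_px = 60,
                       center_worms = 3L,
                       debris_count = 2L,
                       noise_sd = 0.02,
                       vignette_strength = 0.3,
                       foreground_polarity = "dark_on_light",
                       spot_ring = NULL,
                       plate_center = c(128, 128),
                       plate_radius = 100) {
  synthetic_plate_spec(
    image_size = 256L, plate_center = plate_center,
    plate_radius = plate_radius,
    foreground_polarity = foreground_polarity,
    worms_per_quadrant = worms_per_quadrant,
    worm_area_px = worm_area_px, center_worms = center_worms,
    debris_count = debris_count, spot_ring = spot_ring,
    vignette_strength = vignette_strength, noise_sd = noise_sd,
    seed = seed)
}

small_config <- function(...) {
  ct_config(expected_worm_area_px = 60, ...)
}

# quadrant_areas-like list for direct CI arithmetic
areas_list <- function(q1, q2, q3, q4, center = 0L) {
  list(q1 = q1, q2 = q2, q3 = q3, q4 = q4, center_px = center)
}
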