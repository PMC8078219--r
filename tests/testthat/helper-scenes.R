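# Shared small synthetic scenes (kept well below the default preset so the
# unit suite stays fast).

two_pop <- function(sd = 10) list(
  list(label = "T", fraction = 0.5,
       membrane = c(Ki67 = 0, LB = 30, LT = 180, Phago = 0, CD69 = 60, DAPI = 0),
       sd = sd),
  list(label = "B", fraction = 0.5,
       membrane = c(Ki67 = 0, LB = 180, LT = 30, Phago = 0, CD69 = 0, DAPI = 0),
       sd = sd))

small_scene <- function(n = 16, noise_sd = 5, sd = 10, seed = 11,
                        contacts_fraction = 0.25, cluster_fraction = 0.5,
                        image = c(X = 420, Y = 420), n_slices = 8) {
  scene_spec(
    n_cells = n, image_size = image, n_slices = n_slices,
    populations = two_pop(sd),
    cluster = list(fraction = cluster_fraction, spacing = 26, jitter = 1,
                   clearance = 56),
    contacts = list(fraction = contacts_fraction, blob_radius = 2,
                    partner_channel = "Phago", value = 200, threshold = 80,
                    contact_dist = 2),
    noise_sd = noise_sd, seed = seed)
}

# A sparse-only scene for measurement tests: no dense region, looser packing.
measure_scene <- function(n = 50, noise_sd = 0, sd = 0, seed = 5,
                          image = c(X = 700, Y = 700)) {
  scene_spec(
    n_cells = n, image_size = image, n_slices = 8,
    populations = two_pop(sd),
    cluster = list(fraction = 0, spacing = 26, jitter = 1, clearance = 26),
    contacts = list(fraction = 0, blob_radius = 2, partner_channel = "Phago",
                    value = 200, threshold = 80, contact_dist = 2),
    noise_sd = noise_sd, seed = seed)
}

# Minimal in-memory stack: uniform or user-supplied channel planes.
uniform_stack <- function(values, h = 40, w = 40, n_slices = 1,
                          labels = paste0("C", seq_along(values))) {
  a <- array(0, dim = c(h, w, length(values), n_slices))
  for (ch in seq_along(values)) a[, , ch, ] <- values[ch]
  image_stack(a, coi_legend(labels), bit_depth = 8)
}
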