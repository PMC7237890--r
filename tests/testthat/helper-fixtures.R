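# Fixtures are generated in code: binary shapes, smooth random textures for
# optical-flow tests, and small geometry/cohort configurations.

make_disc <- function(radius, n = 2 * radius + 21, center = c((n + 1) / 2,
                                                              (n + 1) / 2)) {
  outer(seq_len(n), seq_len(n), function(r, c)
    (r - center[1])^2 + (c - center[2])^2 <= radius^2)
}

make_square <- function(side, pad = 10) {
  n <- side + 2 * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  m
}

# smooth random texture (blurred white noise), values in [0, 1]
make_texture <- function(n, seed = 1, sigma = 3, pad = 0) {
  set.seed(seed)
  m <- matrix(rnorm((n + 2 * pad)^2), n + 2 * pad, n + 2 * pad)
  m <- as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma))
  (m - min(m)) / diff(range(m))
}

# integer circular shift of a matrix: positive dx moves content +x (columns)
shift_image <- function(img, dx, dy) {
  n <- nrow(img); m <- ncol(img)
  rows <- ((seq_len(n) - 1 - dy) %% n) + 1
  cols <- ((seq_len(m) - 1 - dx) %% m) + 1
  img[rows, cols]
}

small_geometry <- function(seed = 2, n_tracks = 4, ...) {
  build_geometry(field_size = c(600, 600), n_tracks = n_tracks,
                 t_zone_radius = 100, seed = seed, ...)
}

# straight radial tracks: distance to the T-zone centre is monotone in arc
straight_geometry <- function(seed = 3, n_tracks = 4,
                              field_size = c(1000, 1000)) {
  build_geometry(field_size = field_size, n_tracks = n_tracks,
                 angle_jitter_sd = 0, seed = seed)
}

# one long horizontal vessel through the field, T zone at the right end
vessel_scene <- function(field = c(1000, 250), pixel_size = 1,
                         half_width = 25) {
  poly <- cbind(c(40, field[1] - 120), c(field[2] / 2, field[2] / 2))
  mask <- perivax:::rasterize_tube(poly, half_width, field, pixel_size)
  geom <- structure(list(
    t_zone_center = c(field[1] - 60, field[2] / 2),
    t_zone_radius = 50,
    tracks = list(poly),
    track_half_width = half_width,
    vessel_masks = list(mask),
    branch_junctions = matrix(numeric(0), ncol = 2),
    field_size = field,
    pixel_size = pixel_size), class = "perivax_geometry")
  geom
}
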