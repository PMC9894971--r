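# shared fixture builders; everything is generated in code at test time

# voxelized homogeneous ball: radius R mm, attenuation mu, cubic grid of
# n voxels spanning `extent` mm, centred
fix_ball_attenuation <- function(n, R = 10, mu = 0.1, extent = 32) {
  vs <- extent / n
  cx <- (seq_len(n) - 0.5) * vs - extent / 2
  r2 <- outer(outer(cx^2, cx^2, "+"), cx^2, "+")
  attenuation_volume(array(mu * (r2 <= R^2), c(n, n, n)), vs)
}

# all-clay cube with a centred spherical stone (radius in voxels)
fix_stone_in_clay <- function(n = 64, stone_r = 10) {
  g <- array(1L, c(n, n, n))
  cx <- seq_len(n) - 0.5 - n / 2
  r2 <- outer(outer(cx^2, cx^2, "+"), cx^2, "+")
  g[r2 <= stone_r^2] <- 2L
  labeled_volume(g, 1, c("0" = "exterior", "1" = "clay", "2" = "stone"))
}

# two-material ball phantom converted to attenuation for round trips
fix_two_material <- function(n = 48, mu = c(sphere = 0.1, ball = 1.0)) {
  vol <- make_ball_phantom(ball_phantom_config(0.4, c(0.2, 0, 0)), n,
                           voxel_size = 2 / n)
  mats <- material_table(exterior = 0, sphere = mu[["sphere"]],
                         ball = mu[["ball"]])
  list(vol = vol, mats = mats, att = labels_to_attenuation(vol, mats))
}

fix_clay <- function(n_stones = 1, seed = 1, shape = 48) {
  make_phantom(phantom_spec("clay", shape, n_foreign_objects = n_stones,
                            seed = seed))
}

fix_avocado <- function(air = 0.02, seed = 1, shape = 48) {
  make_phantom(phantom_spec("avocado", shape, air_fraction = air,
                            seed = seed))
}

# small projection geometry whose pixel pitch is incommensurate with the
# fixture voxel grids (avoids rays lying exactly on voxel faces)
fix_geom <- function(n_angles = 2, det = 75, ps = 0.39) {
  proj_geometry("parallel", n_angles = n_angles, det_rows = det,
                det_cols = det, pixel_size = ps)
}
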