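# shared fixture builders; everything is generated in code, seeded

# small random non-negative volume
rand_volume <- function(d = c(8, 8, 8), seed = 1, spacing = c(1, 1, 1),
                        lo = 0, hi = 100) {
  set.seed(seed)
  new_volume(array(runif(prod(d), lo, hi), d), spacing)
}

# centered solid ball mask of given radius (voxels)
ball_mask <- function(d = c(32, 32, 32), radius = 10, spacing = c(1, 1, 1)) {
  ctr <- (d - 1) / 2
  idx <- arrayInd(seq_len(prod(d)), d) - 1
  r2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2
  new_mask(array(as.numeric(r2 <= radius^2), d), spacing)
}

# brute-force similarity oracle (triple loop; deliberately naive)
similarity_oracle <- function(a, b) {
  d <- dim(a$data)
  num <- 0; sa <- 0; sb <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    x <- a$data[i, j, k]; y <- b$data[i, j, k]
    num <- num + x * y; sa <- sa + x^2; sb <- sb + y^2
  }
  num / sqrt(sa * sb)
}

# brute-force metric oracles (triple loop)
ssd_oracle <- function(a, b) {
  d <- dim(a$data); acc <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    acc <- acc + (a$data[i, j, k] - b$data[i, j, k])^2
  acc / prod(d)
}

ncc_oracle <- function(a, b) {
  d <- dim(a$data)
  n <- prod(d)
  ma <- sum(a$data) / n; mb <- sum(b$data) / n
  num <- 0; va <- 0; vb <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    x <- a$data[i, j, k] - ma; y <- b$data[i, j, k] - mb
    num <- num + x * y; va <- va + x^2; vb <- vb + y^2
  }
  (num / (n - 1)) / sqrt(va / (n - 1)) / sqrt(vb / (n - 1))
}

# small fast phantom for registration tests; smaller grids keep the same
# ~96 mm field of view with coarser voxels and a slightly smaller head
test_phantom <- function(seed = 7, grid = 48, preset = "20w") {
  if (grid >= 48) {
    spec <- phantom_spec(preset, seed = seed, grid_shape = rep(grid, 3))
  } else {
    spec <- phantom_spec(preset, seed = seed, grid_shape = rep(grid, 3),
                         spacing = rep(96 / grid, 3),
                         semi_axes = c(26, 33, 28) * 0.85)
  }
  make_head_phantom(spec)
}

euler_matrix <- fetalicv:::euler_matrix

# reduced-size registration parameter helper
fast_params <- function(family, seed = 3, ...) {
  args <- modifyList(list(family = family, pyramid_schedule = c(2, 0),
                          max_iterations = 60L, max_samples = 6000L,
                          seed = seed),
                     list(...))
  do.call(registration_params, args)
}

world_center <- function(v) v$origin + v$spacing * (dim(v$data) - 1) / 2

# geometry helpers mirroring the package's 0-based voxel-to-world convention
world_bbox_test <- function(geom) {
  list(lo = geom$origin, hi = geom$origin + geom$spacing * (geom$dim - 1))
}

voxel_centers_test <- function(geom) {
  idx <- arrayInd(seq_len(prod(geom$dim)), geom$dim) - 1
  rbind(geom$origin[1] + geom$spacing[1] * idx[, 1],
        geom$origin[2] + geom$spacing[2] * idx[, 2],
        geom$origin[3] + geom$spacing[3] * idx[, 3])
}
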