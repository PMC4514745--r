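# Shared fixture builders (everything generated in code, nothing on disk).

# occurrence data.frame in planar km
make_records <- function(species, x, y, catalog = NULL) {
  df <- data.frame(
    species_id = species, x = x, y = y,
    catalog_id = if (is.null(catalog)) sprintf("c%03d", seq_along(x))
                 else catalog,
    year = 2010, stringsAsFactors = FALSE)
  attr(df, "coord_mode") <- "planar"
  df
}

# training set built directly from a feature table (bypasses raster plumbing)
make_training <- function(features, label, species = "sp") {
  label <- factor(label, levels = c("absence", "presence"))
  structure(list(species_id = species, features = features, label = label,
                 coords = NULL,
                 n_presence = sum(label == "presence"),
                 n_absence = sum(label == "absence")),
            class = "training_set")
}

# linearly separable training set: presence covariates in [0,1],
# absence covariates in [2,3] on the first feature, noise elsewhere
make_separable_training <- function(n = 150, n_noise = 2, seed = 42) {
  set.seed(seed)
  feats <- data.frame(driver = c(runif(n, 0, 1), runif(n, 2, 3)))
  for (k in seq_len(n_noise)) feats[[paste0("noise", k)]] <- runif(2 * n)
  make_training(feats, rep(c("presence", "absence"), each = n))
}

# one-layer stack whose values are a pure north-south gradient
make_gradient_stack <- function(nx = 20, ny = 20, res = 1, slice = "t0",
                                temporal = "dynamic") {
  vals <- matrix(rep(seq_len(ny), nx), ny, nx)
  covariate_stack(list(grad = sdm_grid(vals, res = res)),
                  temporal = temporal, time_slice = slice)
}

# binary range from a 0/1 matrix (rows south to north)
make_range <- function(m, species = "sp", slice = "t0", res = 1) {
  binarize(rio_surface(sdm_grid(m, res = res), species, slice),
           threshold = 0.5)
}

random_binary_matrix <- function(ny, nx, p = 0.5) {
  matrix(rbinom(ny * nx, 1, p), ny, nx)
}

# smooth RIO surface in [0,1] from a low-frequency field
make_smooth_rio <- function(nx, ny, wx, wy, phase = 0, species = "sp",
                            slice = "t0") {
  xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ys <- matrix(seq_len(ny), ny, nx)
  v <- (sin(2 * pi * (xs / wx) + phase) + cos(2 * pi * (ys / wy)) + 2) / 4
  rio_surface(sdm_grid(v), species, slice)
}
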