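# Shared fixtures: toy patch sets with class-separable intensities, reduced
# network specs, independent brute-force oracles, and a memoised pair of
# trained toy networks reused across end-to-end tests.

# class-separable patch set: class k has mean intensity base + k * step
make_intensity_patches <- function(n_per, n_classes = 2L, ps = 25L, seed = 1,
                                   base = 60, step = 120, sd = 25) {
  set.seed(seed)
  n <- n_per * n_classes
  patches <- array(0, dim = c(ps, ps, n))
  labels <- integer(n)
  for (i in seq_len(n)) {
    cl <- (i - 1L) %% n_classes
    mu <- base + cl * step / max(1L, n_classes - 1L)
    patches[, , i] <- matrix(pmin(pmax(stats::rnorm(ps * ps, mu, sd), 0), 255),
                             ps, ps)
    labels[i] <- cl
  }
  structure(list(patches = patches, labels = labels,
                 centers = cbind(seq_len(n), 1L),
                 classes = seq_len(n_classes) - 1L, per_class = n_per,
                 patch_size = ps, seed = seed),
            class = "patch_dataset")
}

# reduced network spec sharing the canonical 4-conv + 3-FC topology
small_spec <- function(variant, ps = 25L, n_classes = NULL) {
  if (is.null(n_classes)) n_classes <- if (variant == "object") 4L else 2L
  network_spec(variant, input_size = ps,
               conv_filters = c(8L, 12L, 16L, 16L),
               conv_kernels = c(5L, 3L, 3L, 1L),
               fc_units = c(32L, 16L), n_classes = n_classes)
}

# raw enumeration of the discrete binary TV energy minimum; independent of
# both the primal-dual solver and the dynamic-programming oracle
brute_force_tv_min <- function(g, w, lambda, tv_norm = "anisotropic") {
  n <- length(g)
  best <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- matrix(as.integer(bitwAnd(code, 2^(0:(n - 1))) > 0),
                  nrow(g), ncol(g))
    e <- tv_energy(lab, g, w, lambda, tv_norm)
    if (e < best) best <- e
  }
  best
}

# plain O(n^2) directed Hausdorff oracle on coordinate matrices
brute_hausdorff <- function(A, B) {
  d_ab <- max(apply(A, 1L, function(p) min(sqrt((B[, 1] - p[1])^2 + (B[, 2] - p[2])^2))))
  d_ba <- max(apply(B, 1L, function(p) min(sqrt((A[, 1] - p[1])^2 + (A[, 2] - p[2])^2))))
  max(d_ab, d_ba)
}

half_channel_of <- function(scene) {
  resample(apply_clahe(structure_channel(color_deconvolve(scene$image))),
           0.5, mode = "area")
}

sample_scene_patches <- function(scene, n, seed, ps = 25L) {
  ch <- half_channel_of(scene)
  lab4 <- transform_labels(resample(scene$labels, 0.5, mode = "nearest"),
                           scene$malignant)
  sample_balanced_patches(ch, lab4, per_class = n, patch_size = ps, seed = seed)
}

# toy object + separator networks trained on synthetic scenes; trained once
# per test run and cached
.toy_net_cache <- new.env(parent = emptyenv())
get_toy_nets <- function() {
  if (!is.null(.toy_net_cache$nets)) return(.toy_net_cache$nets)
  ps <- 25L
  # toy runs use a slightly hotter learning rate and lighter weight decay
  # than the full-scale schedule so the small nets sharpen within minutes
  cfg <- train_config(eta0 = 0.005, weight_decay = 0.001, batch_size = 30L,
                      max_epochs = 45L, patience = 15L, seed = 9)

  # object net: two scenes per condition for within-class variety
  tr <- combine_patch_datasets(
    sample_scene_patches(generate_scene(scene_config(seed = 21)), 100, 1),
    sample_scene_patches(generate_scene(scene_config(seed = 27)), 100, 11),
    sample_scene_patches(generate_scene(scene_config(seed = 22, malignant = TRUE)), 100, 2),
    sample_scene_patches(generate_scene(scene_config(seed = 28, malignant = TRUE)), 100, 12))
  va <- combine_patch_datasets(
    sample_scene_patches(generate_scene(scene_config(seed = 29)), 30, 3),
    sample_scene_patches(generate_scene(scene_config(seed = 30, malignant = TRUE)), 30, 4))
  net_obj <- train_network(small_spec("object", ps), tr, va, cfg)

  # separator net: positives from touching scenes, extra negatives from
  # plain scenes so it does not fire on ordinary stroma or gland interiors
  sep_set <- function(scene_seed, n, sample_seed) {
    st <- generate_scene(scene_config(seed = scene_seed, touching_fraction = 1,
                                      touch_gap = 3))
    ch_t <- half_channel_of(st)
    sep_half <- resample(st$separator, 0.5, mode = "nearest")
    suppressWarnings(sample_balanced_patches(ch_t, sep_half, n,
                                             patch_size = ps,
                                             seed = sample_seed))
  }
  plain_neg <- function(scene_seed, n, sample_seed, malignant = FALSE) {
    st <- generate_scene(scene_config(seed = scene_seed, malignant = malignant))
    ch <- half_channel_of(st)
    sample_balanced_patches(ch, matrix(0L, nrow(ch), ncol(ch)), n,
                            patch_size = ps, seed = sample_seed, classes = 0L)
  }
  trs <- combine_patch_datasets(sep_set(23, 60, 5), sep_set(24, 60, 7),
                                plain_neg(51, 30, 13),
                                plain_neg(52, 30, 14, TRUE))
  vas <- combine_patch_datasets(sep_set(25, 20, 6), sep_set(26, 20, 8))
  net_sep <- train_network(small_spec("separator", ps), trs, vas, cfg)
  .toy_net_cache$nets <- list(object = net_obj, separator = net_sep)
  .toy_net_cache$nets
}
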