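# Shared fixtures, computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small noiseless scene used by correction/segmentation/feature tests.
tiny_scene <- function(alpha = 0, rho = 0, seed = 5, n = 20, size = 256) {
  ref <- reference_cell_types()
  make_scene(n, ref$type_specs, mixing = ref$mixing,
             params = synthetic_params(seed = seed, image_size = size,
                                       vignette_alpha = alpha,
                                       bleach_residual = rho,
                                       poisson_noise = FALSE,
                                       read_noise_sd = 0,
                                       unspecific_sigma = 0),
             panel = ref$panel)
}

# Full-artifact reference fixture run through the whole pipeline once.
easy_fixture <- function() {
  cached("easy", {
    scene <- easy_scene(seed = 0)
    run <- render_run(scene)
    result <- run_pipeline(run, config = list(
      normalization = list(exclusive_pairs = c(GD2 = "CD45", CD45 = "GD2"))))
    list(scene = scene, run = run, result = result)
  })
}

# Naive per-pixel reference implementations (independent oracles).
oracle_perimeter <- function(mask) {
  d <- dim(mask)
  per <- 0L
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    if (!mask[y, x]) next
    for (nb in list(c(y - 1, x), c(y + 1, x), c(y, x - 1), c(y, x + 1))) {
      if (nb[1] < 1 || nb[1] > d[1] || nb[2] < 1 || nb[2] > d[2] ||
          !mask[nb[1], nb[2]]) {
        per <- per + 1L
      }
    }
  }
  per
}

oracle_intensity <- function(channel, idx) {
  if (!length(idx)) return(c(ME = 0, TO = 0, M20 = 0))
  v <- channel[idx]
  k <- max(1, ceiling(0.2 * length(v)))
  c(ME = mean(v), TO = sum(v), M20 = mean(rev(sort(v))[1:k]))
}

# Minimal hand-built feature table: two markers (A with NC channel "NCA",
# B as A's exclusive counterpart), planted positive/negative populations.
fake_table <- function(n, sample_id = "s1", fov_id = "f1", seed = 1,
                       a_pos_mean = 100, a_neg_mean = 10, frac_pos = 0.5) {
  set.seed(seed)
  pos <- seq_len(n) <= round(frac_pos * n)
  tab <- data.frame(sample_id = sample_id, fov_id = fov_id,
                    cell_id = seq_len(n), cell_label = seq_len(n),
                    nucleus_label = seq_len(n), cyto_empty = FALSE)
  for (s in melcpipe:::stat_suffixes()) {
    tab[[paste0("A_", s)]] <- ifelse(pos, rnorm(n, a_pos_mean, 5),
                                     rnorm(n, a_neg_mean, 1))
    tab[[paste0("B_", s)]] <- ifelse(pos, rnorm(n, 8, 1), rnorm(n, 90, 5))
    tab[[paste0("NCA_", s)]] <- 2
  }
  attr(tab, "positive") <- pos
  class(tab) <- c("feature_table", "data.frame")
  tab
}

random_blob_mask <- function(size, n_blobs, seed) {
  set.seed(seed)
  mask <- matrix(0L, size, size)
  for (b in seq_len(n_blobs)) {
    cx <- runif(1, 4, size - 3); cy <- runif(1, 4, size - 3)
    r <- runif(1, 1.5, 3.5)
    for (y in seq_len(size)) for (x in seq_len(size)) {
      if ((x - cx)^2 + (y - cy)^2 <= r^2 && mask[y, x] == 0) mask[y, x] <- b
    }
  }
  mask
}
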