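# Generators: composition arithmetic, determinism, capture outcomes, traces,
# image-pair conservation.

test_that("cluster compositions obey copy_number = monomers + K * oligomers", {
  for (K in c(1L, 3L, 6L)) {
    cfg <- synthetic_config(seed = 10 + K, K = K, n_clusters = 2000)
    cl <- simulate_cluster_compositions(cfg)
    expect_equal(cl$copy_number, cl$true_monomers + K * cl$true_oligomers)
    expect_identical(cl$observable, cl$copy_number >= 1L)
  }
})

test_that("degenerate mixtures collapse to the expected marginals", {
  # no monomers: every copy number is a multiple of K
  cl <- simulate_cluster_compositions(
    synthetic_config(seed = 3, K = 3, monomer_mean = 0, n_clusters = 2000))
  expect_true(all(cl$copy_number %% 3 == 0))
  # no oligomers: plain Poisson(monomer_mean) draws
  cl <- simulate_cluster_compositions(
    synthetic_config(seed = 4, K = 3, monomer_mean = 2.2, oligomer_mean = 0,
                     n_clusters = 1e5))
  expect_equal(mean(cl$copy_number), 2.2, tolerance = 3 * sqrt(2.2 / 1e5) / 2.2)
  expect_equal(var(cl$copy_number), 2.2, tolerance = 0.05)
})

test_that("sample mean over all draws approaches monomer_mean + K * oligomer_mean", {
  cfg <- synthetic_config(seed = 5, K = 3, monomer_mean = 2.2,
                          oligomer_mean = 1.4667, n_clusters = 1e5)
  cl <- simulate_cluster_compositions(cfg)
  target <- 2.2 + 3 * 1.4667                    # 6.6001
  se <- sqrt((2.2 + 9 * 1.4667) / 1e5)          # var = m + K^2 k
  expect_lt(abs(mean(cl$copy_number) - target), 3 * se)
})

test_that("identical seeds give identical outputs, different seeds differ", {
  cfg <- synthetic_config(seed = 77, n_clusters = 500,
                          capture_probs = c(0, 0.2, 1))
  a <- simulate_cluster_compositions(cfg)
  b <- simulate_cluster_compositions(cfg)
  expect_identical(a, b)
  expect_identical(simulate_capture_outcomes(a, cfg$capture_probs, 9)$vesicle_bound,
                   simulate_capture_outcomes(a, cfg$capture_probs, 9)$vesicle_bound)
  cfg2 <- synthetic_config(seed = 78, n_clusters = 500)
  expect_false(identical(simulate_cluster_compositions(cfg2)$copy_number,
                         a$copy_number))
  tr <- simulate_bleach_trace(5, seed = 1)
  expect_identical(tr$intensity, simulate_bleach_trace(5, seed = 1)$intensity)
})

test_that("filter_observable drops exactly the zero-copy clusters", {
  cl <- cluster_df(c(0L, 1L, 3L))
  expect_message(out <- filter_observable(cl), "removed 1")
  expect_equal(out$copy_number, c(1L, 3L))
  expect_warning(expect_message(filter_observable(cluster_df(c(0L, 0L)))),
                 "no observable")
  cl2 <- cluster_df(c(2L, 5L))
  expect_identical(filter_observable(cl2), cl2)
})

test_that("capture simulation follows the per-oligomer-count probabilities", {
  cl0 <- cluster_df(rep(2L, 300), true_oligomers = 0L)
  out <- simulate_capture_outcomes(cl0, c(0, 1, 1), seed = 1)
  expect_false(any(out$vesicle_bound))          # p0 = 0 always
  cl1 <- cluster_df(rep(5L, 300), true_oligomers = rep(1:3, 100))
  out <- simulate_capture_outcomes(cl1, c(0, 1, 1), seed = 2)
  expect_true(all(out$vesicle_bound))           # p_n = 1 for n >= 1
  # binomial check at the single-trimer capture probability 0.17
  n <- 1e5
  cl <- cluster_df(rep(3L, n), true_oligomers = 1L)
  out <- simulate_capture_outcomes(cl, c(0, 0.17, 0.55, 1, 1), seed = 3)
  expect_lt(abs(mean(out$vesicle_bound) - 0.17),
            3 * sqrt(0.17 * 0.83 / n))
  # saturation: counts beyond the vector reuse the last entry
  cl6 <- cluster_df(rep(30L, 2000), true_oligomers = 10L)
  out <- simulate_capture_outcomes(cl6, c(0, 0.5, 1), seed = 4)
  expect_true(all(out$vesicle_bound))
})

test_that("capture simulation validates its inputs", {
  cl <- cluster_df(3L)
  expect_error(simulate_capture_outcomes(cl, c(0, 0.5), seed = 1),
               "true_oligomers")
  cl$true_oligomers <- 1L
  expect_error(simulate_capture_outcomes(cl, c(0, 1.5), seed = 1), "\\[0, 1\\]")
  expect_error(simulate_capture_outcomes(cl, c(0.2, 0.5), seed = 1), "p0")
})

test_that("noise-free bleaching traces are exact staircases", {
  tr <- simulate_bleach_trace(4, list(noise_sd = 0, unit_step = 100,
                                      baseline = 7), seed = 21)
  expect_equal(tr$intensity[1], 100 * 4 + 7)    # frame 0 = a N + baseline
  drops <- -diff(tr$intensity)
  drops <- drops[drops > 0]
  expect_true(all(drops %% 100 == 0))           # every drop a multiple of a
  expect_equal(sum(drops) / 100, 4 - tr$survivors[length(tr$survivors)])
  # survivors series matches the intensity exactly
  expect_equal(tr$intensity, 100 * tr$survivors + 7)
})

test_that("ensemble bleaching decay matches a N (1-q)^t", {
  q <- 0.05; n_frames <- 60
  acc <- numeric(n_frames)
  for (s in 1:300) {
    tr <- simulate_bleach_trace(20, list(noise_sd = 0, bleach_prob = q,
                                         n_frames = n_frames), seed = s)
    acc <- acc + tr$intensity
  }
  expected <- 100 * 20 * (1 - q)^(0:(n_frames - 1))
  expect_lt(max(abs(acc / 300 - expected) / expected[1]), 0.02)
})

test_that("generator configuration is validated", {
  expect_error(synthetic_config(seed = 1, K = 0), "K")
  expect_error(synthetic_config(seed = 1, monomer_mean = -1), "monomer_mean")
  expect_error(synthetic_config(), "seed")
  expect_error(synthetic_config(seed = 1, capture_probs = c(0.1, 0.5)), "p0")
  expect_error(simulate_bleach_trace(0, seed = 1), "copy_number")
  expect_error(simulate_bleach_trace(3, list(unit_step = -1), seed = 1), "unit step")
})

test_that("domain image pairs conserve total fluorophore number before quenching", {
  for (E in c(1, 3)) {
    img <- simulate_domain_images(list(size_px = 128, n_domains = 6,
                                       enrichment = E, quench = 0.8), seed = 31)
    expect_equal(sum(img$truth$density_with), sum(img$truth$density_without),
                 tolerance = 1e-12)
    expect_true(all(img$truth$density_with[img$truth$mask] ==
                      E * img$truth$density_without[img$truth$mask]))
    # lipopeptide channel nonzero only inside domains (noise-free, zero bg)
    expect_true(all((img$image_with$peptide > 0) == img$truth$mask))
  }
})

test_that("E = 1 with no quenching gives identical image pairs", {
  img <- simulate_domain_images(list(size_px = 64, n_domains = 3,
                                     enrichment = 1, quench = 1), seed = 8)
  expect_equal(img$image_with$pip2, img$image_without$pip2)
})

test_that("over-filled fields are rejected", {
  expect_error(
    simulate_domain_images(list(size_px = 32, n_domains = 40,
                                mean_domain_area_um2 = 1.7), seed = 1),
    "domain area|place")
})

test_that("cluster tables and traces round-trip through their CSV formats", {
  cfg <- synthetic_config(seed = 12, n_clusters = 50,
                          capture_probs = c(0, 0.5, 1))
  cl <- simulate_capture_outcomes(simulate_cluster_compositions(cfg),
                                  cfg$capture_probs, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cluster_table(cl, path)
  back <- read_cluster_table(path)
  expect_equal(back$copy_number, cl$copy_number)
  expect_equal(back$vesicle_bound, cl$vesicle_bound)
  expect_equal(back$true_oligomers, cl$true_oligomers)

  tr <- list(simulate_bleach_trace(3, seed = 1, trace_id = "a"),
             simulate_bleach_trace(5, seed = 2, trace_id = "b"))
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_bleach_traces(tr, tpath)
  back <- read_bleach_traces(tpath)
  expect_equal(back$a$intensity, tr[[1]]$intensity)
  expect_equal(back$b$intensity, tr[[2]]$intensity)
})

test_that("image sets round-trip through TIFF + sidecar", {
  img <- simulate_domain_images(list(size_px = 64, n_domains = 3), seed = 9)
  path <- withr::local_tempfile(fileext = ".tif")
  write_domain_images(img, path)
  back <- read_domain_images(path)
  expect_equal(back$pixel_size_um, img$pixel_size_um)
  expect_equal(back$image_with$pip2, img$image_with$pip2, tolerance = 1e-6)
  expect_equal(back$image_without$pip2, img$image_without$pip2, tolerance = 1e-6)
})

test_that("config round-trips through YAML", {
  cfg <- synthetic_config(seed = 99, K = 6, monomer_mean = 2,
                          oligomer_mean = 1, n_clusters = 226,
                          capture_probs = c(0, 0.8, 1))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_equal(back$K, 6L)
  expect_equal(back$capture_probs, c(0, 0.8, 1))
  expect_equal(back$seed, 99L)
})
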