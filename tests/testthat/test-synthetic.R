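test_that("noise-free construction places events exactly", {
  cfg <- sim_config(noise_sd = 0, bins_chr1 = 400, bins_chr19 = 150)
  p <- simulate_profile(sim_truth("t", "full", "full", purity = 1), cfg,
                        seed = 1)
  b <- p$bins
  mid <- (b$start + b$end) / 2
  in_1p <- b$chrom == "1" & mid < 125e6
  in_19q <- b$chrom == "19" & mid >= 26.5e6
  expect_true(all(abs(b$log2[in_1p] - (-0.6)) < 1e-12))
  expect_true(all(abs(b$log2[in_19q] - (-0.6)) < 1e-12))
  expect_true(all(b$log2[!(in_1p | in_19q)] == 0))
})

test_that("purity attenuates the shift via the linear mixture", {
  cfg <- sim_config(noise_sd = 0, bins_chr1 = 200, bins_chr19 = 80)
  p <- simulate_profile(sim_truth("t", "full", "none", purity = 0.7), cfg,
                        seed = 1)
  expected <- log2(0.7 * 2^-0.6 + 0.3)
  v <- extract_chrom_signal(p, "1")
  expect_equal(v[1], expected, tolerance = 1e-12)
  # in-region mean at purity 1 with noise: within 3*sd/sqrt(n)
  cfg2 <- sim_config(noise_sd = 0.15, bins_chr1 = 1869, bins_chr19 = 649)
  p2 <- simulate_profile(sim_truth("t", "full", "none", purity = 1), cfg2,
                         seed = 2)
  b <- p2$bins
  mid <- (b$start + b$end) / 2
  v1p <- b$log2[b$chrom == "1" & mid < 125e6]
  expect_lt(abs(mean(v1p) - (-0.6)), 3 * 0.15 / sqrt(length(v1p)))
})

test_that("partial events cover 30-60% of the arm and stay negative", {
  cfg <- sim_config(noise_sd = 0, bins_chr1 = 1000, bins_chr19 = 400)
  for (seed in 1:5) {
    p <- simulate_profile(sim_truth("t", "none", "partial", purity = 1),
                          cfg, seed = seed)
    b <- p$bins
    mid <- (b$start + b$end) / 2
    in_19q <- b$chrom == "19" & mid >= 26.5e6
    shifted <- b$log2[in_19q] < -0.3
    frac <- mean(shifted)
    expect_gte(frac, 0.25)
    expect_lte(frac, 0.65)
    # contiguity of the shifted block
    r <- rle(shifted)
    expect_equal(sum(r$values), 1)
    expect_false(call_arm(p, codel_regions()[["19q"]])$call)
  }
})

test_that("simulate_dataset respects counts, labels and determinism", {
  cfg <- sim_config(n_codel = 19, n_control = 42, bins_chr1 = 200,
                    bins_chr19 = 80, seed = 7)
  ds <- simulate_dataset(cfg)
  expect_length(ds$profiles, 61)
  expect_equal(sum(ds$truths$codeletion), 19)
  expect_equal(as.numeric(table(ds$truths$label)[c("codel", "no_codel")]),
               c(19, 42))
  # controls never carry full/full
  ctl <- ds$truths[!ds$truths$codeletion, ]
  expect_false(any(ctl$event_1p == "full" & ctl$event_19q == "full"))
  # determinism
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds$truths, ds2$truths)
  expect_equal(ds$profiles[[5]]$bins$log2, ds2$profiles[[5]]$bins$log2)
  # no codel samples requested -> none produced
  none <- simulate_dataset(sim_config(n_codel = 0, n_control = 3,
                                      bins_chr1 = 50, bins_chr19 = 30))
  expect_false(any(none$truths$codeletion))
})

test_that("array-platform output is probe-dialect compatible and reformats", {
  cfg <- sim_config(n_codel = 1, n_control = 1, platform = "array",
                    bins_chr1 = 5000, bins_chr19 = 2000, seed = 3)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$profiles[[1]]$bins$end - ds$profiles[[1]]$bins$start == 1))
  f <- featurize(ds$profiles[[1]])
  expect_equal(ncol(f$x1), 1869)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, platform = "array")
  rt <- read_array_probes(file.path(dir, "codel_001.probes.tsv"), "codel_001")
  expect_equal(nrow(rt$bins), 7000)
})

test_that("reformatted array profiles match panel group means (harmonization)", {
  # same truth on both platforms, no noise: group means must agree closely
  truth <- sim_truth("t", "full", "full", purity = 0.9)
  pan <- simulate_profile(truth, sim_config(noise_sd = 0), seed = 1)
  arr <- simulate_profile(truth, sim_config(noise_sd = 0, platform = "array"),
                          seed = 2)
  fp <- featurize(pan); fa <- featurize(arr)
  # boundary bins differ where the event edge falls inside a group
  expect_lt(mean(abs(fp$x1 - fa$x1)), 0.01)
  expect_lt(mean(abs(fp$x2 - fa$x2)), 0.01)
})

test_that("dataset round-trips through the CNR dialect on disk", {
  cfg <- sim_config(n_codel = 1, n_control = 1, bins_chr1 = 120,
                    bins_chr19 = 60, seed = 11)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_length(paths, 2)
  p <- read_cnr(paths[1], ds$profiles[[1]]$sample_id)
  expect_equal(p$bins$log2, ds$profiles[[1]]$bins$log2, tolerance = 1e-8)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), 2)
  labels <- read_label_sheet(file.path(dir, "labels.tsv"))
  expect_equal(nrow(labels), 2)
})
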