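# 1p region in 0-based bin space: midpoints in [0, 125e6);
# 19q: midpoints in [26.5e6, 59128983).

del_1p <- function(log2, id = "s") {
  cn_profile(id, spaced_bins("1", 0, 124e6, log2))
}

test_that("call_arm: uniform loss, partial loss, and sparse support", {
  reg <- codel_regions()[["1p"]]
  # 200 in-region bins all deleted
  full <- call_arm(del_1p(rep(-1, 200)), reg)
  expect_true(full$call)
  expect_equal(full$deleted_fraction, 1.0)
  expect_equal(full$n_bins, 200)
  # half deleted, half neutral -> partial -> negative
  half <- call_arm(del_1p(c(rep(-1, 100), rep(0, 100))), reg)
  expect_false(half$call)
  expect_lt(half$deleted_fraction, 0.9)
  # 5 bins below the minimum support
  expect_warning(sparse <- call_arm(del_1p(rep(-1, 5)), reg), "in-region")
  expect_false(sparse$call)
  expect_equal(sparse$n_bins, 5)
})

test_that("call_arm ignores out-of-region bins and uses midpoints", {
  reg <- codel_regions()[["1p"]]
  bins_1p <- spaced_bins("1", 0, 124e6, rep(-1, 150))
  base <- cn_profile("s", bins_1p)
  with_q <- cn_profile("s", rbind(bins_1p,
                                  spaced_bins("1", 126e6, 249e6, rep(0, 300)),
                                  spaced_bins("19", 0, 59e6, rnorm(100))))
  a <- call_arm(base, reg)
  b <- call_arm(with_q, reg)
  expect_equal(b$n_bins, a$n_bins)
  expect_equal(b$deleted_fraction, a$deleted_fraction)
  expect_equal(b$call, a$call)
  # bin straddling the boundary belongs by midpoint: [124e6, 127e6) -> mid
  # 125.5e6 -> outside 1p
  strad <- cn_profile("s", data.frame(chrom = "1", start = 124e6,
                                      end = 127e6, log2 = -1))
  expect_equal(call_arm(strad, reg, min_bins = 1L)$n_bins, 0)
})

test_that("call_arm is monotone: lowering a bin never un-calls a deletion", {
  set.seed(5)
  reg <- codel_regions()[["1p"]]
  for (rep in 1:20) {
    v <- rnorm(120, mean = -0.5, sd = 0.3)
    before <- call_arm(del_1p(v), reg)
    j <- sample(120, 1)
    v[j] <- v[j] - runif(1, 0, 2)
    after <- call_arm(del_1p(v), reg)
    if (before$call) expect_true(after$call)
    expect_gte(after$n_deleted, before$n_deleted - 0L)
  }
})

test_that("smooth_window = 1 recovers the raw per-bin rule", {
  reg <- codel_regions()[["1p"]]
  v <- c(rep(-1, 90), rep(0, 10))
  raw <- call_arm(del_1p(v), reg, smooth_window = 1L)
  expect_equal(raw$n_deleted, 90)
  expect_equal(raw$longest_normal_run, 10)
})

test_that("call_codeletion is the conjunction and checks regions", {
  regs <- codel_regions()
  p_del <- cn_profile("s", rbind(spaced_bins("1", 0, 124e6, rep(-1, 200)),
                                 spaced_bins("19", 27e6, 59e6, rep(-1, 100))))
  p_1p <- cn_profile("s", rbind(spaced_bins("1", 0, 124e6, rep(-1, 200)),
                                spaced_bins("19", 27e6, 59e6, rep(0, 100))))
  c1 <- call_arm(p_del, regs[["1p"]]); c19 <- call_arm(p_del, regs[["19q"]])
  expect_true(call_codeletion(c1, c19))
  expect_false(call_codeletion(call_arm(p_1p, regs[["1p"]]),
                               call_arm(p_1p, regs[["19q"]])))
  expect_error(call_codeletion(c19, c1), "expected arm calls")
  row <- call_sample(p_del)
  expect_true(row$codeletion)
  expect_equal(row$n_bins_19q, 100)
})

test_that("interpret_fish applies the combined criteria with strict cutoffs", {
  # 60 nuclei (1,2): ratio = 60/120 = 0.5 (< 0.75), all nuclei low-target
  all_del <- fish_counts(rep(1, 60), rep(2, 60))
  r <- interpret_fish(all_del)
  expect_equal(r$combined_ratio, 0.5)
  expect_equal(r$frac_low_target, 1.0)
  expect_true(r$deletion_call)

  balanced <- fish_counts(rep(2, 60), rep(2, 60))
  r <- interpret_fish(balanced)
  expect_equal(r$combined_ratio, 1.0)
  expect_false(r$deletion_call)

  # 40 nuclei (1,2) + 60 nuclei (2,2): ratio 160/200 = 0.80, frac 0.40
  mixed <- fish_counts(c(rep(1, 40), rep(2, 60)), rep(2, 100))
  r <- interpret_fish(mixed)
  expect_equal(r$combined_ratio, 0.80)
  expect_equal(r$frac_low_target, 0.40)
  expect_false(r$deletion_call)

  # boundary strictness: ratio exactly 0.75 and frac exactly 0.5 are negative
  # 50 nuclei (1,2) + 50 nuclei (2,2): ratio 150/200 = 0.75, frac 0.50
  edge <- fish_counts(c(rep(1, 50), rep(2, 50)), rep(2, 100))
  r <- interpret_fish(edge)
  expect_equal(r$combined_ratio, 0.75)
  expect_equal(r$frac_low_target, 0.50)
  expect_false(r$deletion_call)
})

test_that("interpret_fish excludes non-evaluable nuclei and flags shortage", {
  counts <- fish_counts(c(rep(1, 55), rep(0, 20)), c(rep(2, 55), rep(1, 20)))
  r <- interpret_fish(counts)
  expect_equal(r$n_evaluable, 55)
  expect_true(r$deletion_call)
  short <- interpret_fish(fish_counts(rep(1, 10), rep(2, 10)))
  expect_false(short$sufficient)
  expect_true(is.na(short$deletion_call))
  empty <- interpret_fish(fish_counts(integer(0), integer(0)))
  expect_false(empty$sufficient)
})

test_that("imbalanced nuclei are tallied but do not drive the call", {
  # 60 nuclei at (3,4): ratio 0.75 is not < 0.75, no low-target nuclei
  imb <- fish_counts(rep(3, 60), rep(4, 60))
  r <- interpret_fish(imb)
  expect_equal(r$n_imbalance, 60)
  expect_false(r$deletion_call)
})
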