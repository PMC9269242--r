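test_that("window grid arithmetic is exact, anchored at base 1", {
  cfg <- scan_config(window_size = 2e6, step_size = 1e4)
  w <- make_windows(c(chr = 4e6), cfg)
  expect_equal(nrow(w), 400L)
  expect_equal(w$start, seq(1L, 3990001L, by = 1e4L))
  expect_equal(w$start[201], 2000001L)
  expect_equal(w$end[201], 4000000L)
  expect_false(w$truncated[201])
  expect_true(all(w$truncated[202:400]))

  # chromosome shorter than a window: everything truncated
  w2 <- make_windows(c(chr = 1500000), cfg)
  expect_true(all(w2$end == 1500000L))
  expect_true(all(w2$truncated))

  # step = window tiles without overlap
  w3 <- make_windows(c(chr = 1e6), scan_config(window_size = 1e5, step_size = 1e5))
  expect_equal(nrow(w3), 10L)
  expect_equal(w3$start, w3$end - 1e5L + 1L)

  expect_error(make_windows(c(chr = -5), cfg), "non-positive")
})

test_that("window means equal a brute-force rescan on random data", {
  set.seed(21)
  n <- 800
  v <- tibble::tibble(
    chrom = sample(c("c1", "c2"), n, replace = TRUE),
    pos = sample.int(1e6, n), ref = "A", alt = "T",
    vclass = sample(c("SNP", "InDel"), n, replace = TRUE, prob = c(.8, .2)),
    multiallelic = FALSE,
    ad_high_ref = rbinom(n, 40, 0.5), ad_high_alt = rbinom(n, 40, 0.5),
    ad_low_ref = rbinom(n, 40, 0.5), ad_low_alt = rbinom(n, 40, 0.5))
  v <- bsa_index(v)
  v <- v[v$depth_high > 0 & v$depth_low > 0, ]
  cfg <- scan_config(window_size = 1e5, step_size = 2.5e4)
  grid <- make_windows(c(c1 = 1e6, c2 = 1e6), cfg)
  for (cl in c("SNP", "InDel")) {
    got <- window_means(grid, v, vclass = cl)
    want <- oracle_window_means(grid, v[v$vclass == cl, ])
    expect_equal(got$n, want$n)
    expect_equal(got$mean_delta, want$mean_delta)
    expect_equal(got$mean_index_high, want$mean_index_high)
    expect_equal(got$mean_index_low, want$mean_index_low)
  }
  # single-window sanity: mean of {0.2, 0.4, 0.9} is 0.5
  vv <- v[1:3, ]
  vv$chrom <- "c1"; vv$pos <- c(10L, 20L, 30L); vv$delta <- c(0.2, 0.4, 0.9)
  one <- window_means(tibble::tibble(chrom = "c1", start = 1L, end = 100L,
                                     truncated = FALSE), vv, min_variants = 1)
  expect_equal(one$mean_delta, 0.5)
  # empty window flagged with undefined means
  none <- window_means(tibble::tibble(chrom = "c9", start = 1L, end = 100L,
                                      truncated = FALSE), vv)
  expect_equal(none$n, 0L)
  expect_true(is.na(none$mean_delta))
  expect_false(none$reliable)
})

test_that("simulated null CIs behave like a depth-aware binomial null", {
  mk <- function(n, depth, p = 0.5, chrom = "c1") {
    tibble::tibble(
      chrom = chrom, pos = seq(100L, by = 100L, length.out = n),
      ref = "A", alt = "T", vclass = "SNP", multiallelic = FALSE,
      ad_high_ref = depth - rbinom(n, depth, p), ad_high_alt = rbinom(n, depth, p),
      ad_low_ref = depth - rbinom(n, depth, p), ad_low_alt = rbinom(n, depth, p)
    ) |> bsa_index()
  }
  win <- tibble::tibble(chrom = "c1", start = 1L, end = 100000L,
                        truncated = FALSE)
  set.seed(5)
  v50 <- mk(50, 40)
  cfg <- scan_config(null_reps = 10000, rng_seed = 1)
  ci <- null_ci(win, v50, cfg)
  # approximately symmetric about zero under the symmetric null
  expect_lt(abs(ci$ci_lo_95 + ci$ci_hi_95), 0.02)
  expect_lt(ci$ci_lo_95, 0)
  expect_gt(ci$ci_hi_95, 0)
  # the 99% interval contains the 95% one
  expect_lte(ci$ci_lo_99, ci$ci_lo_95)
  expect_gte(ci$ci_hi_99, ci$ci_hi_95)

  # single shallow variant: wider interval than the 50-variant window,
  # bounds within [-1, 1]
  v1 <- mk(1, 4)
  ci1 <- null_ci(win, v1, cfg)
  expect_gte(ci1$ci_lo_95, -1); expect_lte(ci1$ci_hi_95, 1)
  expect_gt(ci1$ci_hi_95 - ci1$ci_lo_95, ci$ci_hi_95 - ci$ci_lo_95)

  # infinite-depth limit: the read-noise component of the CI shrinks toward
  # zero, while the full null keeps the bulk-composition floor
  cfg_reads <- scan_config(null_reps = 10000, null_model = "reads",
                           rng_seed = 1)
  v_deep <- mk(50, 40000)
  ci_deep_reads <- null_ci(win, v_deep, cfg_reads)
  ci_reads <- null_ci(win, v50, cfg_reads)
  expect_lt(ci_deep_reads$ci_hi_95 - ci_deep_reads$ci_lo_95,
            (ci_reads$ci_hi_95 - ci_reads$ci_lo_95) / 10)
  ci_deep_full <- null_ci(win, v_deep, cfg)
  # floor ~ 2 * 1.96 * sd of a 50-variant mean of bulk-frequency deltas
  floor_sd <- sqrt(2 * 0.5 * 0.5 / (2 * cfg$pool_size) / 50)
  expect_gt(ci_deep_full$ci_hi_95 - ci_deep_full$ci_lo_95, 2 * floor_sd)

  # seeded: reproducible
  ci_again <- null_ci(win, v50, cfg)
  expect_equal(ci$ci_lo_95, ci_again$ci_lo_95)
  expect_error(null_ci(win, v50, scan_config(null_reps = 0)), "null_reps")
})

test_that("region calling needs both tracks and merges across a peak", {
  cfg <- scan_config(window_size = 1e5, step_size = 5e4, null_reps = 200,
                     min_variants = 5, rng_seed = 2)
  set.seed(2)
  mkv <- function(n, pos_lo, pos_hi, p_h, p_l, vclass) {
    pos <- sort(sample(seq.int(pos_lo, pos_hi), n))
    depth <- 40L
    tibble::tibble(
      chrom = "c1", pos = pos, ref = "A", alt = "T", vclass = vclass,
      multiallelic = FALSE,
      ad_high_ref = depth - rbinom(n, depth, p_h),
      ad_high_alt = rbinom(n, depth, p_h),
      ad_low_ref = depth - rbinom(n, depth, p_l),
      ad_low_alt = rbinom(n, depth, p_l)) |> bsa_index()
  }
  # strong divergence at 400-600 kb in both classes, null elsewhere
  v <- dplyr::bind_rows(
    mkv(120, 1, 4e5, 0.5, 0.5, "SNP"), mkv(40, 1, 4e5, 0.5, 0.5, "InDel"),
    mkv(80, 4e5, 6e5, 0.98, 0.02, "SNP"), mkv(30, 4e5, 6e5, 0.98, 0.02, "InDel"),
    mkv(120, 6e5, 1e6, 0.5, 0.5, "SNP"), mkv(40, 6e5, 1e6, 0.5, 0.5, "InDel"))
  v <- dplyr::arrange(v, chrom, pos)
  grid <- make_windows(c(c1 = 1e6), cfg)
  tracks <- lapply(c("SNP", "InDel"), function(cl) {
    w <- window_means(grid, v, vclass = cl, min_variants = cfg$min_variants)
    null_ci(w, v, cfg, vclass = cl)
  })
  regions <- call_regions(tracks[[1]], tracks[[2]], config = cfg)
  expect_equal(nrow(regions), 1L)
  expect_lte(regions$start, 450001L)
  expect_gte(regions$end, 550000L)
  expect_equal(regions$supported_by, "SNP,InDel")
  expect_gte(regions$peak_delta, cfg$delta_threshold)

  # single-track significance is excluded by default, included without the
  # consistency requirement
  null_indel <- dplyr::bind_rows(
    mkv(40, 1, 4e5, 0.5, 0.5, "InDel"), mkv(30, 4e5, 6e5, 0.5, 0.5, "InDel"),
    mkv(40, 6e5, 1e6, 0.5, 0.5, "InDel")) |> dplyr::arrange(pos)
  w_ind_null <- null_ci(window_means(grid, null_indel, vclass = "InDel",
                                     min_variants = cfg$min_variants),
                        null_indel, cfg, vclass = "InDel")
  expect_equal(nrow(call_regions(tracks[[1]], w_ind_null, config = cfg)), 0L)
  cfg_any <- scan_config(window_size = 1e5, step_size = 5e4, null_reps = 200,
                         min_variants = 5, consistency = FALSE, rng_seed = 2)
  expect_gte(nrow(call_regions(tracks[[1]], w_ind_null, config = cfg_any)), 1L)

  # mismatched grids are an error
  expect_error(call_regions(tracks[[1]], tracks[[2]][-1, ], config = cfg),
               "grid")
})

test_that("region calling is consistent when chromosomes are concatenated", {
  cfg <- scan_config(window_size = 1e5, step_size = 1e5, null_reps = 100,
                     min_variants = 5, rng_seed = 3)
  set.seed(13)
  mk_chr <- function(chrom, peak) {
    p_h <- if (peak) 0.98 else 0.5
    p_l <- if (peak) 0.02 else 0.5
    n <- 200
    tibble::tibble(
      chrom = chrom, pos = sort(sample.int(5e5, n)), ref = "A", alt = "T",
      vclass = rep(c("SNP", "InDel"), length.out = n), multiallelic = FALSE,
      ad_high_ref = 40L - rbinom(n, 40, p_h), ad_high_alt = rbinom(n, 40, p_h),
      ad_low_ref = 40L - rbinom(n, 40, p_l), ad_low_alt = rbinom(n, 40, p_l)
    ) |> bsa_index()
  }
  v <- dplyr::bind_rows(mk_chr("cA", TRUE), mk_chr("cB", FALSE))
  lens <- c(cA = 5e5, cB = 5e5)
  joint <- bsa_scan(v, lens, config = cfg)
  sep <- lapply(names(lens), function(ch)
    bsa_scan(v[v$chrom == ch, ], lens[ch], config = cfg))
  sep_regions <- dplyr::bind_rows(lapply(sep, function(s) s$regions))
  expect_equal(joint$regions[c("chrom", "start", "end")],
               sep_regions[c("chrom", "start", "end")])
})
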