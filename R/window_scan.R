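#' Scan configuration for the sliding-window analysis
#'
#' Defaults follow common QTL-seq practice: 2 Mb windows advanced in 10 kb
#' steps, per-window simulated confidence intervals at 95% and 99%, and an
#' association threshold of 0.90 on the absolute window-mean delta index.
#'
#' @param window_size Window width in bases (default 2e6).
#' @param step_size Step between window starts in bases (default 1e4).
#' @param ci_levels Two-sided confidence levels for the simulated null
#'   (default `c(0.95, 0.99)`); the first level drives region calling.
#' @param null_reps Monte-Carlo replicates for the null CIs (default 10000).
#' @param delta_threshold Association threshold on `|mean delta|`
#'   (default 0.90).
#' @param min_variants Minimum member variants for a window to be considered
#'   reliable (default 10).
#' @param region_mode How a window becomes significant for region calling:
#'   `"threshold_and_ci"` (default), `"threshold"`, or `"ci"`.
#' @param null_model Null for the simulated CIs. `"bulk_and_reads"`
#'   (default) resamples the bulk allele frequency of each pool
#'   (`Binomial(2 * pool_size, p-hat) / (2 * pool_size)`) and then the reads
#'   at the observed depth — the natural-population analogue of the QTL-seq
#'   simulated null, calibrated against the bulk-composition variance that
#'   two distinct accession subsets carry even without a trait locus.
#'   `"reads"` resamples read counts only (anti-conservative; kept for
#'   studying the read-noise component in isolation).
#' @param pool_size Accessions per bulk, used by the `"bulk_and_reads"` null
#'   (default 49).
#' @param consistency Require significance in both the SNP and InDel tracks
#'   (default TRUE).
#' @param rng_seed Optional seed for the null simulation.
#' @return A list of class `"scan_config"`.
#' @export
scan_config <- function(window_size = 2e6, step_size = 1e4,
                        ci_levels = c(0.95, 0.99), null_reps = 10000,
                        delta_threshold = 0.90, min_variants = 10,
                        region_mode = c("threshold_and_ci", "threshold", "ci"),
                        null_model = c("bulk_and_reads", "reads"),
                        pool_size = 49, consistency = TRUE, rng_seed = NULL) {
  assert_scalar_num(window_size, "window_size", 1)
  assert_scalar_num(step_size, "step_size", 1, window_size)
  assert_scalar_num(delta_threshold, "delta_threshold", 1e-9, 1)
  assert_scalar_num(null_reps, "null_reps", 1)
  if (any(ci_levels <= 0 | ci_levels >= 1)) abort("ci_levels must be in (0, 1)")
  structure(list(window_size = as.integer(window_size),
                 step_size = as.integer(step_size),
                 ci_levels = ci_levels, null_reps = as.integer(null_reps),
                 delta_threshold = delta_threshold,
                 min_variants = as.integer(min_variants),
                 region_mode = match.arg(region_mode),
                 null_model = match.arg(null_model),
                 pool_size = as.integer(pool_size),
                 consistency = isTRUE(consistency),
                 rng_seed = rng_seed),
            class = "scan_config")
}

#' Build the sliding-window grid
#'
#' Windows are anchored at base 1 of each chromosome and advanced by the
#' step size; a window exists whenever its start does not exceed the
#' chromosome length, and windows running past the end are truncated there
#' and flagged.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param config A [scan_config()].
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   `truncated`.
#' @export
make_windows <- function(chrom_lengths, config = scan_config()) {
  if (any(chrom_lengths <= 0)) abort("non-positive chromosome length")
  if (is.null(names(chrom_lengths))) abort("chrom_lengths must be named")
  out <- purrr::map(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    start <- seq.int(1L, len, by = config$step_size)
    end <- pmin(start + config$window_size - 1L, len)
    tibble(chrom = ch, start = start, end = end,
           truncated = (end - start + 1L) < config$window_size)
  })
  bind_rows(out)
}

# contiguous member-index range of each window among position-sorted variants
window_ranges <- function(starts, ends, pos) {
  i1 <- findInterval(starts - 1L, pos) + 1L
  i2 <- findInterval(ends, pos)
  list(i1 = i1, i2 = i2, n = pmax(i2 - i1 + 1L, 0L))
}

#' Per-window mean indices and delta
#'
#' Computes, for every window, the arithmetic mean of the high-pool index,
#' low-pool index and delta index over the member variants of the requested
#' class. Windows with fewer than `min_variants` members (or truncated at a
#' chromosome end) are flagged unreliable.
#'
#' @param windows Window grid from [make_windows()].
#' @param variants Indexed variants (from [bsa_filter()] or [bsa_index()]).
#' @param vclass `"SNP"`, `"InDel"` or `NULL` for all classes.
#' @param min_variants Reliability cutoff (default 10).
#' @return The window tibble with `n`, `mean_index_high`, `mean_index_low`,
#'   `mean_delta`, `reliable` added.
#' @export
window_means <- function(windows, variants, vclass = NULL, min_variants = 10) {
  assert_cols(variants, c("chrom", "pos", "index_high", "index_low", "delta"),
              "variants")
  if (!is.null(vclass)) variants <- variants[variants$vclass == vclass, ]
  variants <- arrange(variants, .data$chrom, .data$pos)
  out <- windows
  out$n <- 0L
  out$mean_index_high <- NA_real_
  out$mean_index_low <- NA_real_
  out$mean_delta <- NA_real_
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    vv <- variants[variants$chrom == ch, ]
    if (nrow(vv) == 0L) next
    wr <- window_ranges(out$start[wi], out$end[wi], vv$pos)
    # zero-padded cumulative sums: window sum = cs[i2 + 1] - cs[i1]
    ch_h <- c(0, cumsum(vv$index_high)); ch_l <- c(0, cumsum(vv$index_low))
    ch_d <- c(0, cumsum(vv$delta))
    csum <- function(cs, i1, i2) cs[i2 + 1L] - cs[i1]
    n <- wr$n
    out$n[wi] <- n
    nz <- which(n > 0L)
    out$mean_index_high[wi[nz]] <- csum(ch_h, wr$i1, wr$i2)[nz] / n[nz]
    out$mean_index_low[wi[nz]] <- csum(ch_l, wr$i1, wr$i2)[nz] / n[nz]
    out$mean_delta[wi[nz]] <- csum(ch_d, wr$i1, wr$i2)[nz] / n[nz]
  }
  out$reliable <- out$n >= min_variants & !out$truncated
  out
}

#' Simulated null confidence intervals per window
#'
#' Monte-Carlo null of "no allele-frequency divergence between pools", with
#' `p-hat` per variant taken as the pooled alternate fraction over both
#' bulks. Under the default `"bulk_and_reads"` model each replicate first
#' redraws the true allele frequency of each bulk
#' (`Binomial(2 * pool_size, p-hat) / (2 * pool_size)` — two disjoint
#' accession subsets differ even without a trait locus) and then the
#' alternate read counts at the observed pool depths; under `"reads"` only
#' the read counts are redrawn. The window mean delta is recomputed per
#' replicate and the CI is the empirical two-sided quantile at each level.
#' Depth-aware: windows whose variants have low read depths get wider
#' intervals.
#'
#' The null additionally honours the ascertainment imposed by the variant
#' filters: a retained site's observed indices passed the low-index and
#' equal-genotype rules, so its null replicates are conditioned on passing
#' them too (replicates that fail are resampled from the passing ones).
#' Without this conditioning the null is too narrow at sites near the filter
#' boundaries, where only divergent read draws survive filtering.
#'
#' @inheritParams window_means
#' @param config A [scan_config()]; `null_reps`, `ci_levels`, `null_model`,
#'   `pool_size` and `rng_seed` are used.
#' @param filter_cfg The [filter_config()] the variants were retained under,
#'   used to condition the null on filter ascertainment; `NULL` disables the
#'   conditioning.
#' @return The window tibble with columns `ci_lo_<level>` / `ci_hi_<level>`
#'   per confidence level.
#' @export
null_ci <- function(windows, variants, config = scan_config(), vclass = NULL,
                    filter_cfg = filter_config()) {
  assert_cols(variants, c("chrom", "pos", "ad_high_alt", "ad_low_alt",
                          "depth_high", "depth_low"), "variants")
  if (config$null_reps < 1) abort("null_reps must be >= 1")
  if (!is.null(vclass)) variants <- variants[variants$vclass == vclass, ]
  variants <- arrange(variants, .data$chrom, .data$pos)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  reps <- config$null_reps
  lv <- config$ci_levels
  lo_names <- sprintf("ci_lo_%g", lv * 100)
  hi_names <- sprintf("ci_hi_%g", lv * 100)
  out <- windows
  for (nm in c(lo_names, hi_names)) out[[nm]] <- NA_real_

  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    vv <- variants[variants$chrom == ch, ]
    nv <- nrow(vv)
    if (nv == 0L) next
    p_hat <- (vv$ad_high_alt + vv$ad_low_alt) / (vv$depth_high + vv$depth_low)
    # variants x reps replicate deltas under the pooled-frequency null
    p_rep <- rep(p_hat, reps)
    if (config$null_model == "bulk_and_reads") {
      two_n <- 2L * config$pool_size
      q_h <- rbinom(nv * reps, two_n, p_rep) / two_n
      q_l <- rbinom(nv * reps, two_n, p_rep) / two_n
    } else {
      q_h <- p_rep
      q_l <- p_rep
    }
    ah <- matrix(rbinom(nv * reps, rep(vv$depth_high, reps), q_h), nrow = nv)
    al <- matrix(rbinom(nv * reps, rep(vv$depth_low, reps), q_l), nrow = nv)
    ih <- ah / vv$depth_high
    il <- al / vv$depth_low
    if (!is.null(filter_cfg)) {
      # condition each variant's replicates on passing the index filters
      mi <- filter_cfg$min_index
      fail <- if (filter_cfg$low_index_mode == "both") {
        ih < mi & il < mi
      } else {
        ih < mi | il < mi
      }
      if (filter_cfg$drop_equal_genotypes) {
        b <- filter_cfg$hom_band
        fail <- fail | (ih < b & il < b) | (ih > 1 - b & il > 1 - b)
      }
      redo <- which(rowSums(fail) > 0L & rowSums(!fail) > 0L)
      for (j in redo) {
        ok <- which(!fail[j, ])
        res <- ok[sample.int(length(ok), reps, replace = TRUE)]
        ih[j, ] <- ih[j, res]
        il[j, ] <- il[j, res]
      }
    }
    dm <- ih - il
    cs <- apply(dm, 2, cumsum)
    if (nv == 1L) cs <- matrix(cs, nrow = 1L)
    wr <- window_ranges(windows$start[wi], windows$end[wi], vv$pos)
    for (k in seq_along(wi)) {
      if (wr$n[k] == 0L) next
      i1 <- wr$i1[k]; i2 <- wr$i2[k]
      sums <- cs[i2, ] - (if (i1 > 1L) cs[i1 - 1L, ] else 0)
      means <- sums / wr$n[k]
      for (j in seq_along(lv)) {
        a <- (1 - lv[j]) / 2
        qs <- quantile(means, c(a, 1 - a), names = FALSE, type = 7)
        out[[lo_names[j]]][wi[k]] <- qs[1]
        out[[hi_names[j]]][wi[k]] <- qs[2]
      }
    }
  }
  out
}

window_significance <- function(windows, config) {
  lv1 <- sprintf("ci_lo_%g", config$ci_levels[1] * 100)
  hv1 <- sprintf("ci_hi_%g", config$ci_levels[1] * 100)
  sig_thr <- !is.na(windows$mean_delta) &
    abs(windows$mean_delta) >= config$delta_threshold
  sig_ci <- !is.na(windows$mean_delta) & !is.na(windows[[lv1]]) &
    (windows$mean_delta < windows[[lv1]] | windows$mean_delta > windows[[hv1]])
  sig <- switch(config$region_mode,
                threshold_and_ci = sig_thr & sig_ci,
                threshold = sig_thr,
                ci = sig_ci)
  windows$sig_threshold <- sig_thr
  windows$sig_ci <- sig_ci
  windows$significant <- sig & windows$reliable
  windows
}

merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[0, ])
  df <- arrange(df, .data$start)
  out <- list(); cur <- df[1, ]
  for (i in seq_len(nrow(df))[-1]) {
    if (df$start[i] <= cur$end + 1L) {
      cur$end <- max(cur$end, df$end[i])
      cur$peak_delta <- max(cur$peak_delta, df$peak_delta[i])
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- df[i, ]
    }
  }
  out[[length(out) + 1L]] <- cur
  bind_rows(out)
}

#' Call candidate regions from the SNP and InDel window tracks
#'
#' A window is significant according to the configured mode (by default it
#' must exceed the delta threshold *and* fall outside its simulated CI);
#' overlapping significant windows are merged into regions, and by default a
#' region is reported only when it is supported consistently by both the SNP
#' and the InDel track. Genes are attached by interval overlap of their
#' transcription bounds.
#'
#' @param snp_windows,indel_windows Window tibbles from [window_means()] +
#'   [null_ci()], computed on identical grids.
#' @param genes Optional gene models from [read_gene_models()].
#' @param config A [scan_config()].
#' @return Tibble of regions: `chrom`, `start`, `end`, `peak_delta`,
#'   `supported_by`, and a `genes` list-column of gene ids.
#' @export
call_regions <- function(snp_windows, indel_windows, genes = NULL,
                         config = scan_config()) {
  key <- c("chrom", "start", "end")
  if (!identical(snp_windows[key], indel_windows[key])) {
    abort("SNP and InDel tracks are not on the same window grid")
  }
  s <- window_significance(snp_windows, config)
  i <- window_significance(indel_windows, config)
  joint <- if (config$consistency) s$significant & i$significant
           else s$significant | i$significant
  if (!any(joint)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  peak_delta = numeric(), supported_by = character(),
                  genes = list()))
  }
  cand <- tibble(chrom = s$chrom[joint], start = s$start[joint],
                 end = s$end[joint],
                 peak_delta = pmax(abs(s$mean_delta[joint]),
                                   abs(i$mean_delta[joint]), na.rm = TRUE))
  regions <- cand |>
    group_by(.data$chrom) |>
    dplyr::group_modify(~ merge_intervals(.x)) |>
    ungroup()

  regions$supported_by <- vapply(seq_len(nrow(regions)), function(r) {
    ov <- s$chrom == regions$chrom[r] & s$start <= regions$end[r] &
      s$end >= regions$start[r]
    paste(c(if (any(s$significant & ov)) "SNP",
            if (any(i$significant & ov)) "InDel"), collapse = ",")
  }, character(1))

  regions$genes <- purrr::map(seq_len(nrow(regions)), function(r) {
    if (is.null(genes) || nrow(genes) == 0L) return(character(0))
    hit <- genes$chrom == regions$chrom[r] &
      genes$tx_start <= regions$end[r] & genes$tx_end >= regions$start[r]
    genes$gene_id[hit]
  })
  regions
}

#' Run the full two-track window scan
#'
#' Convenience wrapper: builds the window grid, computes window means and
#' simulated null CIs for the SNP and InDel tracks, and calls candidate
#' regions.
#'
#' @param variants Filtered, indexed variants (see [bsa_filter()]).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param genes Optional gene models.
#' @param config A [scan_config()].
#' @param filter_cfg The [filter_config()] used upstream, passed to
#'   [null_ci()] for its ascertainment conditioning.
#' @return An object of class `"bsa_scan"`: a list with `snp`, `indel`
#'   window tibbles (with significance flags), `regions`, and `config`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
bsa_scan <- function(variants, chrom_lengths, genes = NULL,
                     config = scan_config(), filter_cfg = filter_config()) {
  grid <- make_windows(chrom_lengths, config)
  tracks <- lapply(c(SNP = "SNP", InDel = "InDel"), function(cl) {
    w <- window_means(grid, variants, vclass = cl,
                      min_variants = config$min_variants)
    w <- null_ci(w, variants, config, vclass = cl, filter_cfg = filter_cfg)
    window_significance(w, config)
  })
  regions <- call_regions(tracks$SNP, tracks$InDel, genes, config)
  structure(list(snp = tracks$SNP, indel = tracks$InDel,
                 regions = regions, config = config),
            class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat(sprintf("<bsa_scan> %d windows/track, %d reliable (SNP), %d candidate region(s)\n",
              nrow(x$snp), sum(x$snp$reliable), nrow(x$regions)))
  if (nrow(x$regions) > 0L) print(x$regions)
  invisible(x)
}
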