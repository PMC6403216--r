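# Synthetic copy-number profile simulator: the package's self-contained
# source of labeled test and demo data. Emulates targeted-panel profiles
# (~1869 chr1 bins, ~649 chr19 bins) or dense SNP-array profiles (tens of
# thousands of probes) with arm-level deletion shifts attenuated by tumor
# purity, optional partial (sub-arm) deletions, and per-bin Gaussian noise.

CHR_LEN <- c("1" = 249250621, "19" = 59128983)  # hg19

#' Simulator configuration
#'
#' Defaults emulate the development cohort structure: 19 co-deleted cases
#' vs 42 controls on a targeted panel, a heterozygous-loss log2 shift of
#' -0.6 at full purity, per-bin noise sd 0.15, and tumor purity uniform in
#' \[0.6, 1\]. Controls may carry a partial (sub-arm) deletion with
#' probability `partial_fraction`, or a single-arm full deletion (1p only
#' or 19q only, probability `single_arm_fraction` each) to exercise the
#' co-deletion conjunction; they never carry a full/full event.
#'
#' @param n_codel number of co-deleted samples.
#' @param n_control number of control samples.
#' @param platform `"panel"` (CNR-style bins) or `"array"` (unit-width
#'   probes).
#' @param bins_chr1,bins_chr19 bins per chromosome (panel defaults
#'   1869/649; array defaults 30000/12000).
#' @param del_shift log2 shift of a deleted arm at purity 1 (<= 0).
#' @param noise_sd per-bin Gaussian noise sd (>= 0).
#' @param purity_range tumor-purity range, drawn uniformly per sample.
#' @param partial_fraction probability a control carries a partial event.
#' @param single_arm_fraction probability (each) of a 1p-only or 19q-only
#'   full deletion in a control.
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_codel = 19L, n_control = 42L,
                       platform = c("panel", "array"),
                       bins_chr1 = NULL, bins_chr19 = NULL,
                       del_shift = -0.6, noise_sd = 0.15,
                       purity_range = c(0.6, 1.0),
                       partial_fraction = 0.1,
                       single_arm_fraction = 0.05,
                       seed = 1L) {
  platform <- match.arg(platform)
  if (is.null(bins_chr1))
    bins_chr1 <- if (platform == "panel") 1869L else 30000L
  if (is.null(bins_chr19))
    bins_chr19 <- if (platform == "panel") 649L else 12000L
  stopifnot(n_codel >= 0, n_control >= 0, del_shift <= 0, noise_sd >= 0,
            length(purity_range) == 2,
            purity_range[1] > 0, purity_range[2] <= 1,
            purity_range[1] <= purity_range[2],
            partial_fraction >= 0, partial_fraction <= 1,
            single_arm_fraction >= 0,
            partial_fraction + 2 * single_arm_fraction <= 1,
            bins_chr1 >= 1, bins_chr19 >= 1)
  structure(list(n_codel = as.integer(n_codel),
                 n_control = as.integer(n_control),
                 platform = platform,
                 bins_chr1 = as.integer(bins_chr1),
                 bins_chr19 = as.integer(bins_chr19),
                 del_shift = del_shift, noise_sd = noise_sd,
                 purity_range = as.numeric(purity_range),
                 partial_fraction = partial_fraction,
                 single_arm_fraction = single_arm_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample truth record
#'
#' @param sample_id sample identifier.
#' @param event_1p,event_19q one of `"none"`, `"full"`, `"partial"`.
#' @param purity tumor purity in (0, 1].
#' @return an object of class `sim_truth`; `codeletion` is `TRUE` iff
#'   both events are `"full"`.
#' @export
sim_truth <- function(sample_id, event_1p = "none", event_19q = "none",
                      purity = 1.0) {
  ev <- c("none", "full", "partial")
  stopifnot(event_1p %in% ev, event_19q %in% ev, purity > 0, purity <= 1)
  structure(list(sample_id = sample_id, event_1p = event_1p,
                 event_19q = event_19q, purity = purity,
                 codeletion = event_1p == "full" && event_19q == "full"),
            class = "sim_truth")
}

# purity-attenuated log2 shift: two-population mixture on linear copy number
purity_shift <- function(del_shift, purity) {
  log2(purity * 2^del_shift + (1 - purity))
}

tile_bins <- function(chrom, n, platform) {
  len <- CHR_LEN[[chrom]]
  if (platform == "panel") {
    edge <- floor(seq(0, len, length.out = n + 1))
    data.frame(chrom = chrom, start = edge[-(n + 1)], end = edge[-1],
               stringsAsFactors = FALSE)
  } else {
    pos <- floor(seq(1, len - 1, length.out = n))
    data.frame(chrom = chrom, start = pos, end = pos + 1,
               stringsAsFactors = FALSE)
  }
}

# indices of bins whose midpoint lies in the canonical region for this arm
region_bin_idx <- function(bins, arm) {
  reg <- codel_regions()[[arm]]
  mid <- (bins$start + bins$end) / 2
  which(bins$chrom == reg$chrom & mid >= reg$start - 1 & mid < reg$end)
}

apply_event <- function(log2v, bins, arm, event, shift) {
  idx <- region_bin_idx(bins, arm)
  if (event == "full") {
    log2v[idx] <- log2v[idx] + shift
  } else if (event == "partial") {
    frac <- runif(1, 0.3, 0.6)
    w <- max(1L, floor(length(idx) * frac))
    s <- sample.int(length(idx) - w + 1L, 1)
    log2v[idx[s:(s + w - 1L)]] <- log2v[idx[s:(s + w - 1L)]] + shift
  }
  log2v
}

#' Simulate one copy-number profile
#'
#' Bins tile chromosomes 1 and 19 uniformly; baseline log2 values are
#' `Normal(0, noise_sd)`. A full arm event adds the purity-attenuated
#' shift `log2(purity * 2^del_shift + (1 - purity))` to every bin whose
#' midpoint lies in the canonical arm region; a partial event shifts a
#' random contiguous 30-60% sub-interval of the arm.
#'
#' @param truth a [sim_truth()].
#' @param config a [sim_config()].
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return a [cn_profile()].
#' @export
simulate_profile <- function(truth, config = sim_config(), seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  with_seed(seed, {
    bins <- rbind(tile_bins("1", config$bins_chr1, config$platform),
                  tile_bins("19", config$bins_chr19, config$platform))
    log2v <- rnorm(nrow(bins), 0, config$noise_sd)
    shift <- purity_shift(config$del_shift, truth$purity)
    log2v <- apply_event(log2v, bins, "1p", truth$event_1p, shift)
    log2v <- apply_event(log2v, bins, "19q", truth$event_19q, shift)
    bins$log2 <- log2v
    bins$label <- sprintf("bin_%s_%05d", bins$chrom,
                          unlist(lapply(table(bins$chrom)[unique(bins$chrom)],
                                        seq_len), use.names = FALSE))
    cn_profile(truth$sample_id, bins)
  })
}

draw_control_truth <- function(id, config, purity) {
  u <- runif(1)
  p <- config$partial_fraction
  s <- config$single_arm_fraction
  if (u < p) {
    arm <- sample(c("1p", "19q"), 1)
    sim_truth(id, event_1p = if (arm == "1p") "partial" else "none",
              event_19q = if (arm == "19q") "partial" else "none",
              purity = purity)
  } else if (u < p + s) {
    sim_truth(id, event_1p = "full", event_19q = "none", purity = purity)
  } else if (u < p + 2 * s) {
    sim_truth(id, event_1p = "none", event_19q = "full", purity = purity)
  } else {
    sim_truth(id, purity = purity)
  }
}

#' Simulate a labeled dataset
#'
#' Produces exactly `n_codel` co-deleted samples (full 1p and full 19q
#' events) and `n_control` controls (no event, a partial event, or a
#' single-arm full event — never full/full). Reproducible under
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `profiles` (list of [cn_profile()]) and `truths`
#'   (data.frame: `sample_id`, `codeletion`, `event_1p`, `event_19q`,
#'   `purity`, `label`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    truths <- list()
    for (i in seq_len(config$n_codel)) {
      truths[[length(truths) + 1L]] <- sim_truth(
        sprintf("codel_%03d", i), "full", "full",
        purity = runif(1, config$purity_range[1], config$purity_range[2]))
    }
    for (i in seq_len(config$n_control)) {
      truths[[length(truths) + 1L]] <- draw_control_truth(
        sprintf("control_%03d", i), config,
        purity = runif(1, config$purity_range[1], config$purity_range[2]))
    }
    profiles <- lapply(truths, simulate_profile, config = config)
    list(profiles = profiles,
         truths = data.frame(
           sample_id = vapply(truths, `[[`, "", "sample_id"),
           codeletion = vapply(truths, `[[`, TRUE, "codeletion"),
           event_1p = vapply(truths, `[[`, "", "event_1p"),
           event_19q = vapply(truths, `[[`, "", "event_19q"),
           purity = vapply(truths, `[[`, 1.0, "purity"),
           label = ifelse(vapply(truths, `[[`, TRUE, "codeletion"),
                          "codel", "no_codel"),
           stringsAsFactors = FALSE))
  })
}

#' Write a simulated dataset to disk
#'
#' Emits one profile file per sample (CNR dialect for the panel platform,
#' probe dialect for the array platform) plus `truth.tsv` and a label
#' sheet `labels.tsv`.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param platform dialect to emit.
#' @return character vector of written profile paths, invisibly.
#' @export
write_dataset <- function(dataset, dir, platform = c("panel", "array")) {
  platform <- match.arg(platform)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (platform == "panel") ".cnr" else ".probes.tsv"
  paths <- vapply(dataset$profiles, function(p) {
    path <- file.path(dir, paste0(p$sample_id, ext))
    if (platform == "panel") write_cnr(p, path)
    else write_array_probes(p, path)
    path
  }, "")
  utils::write.table(dataset$truths, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truths[, c("sample_id", "label")],
                     file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
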