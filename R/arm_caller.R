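# Rule-based arm-deletion calling: the computational surrogate for manual
# review of per-bin CNV plots. "Complete segmental loss" of an arm is
# operationalized on the in-region bin signal after a centered running-mean
# smooth: nearly all smoothed bins must sit at or below a deletion
# threshold, with no long contiguous run of copy-neutral bins. Also
# implements the FISH nucleus-count interpretation rules.

#' Chromosome-arm region
#'
#' Coordinates are 1-based inclusive (the convention regions are printed
#' in); conversion to the 0-based internal bin convention happens inside
#' [call_arm()].
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive positions.
#' @param name arm name (e.g. `"1p"`, `"19q"`).
#' @return an object of class `arm_region`.
#' @export
arm_region <- function(chrom, start, end, name) {
  stopifnot(start >= 1, end >= start)
  structure(list(chrom = sub("^chr", "", chrom), start = start, end = end,
                 name = name),
            class = "arm_region")
}

#' Canonical 1p and 19q regions (hg19)
#'
#' The regions defining arm deletion for co-deletion calling:
#' chr1:1-125,000,000 (1p) and chr19:26,500,001-59,128,983 (19q).
#'
#' @return named list of two [arm_region()] objects, `"1p"` and `"19q"`.
#' @export
codel_regions <- function() {
  list("1p" = arm_region("1", 1, 125000000, "1p"),
       "19q" = arm_region("19", 26500001, 59128983, "19q"))
}

# centered running mean with truncated windows at the edges
running_mean <- function(v, window) {
  n <- length(v)
  window <- min(as.integer(window), n)
  if (window <= 1L) return(v)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (window - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

longest_run <- function(flag) {
  if (!length(flag) || !any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Rule-based arm-deletion call
#'
#' A bin belongs to the region iff its midpoint falls inside it (bins
#' outside the region never influence the call). The in-region log2
#' signal is smoothed with a centered running mean of `smooth_window` bins
#' (`1` disables smoothing); a smoothed bin counts as deleted when it is
#' at or below `del_log2`. The arm is called deleted ("complete segmental
#' loss") iff at least `min_bins` bins fall in the region, the deleted
#' fraction is at least `min_deleted_frac`, and the longest run of
#' consecutive non-deleted bins is at most `max_normal_run`. Partial
#' segmental loss therefore yields a negative call.
#'
#' The thresholds are calibrated for heterozygous arm loss at tumor purity
#' down to ~0.6 (expected log2 about -0.33 to -0.6) with per-bin noise up
#' to ~0.2; all are exposed.
#'
#' @param profile a [cn_profile()].
#' @param region an [arm_region()].
#' @param del_log2 deletion threshold on the smoothed log2 signal.
#' @param min_deleted_frac minimum fraction of in-region bins deleted.
#' @param max_normal_run maximum tolerated run of consecutive non-deleted
#'   in-region bins.
#' @param min_bins minimum in-region bin support; fewer bins yield a
#'   negative call with a warning.
#' @param smooth_window running-mean window (bins, odd recommended).
#' @return an object of class `arm_call`: `region`, `n_bins`, `n_deleted`,
#'   `deleted_fraction`, `longest_normal_run`, `call`.
#' @export
call_arm <- function(profile, region, del_log2 = -0.2,
                     min_deleted_frac = 0.9, max_normal_run = 50L,
                     min_bins = 10L, smooth_window = 21L) {
  stopifnot(inherits(profile, "cn_profile"), inherits(region, "arm_region"))
  b <- profile$bins
  mid <- (b$start + b$end) / 2           # 0-based midpoint
  lo <- region$start - 1                 # convert region to 0-based half-open
  hi <- region$end
  in_reg <- b$chrom == region$chrom & mid >= lo & mid < hi
  v <- b$log2[in_reg]
  n <- length(v)
  if (n < min_bins) {
    if (n > 0)
      warning(sprintf("arm %s: only %d in-region bin(s) (< %d); calling negative",
                      region$name, n, min_bins))
    return(structure(list(region = region, n_bins = n,
                          n_deleted = if (n) sum(v <= del_log2) else 0L,
                          deleted_fraction = if (n) mean(v <= del_log2) else NA_real_,
                          longest_normal_run = if (n) longest_run(v > del_log2) else 0L,
                          call = FALSE),
                     class = "arm_call"))
  }
  sm <- running_mean(v, smooth_window)
  deleted <- sm <= del_log2
  structure(list(region = region,
                 n_bins = n,
                 n_deleted = sum(deleted),
                 deleted_fraction = mean(deleted),
                 longest_normal_run = longest_run(!deleted),
                 call = mean(deleted) >= min_deleted_frac &&
                   longest_run(!deleted) <= max_normal_run),
            class = "arm_call")
}

#' @export
print.arm_call <- function(x, ...) {
  cat(sprintf(
    "<arm_call> %s: %s (%d bins, %.1f%% deleted, longest normal run %d)\n",
    x$region$name, if (x$call) "DELETED" else "not deleted",
    x$n_bins, 100 * (if (is.na(x$deleted_fraction)) 0 else x$deleted_fraction),
    x$longest_normal_run))
  invisible(x)
}

#' 1p/19q co-deletion from the two arm calls
#'
#' @param call_1p an [call_arm()] result for region `"1p"`.
#' @param call_19q an [call_arm()] result for region `"19q"`.
#' @return `TRUE` iff both arms are called deleted.
#' @export
call_codeletion <- function(call_1p, call_19q) {
  stopifnot(inherits(call_1p, "arm_call"), inherits(call_19q, "arm_call"))
  if (!identical(call_1p$region$name, "1p") ||
      !identical(call_19q$region$name, "19q"))
    stop(sprintf("expected arm calls for 1p and 19q, got %s and %s",
                 call_1p$region$name, call_19q$region$name))
  isTRUE(call_1p$call) && isTRUE(call_19q$call)
}

#' Per-sample arm calls and co-deletion
#'
#' Convenience wrapper running [call_arm()] on both canonical regions.
#'
#' @param profile a [cn_profile()].
#' @param regions list as returned by [codel_regions()].
#' @param ... thresholds passed to [call_arm()].
#' @return one-row data.frame: `sample_id`, `n_bins_1p`, `frac_del_1p`,
#'   `call_1p`, `n_bins_19q`, `frac_del_19q`, `call_19q`, `codeletion`.
#' @export
call_sample <- function(profile, regions = codel_regions(), ...) {
  c1 <- call_arm(profile, regions[["1p"]], ...)
  c19 <- call_arm(profile, regions[["19q"]], ...)
  data.frame(sample_id = profile$sample_id,
             n_bins_1p = c1$n_bins,
             frac_del_1p = c1$deleted_fraction,
             call_1p = c1$call,
             n_bins_19q = c19$n_bins,
             frac_del_19q = c19$deleted_fraction,
             call_19q = c19$call,
             codeletion = call_codeletion(c1, c19),
             stringsAsFactors = FALSE)
}

#' FISH nucleus counts
#'
#' @param target integer vector of target-probe signals per nucleus.
#' @param control integer vector of control-probe signals per nucleus.
#' @return an object of class `fish_counts`.
#' @export
fish_counts <- function(target, control) {
  stopifnot(length(target) == length(control),
            all(target >= 0), all(control >= 0),
            all(target == floor(target)), all(control == floor(control)))
  structure(data.frame(target = as.integer(target),
                       control = as.integer(control)),
            class = c("fish_counts", "data.frame"))
}

#' Interpret FISH signal counts
#'
#' Nuclei with fewer than two control signals are not evaluable and are
#' excluded. A deletion is called when the combined target-to-control
#' signal ratio (sum of targets / sum of controls over evaluable nuclei)
#' is below 0.75, or when more than 50% of evaluable nuclei show 0 or 1
#' target signals. Both thresholds are strict (< and >) as stated.
#' Nuclei with more than one target signal but disproportionate
#' target/control counts (3/2, 4/3, ...) are tallied as `n_imbalance`
#' but do not enter the deletion call.
#'
#' @param counts a [fish_counts()] (or data.frame with `target`,
#'   `control`).
#' @param min_nuclei minimum evaluable nuclei required (default 50);
#'   below this the result is flagged insufficient and `deletion_call`
#'   is `NA`.
#' @param ratio_cutoff combined-ratio threshold (default 0.75).
#' @param low_target_cutoff low-target nucleus-fraction threshold
#'   (default 0.5).
#' @return an object of class `fish_result`: `n_evaluable`,
#'   `combined_ratio`, `frac_low_target`, `n_imbalance`, `sufficient`,
#'   `deletion_call`.
#' @export
interpret_fish <- function(counts, min_nuclei = 50L, ratio_cutoff = 0.75,
                           low_target_cutoff = 0.5) {
  stopifnot(is.data.frame(counts),
            all(c("target", "control") %in% names(counts)))
  ev <- counts[counts$control >= 2L, , drop = FALSE]
  n <- nrow(ev)
  if (n < min_nuclei) {
    return(structure(list(n_evaluable = n, combined_ratio = NA_real_,
                          frac_low_target = NA_real_,
                          n_imbalance = NA_integer_,
                          sufficient = FALSE, deletion_call = NA),
                     class = "fish_result"))
  }
  ratio <- sum(ev$target) / sum(ev$control)
  frac_low <- mean(ev$target <= 1L)
  imbal <- sum(ev$target > 1L & ev$target < ev$control)
  structure(list(n_evaluable = n,
                 combined_ratio = ratio,
                 frac_low_target = frac_low,
                 n_imbalance = as.integer(imbal),
                 sufficient = TRUE,
                 deletion_call = ratio < ratio_cutoff ||
                   frac_low > low_target_cutoff),
            class = "fish_result")
}

#' @export
print.fish_result <- function(x, ...) {
  if (!x$sufficient) {
    cat(sprintf("<fish_result> insufficient nuclei (%d evaluable)\n",
                x$n_evaluable))
  } else {
    cat(sprintf(
      "<fish_result> %s (%d nuclei, ratio %.3f, low-target %.1f%%, imbalances %d)\n",
      if (x$deletion_call) "DELETION" else "no deletion",
      x$n_evaluable, x$combined_ratio, 100 * x$frac_low_target,
      x$n_imbalance))
  }
  invisible(x)
}
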