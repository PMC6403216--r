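# Chromosome-signal vectorization: a chromosome's bins, in relative order,
# become a fixed-length vector (1869 for chr1, 649 for chr19). Genomic
# start/length information is intentionally discarded; only the bin order
# matters. Dense array profiles are harmonized onto the same lengths by
# contiguous group averaging; inputs shorter than the target are linearly
# interpolated (a path real panel/array data never exercises).

#' Extract a chromosome's ordered log2 signal
#'
#' @param profile a [cn_profile()].
#' @param chrom chromosome name (without `"chr"` prefix).
#' @return numeric vector of log2 values in bin relative order.
#' @export
extract_chrom_signal <- function(profile, chrom) {
  stopifnot(inherits(profile, "cn_profile"))
  chrom <- sub("^chr", "", chrom)
  v <- profile$bins$log2[profile$bins$chrom == chrom]
  if (!length(v))
    stop(sprintf("profile '%s' has no bins on chromosome %s",
                 profile$sample_id, chrom))
  v
}

#' Partition n ordered items into g contiguous groups
#'
#' Item i (0-based) is assigned to group `floor(i * g / n)`: groups are
#' contiguous, disjoint, cover all items in order, and sizes differ by at
#' most one.
#'
#' @param n number of items (`n >= g`).
#' @param g number of groups (`g >= 1`).
#' @return data.frame with one row per group: `group` (1-based), `start`,
#'   `end` (1-based inclusive item indices), `size`.
#' @export
group_partition <- function(n, g) {
  n <- as.integer(n); g <- as.integer(g)
  if (g < 1) stop("g must be >= 1")
  if (n < g) stop(sprintf("cannot partition %d items into %d groups", n, g))
  grp <- floor((0:(n - 1)) * as.numeric(g) / n)  # 0-based group per item
  start <- which(!duplicated(grp))
  end <- c(start[-1] - 1L, n)
  data.frame(group = seq_len(g), start = start, end = end,
             size = end - start + 1L)
}

#' Reformat a signal to a fixed target length
#'
#' Longer inputs are averaged over the contiguous groups of
#' [group_partition()] (the cross-platform harmonization rule: the
#' representative value of each group is the mean log2 of its bins).
#' Inputs already at the target length pass through unchanged; shorter
#' inputs are linearly interpolated onto `target_len` equally spaced
#' points (with a message, since panel-scale data never takes this path).
#'
#' @param values numeric vector (finite, length >= 1).
#' @param target_len desired output length.
#' @return numeric vector of length `target_len`.
#' @export
reformat_signal <- function(values, target_len) {
  target_len <- as.integer(target_len)
  n <- length(values)
  if (n == 0) stop("cannot reformat an empty signal")
  if (any(!is.finite(values))) stop("signal contains non-finite values")
  if (n == target_len) return(as.numeric(values))
  if (n > target_len) {
    part <- group_partition(n, target_len)
    cs <- cumsum(c(0, values))
    return((cs[part$end + 1L] - cs[part$start]) / part$size)
  }
  message(sprintf("reformat_signal: interpolating %d values up to %d", n,
                  target_len))
  if (n == 1) return(rep(as.numeric(values), target_len))
  stats::approx(x = seq(0, 1, length.out = n), y = values,
                xout = seq(0, 1, length.out = target_len))$y
}

#' Feature-vector set for one or more samples
#'
#' Holds the fixed-length chr1 (`x1`) and chr19 (`x2`) signal matrices and
#' an optional class label per sample (`codel` = class 1 = 1p/19q
#' co-deletion; `no_codel` = class 2).
#'
#' @param sample_id character vector of sample identifiers.
#' @param x1 numeric matrix (samples x chr1 length).
#' @param x2 numeric matrix (samples x chr19 length).
#' @param label optional character/factor of class labels (NA allowed).
#' @return an object of class `codel_features`.
#' @export
codel_features <- function(sample_id, x1, x2, label = NA) {
  x1 <- rbind(x1); x2 <- rbind(x2)  # promote vectors to one-row matrices
  n <- length(sample_id)
  stopifnot(nrow(x1) == n, nrow(x2) == n)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  if (any(!is.finite(x1)) || any(!is.finite(x2)))
    stop("feature values must be finite")
  label <- factor(as.character(label), levels = class_levels())
  if (length(label) == 1) label <- rep(label, n)
  stopifnot(length(label) == n)
  structure(list(sample_id = as.character(sample_id),
                 x1 = unname(x1), x2 = unname(x2), label = label),
            class = "codel_features")
}

#' @export
print.codel_features <- function(x, ...) {
  cat(sprintf("<codel_features> %d sample(s); x1: %d, x2: %d; labels: %s\n",
              length(x$sample_id), ncol(x$x1), ncol(x$x2),
              paste(sprintf("%s=%d", class_levels(),
                            table(x$label)[class_levels()]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.codel_features <- function(x) length(x$sample_id)

#' Combine or subset feature sets
#'
#' @param ... `codel_features` objects with matching vector lengths.
#' @return a combined `codel_features`.
#' @export
bind_features <- function(...) {
  fs <- list(...)
  stopifnot(all(vapply(fs, inherits, TRUE, "codel_features")))
  codel_features(unlist(lapply(fs, `[[`, "sample_id")),
                 do.call(rbind, lapply(fs, `[[`, "x1")),
                 do.call(rbind, lapply(fs, `[[`, "x2")),
                 unlist(lapply(fs, function(f) as.character(f$label))))
}

#' @export
`[.codel_features` <- function(x, i, ...) {
  codel_features(x$sample_id[i], x$x1[i, , drop = FALSE],
                 x$x2[i, , drop = FALSE], as.character(x$label)[i])
}

# 0-based class index used by the C++ engine: codel = 0, no_codel = 1
feature_classes <- function(features) {
  as.integer(features$label) - 1L
}

#' Featurize a copy-number profile
#'
#' Extracts the chr1 and chr19 ordered log2 signals and reformats them to
#' the canonical lengths (1869 and 649). Values are clipped to
#' `[-clip, clip]` to bound extreme bins (set `clip = Inf` to disable); no
#' other normalization is applied.
#'
#' @param profile a [cn_profile()] with bins on chromosomes 1 and 19.
#' @param label optional class label (`"codel"` / `"no_codel"`).
#' @param target_lens output lengths for chr1 and chr19.
#' @param clip symmetric clipping bound on log2 values (default 3).
#' @return a one-sample [codel_features()].
#' @export
featurize <- function(profile, label = NA, target_lens = c(1869L, 649L),
                      clip = 3) {
  stopifnot(length(target_lens) == 2)
  v1 <- reformat_signal(extract_chrom_signal(profile, "1"), target_lens[1])
  v2 <- reformat_signal(extract_chrom_signal(profile, "19"), target_lens[2])
  if (is.finite(clip)) {
    v1 <- pmin(pmax(v1, -clip), clip)
    v2 <- pmin(pmax(v2, -clip), clip)
  }
  codel_features(profile$sample_id, matrix(v1, 1), matrix(v2, 1), label)
}

#' Featurize a list of profiles
#'
#' @param profiles list of [cn_profile()] objects.
#' @param labels optional vector of class labels (recycled NA if absent).
#' @inheritParams featurize
#' @return a [codel_features()] with one row per profile.
#' @export
featurize_profiles <- function(profiles, labels = NULL,
                               target_lens = c(1869L, 649L), clip = 3) {
  if (!length(profiles)) stop("no profiles given")
  if (is.null(labels)) labels <- rep(NA_character_, length(profiles))
  stopifnot(length(labels) == length(profiles))
  do.call(bind_features, Map(function(p, l)
    featurize(p, l, target_lens = target_lens, clip = clip),
    profiles, labels))
}

#' Persist / load a feature matrix as TSV
#'
#' One row per sample: `sample_id`, `label`, `x1_0001..`, `x2_0001..`.
#'
#' @param features a [codel_features()].
#' @param path file path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns a [codel_features()].
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "codel_features"))
  x1 <- features$x1; x2 <- features$x2
  colnames(x1) <- sprintf("x1_%04d", seq_len(ncol(x1)))
  colnames(x2) <- sprintf("x2_%04d", seq_len(ncol(x2)))
  out <- data.frame(sample_id = features$sample_id,
                    label = as.character(features$label),
                    x1, x2, stringsAsFactors = FALSE)
  out$label[is.na(out$label)] <- "NA"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  c1 <- grep("^x1_", names(tab)); c2 <- grep("^x2_", names(tab))
  if (!length(c1) || !length(c2))
    stop(path, ": not a feature matrix (missing x1_/x2_ columns)")
  codel_features(as.character(tab$sample_id),
                 as.matrix(tab[, c1, drop = FALSE]),
                 as.matrix(tab[, c2, drop = FALSE]),
                 ifelse(tab$label == "NA", NA_character_, tab$label))
}
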