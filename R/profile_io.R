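# Per-bin copy-number profile container and TSV readers/writers.
#
# Internal convention: coordinates are 0-based half-open (the CNR table
# convention); "chr" prefixes are stripped on read and never emitted.
# Bins with non-finite log2 are rejected rather than imputed.

class_levels <- function() c("codel", "no_codel")

#' Copy-number profile of one sample
#'
#' An ordered collection of genomic bins, each carrying a log2 copy ratio.
#' Bins are sorted by (chromosome, start) and must be non-overlapping and
#' strictly increasing within a chromosome; the relative order of bins
#' within a chromosome is the index used by downstream vectorization.
#'
#' @param sample_id sample identifier.
#' @param bins data.frame with columns `chrom` (character), `start`
#'   (integer-valued, 0-based half-open start), `end` (exclusive), `log2`
#'   (finite numeric); optional `label` (bin/gene/probe id), `depth` and
#'   `weight` (non-negative, default 1).
#' @param genome_build reference tag (default `"hg19"`).
#' @return an object of class `cn_profile`.
#' @export
cn_profile <- function(sample_id, bins, genome_build = "hg19") {
  stopifnot(is.character(sample_id), length(sample_id) == 1,
            is.data.frame(bins))
  need <- c("chrom", "start", "end", "log2")
  miss <- setdiff(need, names(bins))
  if (length(miss))
    stop("bins lack required column(s): ", paste(miss, collapse = ", "))
  bins$chrom <- sub("^chr", "", as.character(bins$chrom))
  bins$start <- as.numeric(bins$start)
  bins$end <- as.numeric(bins$end)
  bins$log2 <- as.numeric(bins$log2)
  if (is.null(bins$label)) bins$label <- rep("-", nrow(bins))
  if (is.null(bins$weight)) bins$weight <- rep(1, nrow(bins))
  if (is.null(bins$depth)) bins$depth <- rep(NA_real_, nrow(bins))
  bins <- bins[, c("chrom", "start", "end", "label", "log2", "depth", "weight")]
  if (nrow(bins)) {
    if (any(!is.finite(bins$log2)))
      stop("non-finite log2 value(s) in bins ",
           paste(utils::head(which(!is.finite(bins$log2)), 3), collapse = ", "))
    if (any(bins$start >= bins$end))
      stop("bin start must be < end (violated at row ",
           which(bins$start >= bins$end)[1], ")")
    if (any(bins$weight < 0)) stop("bin weights must be >= 0")
    bins <- bins[order(bins$chrom, bins$start, bins$end), , drop = FALSE]
    rownames(bins) <- NULL
    by_chr <- split(seq_len(nrow(bins)), bins$chrom)
    for (ix in by_chr) {
      if (length(ix) > 1) {
        s <- bins$start[ix]; e <- bins$end[ix]
        bad <- which(s[-1] < e[-length(e)])
        if (length(bad))
          stop(sprintf(
            "overlapping or duplicate bins on chromosome %s near start %s",
            bins$chrom[ix[1]], format(s[bad[1] + 1], scientific = FALSE)))
      }
    }
  }
  structure(list(sample_id = sample_id, bins = bins,
                 genome_build = genome_build),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  tab <- table(x$bins$chrom)
  cat(sprintf("<cn_profile> %s (%s): %d bins on %d chromosome(s)\n",
              x$sample_id, x$genome_build, nrow(x$bins), length(tab)))
  if (length(tab))
    cat("  ", paste(sprintf("chr%s: %d", names(tab), tab), collapse = ", "),
        "\n")
  invisible(x)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  tab
}

# parse a numeric column, reporting the 1-based file line of the first failure
parse_num <- function(x, col, path) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !(is.na(x) | x == "" | x == "NA"))
  bad <- c(bad, which(is.na(x) | x == ""))
  if (length(bad))
    stop(sprintf("%s: non-numeric %s value '%s' on line %d",
                 path, col, x[min(bad)], min(bad) + 1L))
  v
}

#' Read a per-bin copy-ratio table (CNR dialect)
#'
#' Tab-delimited with a header containing at least `chromosome`, `start`,
#' `end` and `log2`; optional `gene`, `depth` and `weight` columns are
#' preserved (missing `weight` defaults to 1). Chromosome names are
#' normalized by stripping a leading `"chr"`; rows are sorted by
#' (chromosome, start). Malformed rows, non-finite log2 values or
#' overlapping bins raise an error naming the offending line.
#'
#' @param path file path.
#' @param sample_id sample identifier to attach.
#' @param genome_build reference tag.
#' @return a [cn_profile()].
#' @export
read_cnr <- function(path, sample_id, genome_build = "hg19") {
  tab <- read_tsv_checked(path, c("chromosome", "start", "end", "log2"))
  n <- nrow(tab)
  bins <- data.frame(
    chrom = as.character(tab$chromosome),
    start = if (n) parse_num(tab$start, "start", path) else numeric(0),
    end = if (n) parse_num(tab$end, "end", path) else numeric(0),
    log2 = if (n) parse_num(tab$log2, "log2", path) else numeric(0),
    stringsAsFactors = FALSE)
  if (n && any(!is.finite(bins$log2)))
    stop(sprintf("%s: non-finite log2 on line %d", path,
                 which(!is.finite(bins$log2))[1] + 1L))
  if (!is.null(tab$gene)) bins$label <- as.character(tab$gene)
  if (!is.null(tab$depth) && n) bins$depth <- parse_num(tab$depth, "depth", path)
  if (!is.null(tab$weight) && n)
    bins$weight <- parse_num(tab$weight, "weight", path)
  cn_profile(sample_id, bins, genome_build)
}

#' Write a profile in the CNR dialect
#'
#' Round-trips with [read_cnr()]: `read_cnr(write_cnr(p))` equals `p` up
#' to floating-point text precision. The `depth` column is emitted only
#' when any bin carries one.
#'
#' @param profile a [cn_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cnr <- function(profile, path) {
  stopifnot(inherits(profile, "cn_profile"))
  b <- profile$bins
  out <- data.frame(chromosome = b$chrom,
                    start = format(b$start, scientific = FALSE, trim = TRUE),
                    end = format(b$end, scientific = FALSE, trim = TRUE),
                    gene = b$label,
                    log2 = format(b$log2, digits = 10, scientific = FALSE,
                                  trim = TRUE),
                    stringsAsFactors = FALSE)
  if (nrow(b) && any(!is.na(b$depth)))
    out$depth <- format(b$depth, digits = 10, scientific = FALSE, trim = TRUE)
  out$weight <- if (nrow(b))
    format(b$weight, digits = 10, scientific = FALSE, trim = TRUE)
  else character(0)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a SNP-array probe table
#'
#' Tab-delimited columns `chromosome`, `position`, `log2`. Each probe
#' becomes a unit-width bin (`start = position`, `end = position + 1`,
#' weight 1); probes are sorted by position and duplicate positions raise
#' an error.
#'
#' @inheritParams read_cnr
#' @return a [cn_profile()].
#' @export
read_array_probes <- function(path, sample_id, genome_build = "hg19") {
  tab <- read_tsv_checked(path, c("chromosome", "position", "log2"))
  n <- nrow(tab)
  pos <- if (n) parse_num(tab$position, "position", path) else numeric(0)
  bins <- data.frame(
    chrom = as.character(tab$chromosome),
    start = pos, end = pos + 1,
    log2 = if (n) parse_num(tab$log2, "log2", path) else numeric(0),
    stringsAsFactors = FALSE)
  if (n && any(!is.finite(bins$log2)))
    stop(sprintf("%s: non-finite log2 on line %d", path,
                 which(!is.finite(bins$log2))[1] + 1L))
  cn_profile(sample_id, bins, genome_build)
}

#' Write a profile in the array-probe dialect
#'
#' Emits `chromosome`, `position`, `log2` using each bin's start as the
#' probe position.
#'
#' @inheritParams write_cnr
#' @return `path`, invisibly.
#' @export
write_array_probes <- function(profile, path) {
  stopifnot(inherits(profile, "cn_profile"))
  b <- profile$bins
  out <- data.frame(chromosome = b$chrom,
                    position = format(b$start, scientific = FALSE,
                                      trim = TRUE),
                    log2 = format(b$log2, digits = 10, scientific = FALSE,
                                  trim = TRUE),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample label sheet
#'
#' Tab-delimited columns `sample_id` and `label`, the latter in
#' `{codel, no_codel}` (class 1 = 1p/19q co-deletion).
#'
#' @param path file path.
#' @return data.frame with `sample_id` (character) and `label` (factor).
#' @export
read_label_sheet <- function(path) {
  tab <- read_tsv_checked(path, c("sample_id", "label"))
  bad <- which(!(tab$label %in% class_levels()))
  if (length(bad))
    stop(sprintf("%s: invalid label '%s' on line %d (expected %s)",
                 path, tab$label[bad[1]], bad[1] + 1L,
                 paste(class_levels(), collapse = "/")))
  data.frame(sample_id = as.character(tab$sample_id),
             label = factor(tab$label, levels = class_levels()),
             stringsAsFactors = FALSE)
}
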