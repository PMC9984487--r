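#' Genomic intervals with explicit coordinate conventions
#'
#' `genomic_interval()` constructs an interval in the package's internal
#' convention: 0-based, half-open `[start, end)`, tagged with a genome
#' assembly. Printed coordinates in the literature (and in this package's
#' formatted output) are 1-based inclusive, so a printed `chrN:a-b` of
#' inclusive length `b - a + 1` corresponds to `start = a - 1`, `end = b`.
#'
#' @param chrom Chromosome name, e.g. `"chr12"`.
#' @param start 0-based start (bp).
#' @param end End (bp), exclusive; must satisfy `end > start`.
#' @param assembly Genome build tag, e.g. `"mm10"`.
#' @return An object of class `genomic_interval`.
#' @examples
#' iv <- genomic_interval("chr12", 114182510, 114183025, "mm10")
#' interval_length(iv)  # 515
#' @export
genomic_interval <- function(chrom, start, end, assembly = "mm10") {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 0) {
    stop("interval bounds must be finite non-negative numbers", call. = FALSE)
  }
  if (start >= end) {
    stop(sprintf("invalid interval: start (%s) must be < end (%s)",
                 format(start, scientific = FALSE),
                 format(end, scientific = FALSE)), call. = FALSE)
  }
  structure(list(chrom = chrom, start = start, end = end, assembly = assembly),
            class = "genomic_interval")
}

#' Parse a printed 1-based inclusive coordinate string
#'
#' Accepts `"chr12:114182511-114183025"` style strings, with optional
#' thousands separators (commas), and converts to the internal 0-based
#' half-open convention.
#'
#' @param text Coordinate string `"chr<name>:<a>-<b>"`.
#' @param assembly Genome build tag attached to the result.
#' @return A [genomic_interval()].
#' @examples
#' parse_interval("chr12:114182511-114183025")            # 515 bp
#' parse_interval("chr12:113,215,000-116,045,000")        # 2,830,001 bp
#' @export
parse_interval <- function(text, assembly = "mm10") {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub(",", "", trimws(text), fixed = TRUE)
  m <- regexec("^(chr[A-Za-z0-9_.]+):([0-9]+)-([0-9]+)$", txt)
  parts <- regmatches(txt, m)[[1L]]
  if (length(parts) != 4L) {
    bad <- if (!grepl("^chr", txt)) sub(":.*$", "", txt) else txt
    stop(sprintf("cannot parse coordinate string: offending token '%s' in '%s'",
                 bad, text), call. = FALSE)
  }
  a <- as.numeric(parts[3L]); b <- as.numeric(parts[4L])
  if (a > b) {
    stop(sprintf("invalid interval '%s': start %s > end %s", text,
                 parts[3L], parts[4L]), call. = FALSE)
  }
  genomic_interval(parts[2L], a - 1, b, assembly = assembly)
}

#' Format an interval as a printed 1-based inclusive string
#' @param iv A [genomic_interval()].
#' @return `"chrN:a-b"` with 1-based inclusive bounds.
#' @export
format_interval <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  sprintf("%s:%s-%s", iv$chrom,
          format(iv$start + 1, scientific = FALSE, trim = TRUE),
          format(iv$end, scientific = FALSE, trim = TRUE))
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s (%s, %s bp)\n",
              format_interval(x), x$assembly,
              format(interval_length(x), big.mark = ",")))
  invisible(x)
}

#' Interval length in bp (half-open, equals the printed inclusive length)
#' @param iv A [genomic_interval()].
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  iv$end - iv$start
}

#' Fixed-width binning of a genomic region
#'
#' Bins are anchored at the region start by default (bin `i`, 1-based, covers
#' `[start + (i-1) * bin_size, start + i * bin_size)` clipped to the region),
#' or at absolute multiples of `bin_size` (`anchor = "genome"`), the
#' convention of genome-wide matrix dumps.
#'
#' @param region A [genomic_interval()].
#' @param bin_size Bin width in bp (default 10 kb, the working Hi-C
#'   resolution).
#' @param anchor `"region"` (default) or `"genome"`.
#' @return An object of class `binned_region` with `n_bins` and bin edge
#'   accessors.
#' @export
binned_region <- function(region, bin_size = 10000, anchor = c("region", "genome")) {
  stopifnot(inherits(region, "genomic_interval"), bin_size >= 1)
  anchor <- match.arg(anchor)
  origin <- if (anchor == "genome") floor(region$start / bin_size) * bin_size else region$start
  n_bins <- ceiling((region$end - origin) / bin_size)
  structure(list(region = region, bin_size = bin_size, n_bins = as.integer(n_bins),
                 origin = origin, anchor = anchor),
            class = "binned_region")
}

#' @export
print.binned_region <- function(x, ...) {
  cat(sprintf("<binned_region> %s, %d bins of %s bp (%s-anchored)\n",
              format_interval(x$region), x$n_bins,
              format(x$bin_size, big.mark = ","), x$anchor))
  invisible(x)
}

#' Bin boundaries of a binned region
#'
#' @param binned A [binned_region()].
#' @return A two-column matrix of half-open `[start, end)` bin spans in bp,
#'   clipped to the region.
#' @export
bin_bounds <- function(binned) {
  stopifnot(inherits(binned, "binned_region"))
  i <- seq_len(binned$n_bins) - 1L
  s <- pmax(binned$origin + i * binned$bin_size, binned$region$start)
  e <- pmin(binned$origin + (i + 1L) * binned$bin_size, binned$region$end)
  cbind(start = s, end = e)
}

#' Map an interval to the bins it overlaps
#'
#' @param iv A [genomic_interval()] on the same chromosome as the binning.
#' @param binned A [binned_region()].
#' @return Sorted integer vector of 1-based bin indices whose half-open span
#'   intersects `iv`.
#' @export
interval_to_bins <- function(iv, binned) {
  stopifnot(inherits(iv, "genomic_interval"), inherits(binned, "binned_region"))
  if (!identical(iv$chrom, binned$region$chrom)) {
    stop(sprintf("interval chromosome %s does not match region chromosome %s",
                 iv$chrom, binned$region$chrom), call. = FALSE)
  }
  b <- bin_bounds(binned)
  hit <- which(b[, "start"] < iv$end & b[, "end"] > iv$start)
  if (length(hit) == 0L) {
    stop(sprintf("interval %s does not overlap binned region %s",
                 format_interval(iv), format_interval(binned$region)),
         call. = FALSE)
  }
  hit
}

#' Read element intervals from a BED file
#'
#' Thin wrapper over `rtracklayer::import()` returning the package's interval
#' type. BED is 0-based half-open on disk, matching the internal convention.
#'
#' @param path Path to a 3+ column BED file.
#' @param assembly Genome build tag attached to each interval.
#' @return Named list of [genomic_interval()] (names from the BED name column
#'   when present).
#' @export
read_bed <- function(path, assembly = "mm10") {
  gr <- rtracklayer::import(path, format = "BED")
  out <- lapply(seq_along(gr), function(i) {
    genomic_interval(as.character(GenomicRanges::seqnames(gr)[i]),
                     GenomicRanges::start(gr)[i] - 1L,
                     GenomicRanges::end(gr)[i],
                     assembly = assembly)
  })
  nm <- gr$name
  if (!is.null(nm)) names(out) <- nm
  out
}
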