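#' Binned contact matrices
#'
#' A `contact_matrix` holds a square symmetric matrix of contact values over
#' a [binned_region()], a per-bin validity mask, and a `kind` tag recording
#' where in the normalization pipeline the values sit: `"raw"` counts,
#' `"kr"` (Knight-Ruiz balanced), `"quantile_normalized"` (against a polymer
#' null target) or `"difference"` (subtraction of two quantile-normalized
#' maps; the only kind allowed negative values). Entries of masked bins are
#' stored as `NA`.
#'
#' @param values `n_bins x n_bins` numeric matrix, symmetric.
#' @param binned A [binned_region()] with `n_bins` matching `values`.
#' @param kind One of `"raw"`, `"kr"`, `"quantile_normalized"`,
#'   `"difference"`.
#' @param mask Logical vector, `TRUE` for valid bins. Default all valid.
#' @param sym_tol Relative tolerance for the symmetry check.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, binned, kind = c("raw", "kr", "quantile_normalized", "difference"),
                           mask = NULL, sym_tol = 1e-8) {
  kind <- match.arg(kind)
  stopifnot(inherits(binned, "binned_region"), is.matrix(values))
  n <- binned$n_bins
  if (nrow(values) != n || ncol(values) != n) {
    stop(sprintf("matrix is %dx%d but region has %d bins",
                 nrow(values), ncol(values), n), call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(is.logical(mask), length(mask) == n)
  asym <- max(abs(values - t(values)), na.rm = TRUE)
  scale <- max(abs(values), na.rm = TRUE)
  if (is.finite(asym) && asym > sym_tol * max(scale, 1)) {
    stop(sprintf("matrix is not symmetric: max |A - t(A)| = %g", asym),
         call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (kind != "difference" && any(values < 0, na.rm = TRUE)) {
    stop(sprintf("negative entries are not allowed for kind = '%s' (min = %g)",
                 kind, min(values, na.rm = TRUE)), call. = FALSE)
  }
  if (any(!mask)) {
    values[!mask, ] <- NA_real_
    values[, !mask] <- NA_real_
  }
  structure(list(values = values, binned = binned, kind = kind, mask = mask),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s | %d bins x %s bp | kind = %s | %d masked\n",
              format_interval(x$binned$region), x$binned$n_bins,
              format(x$binned$bin_size, big.mark = ","), x$kind, sum(!x$mask)))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$values)

upper_tri_idx <- function(n, min_separation = 0L) {
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  ij[ij[, 2L] - ij[, 1L] >= min_separation, , drop = FALSE]
}

#' Extract unmasked upper-triangle cells beyond a diagonal offset
#'
#' @param M A [contact_matrix()].
#' @param min_separation Minimum `|i - j|` (in bins) to include; default 2
#'   excludes the diagonal and bonded neighbours.
#' @return Data frame with columns `i`, `j`, `value` (unmasked cells only).
#' @export
matrix_cells <- function(M, min_separation = 2L) {
  stopifnot(inherits(M, "contact_matrix"))
  ij <- upper_tri_idx(M$binned$n_bins, min_separation)
  keep <- M$mask[ij[, 1L]] & M$mask[ij[, 2L]]
  ij <- ij[keep, , drop = FALSE]
  data.frame(i = ij[, 1L], j = ij[, 2L], value = M$values[ij])
}

#' Write a contact matrix as dense TSV
#'
#' The dialect is a single header line
#' `#region=chr:a-b;bin_size=N;assembly=mm10;kind=raw` (region printed
#' 1-based inclusive) followed by `n_bins` tab-separated rows. Values are
#' written with 17 significant digits so a read/write round trip is
#' bit-exact; masked entries are `NA`.
#'
#' @param M A [contact_matrix()].
#' @param path Output file path.
#' @export
write_contact_matrix <- function(M, path) {
  stopifnot(inherits(M, "contact_matrix"))
  hdr <- sprintf("#region=%s;bin_size=%d;assembly=%s;kind=%s",
                 format_interval(M$binned$region), M$binned$bin_size,
                 M$binned$region$assembly, M$kind)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  txt <- apply(M$values, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, con)
  invisible(path)
}

#' Read a dense TSV contact matrix
#'
#' @param path File written by [write_contact_matrix()] (or matching its
#'   header dialect).
#' @return A [contact_matrix()]; the per-bin mask is inferred from all-`NA`
#'   rows.
#' @export
read_contact_matrix <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#")) stop("missing '#region=...' header line", call. = FALSE)
  fields <- strsplit(sub("^#", "", hdr), ";", fixed = TRUE)[[1L]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  need <- c("region", "bin_size", "assembly", "kind")
  if (!all(need %in% keys)) {
    stop(sprintf("header must declare %s", paste(need, collapse = ", ")), call. = FALSE)
  }
  region <- parse_interval(vals[keys == "region"], assembly = vals[keys == "assembly"])
  bin_size <- as.numeric(vals[keys == "bin_size"])
  kind <- vals[keys == "kind"]
  vm <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L,
                                    colClasses = "numeric", header = FALSE))
  dimnames(vm) <- NULL
  binned <- binned_region(region, bin_size = bin_size)
  if (nrow(vm) != binned$n_bins) {
    stop(sprintf("bin-size mismatch: %d rows but region %s at %d bp implies %d bins",
                 nrow(vm), format_interval(region), bin_size, binned$n_bins),
         call. = FALSE)
  }
  mask <- !apply(vm, 1L, function(r) all(is.na(r)))
  contact_matrix(vm, binned, kind = kind, mask = mask)
}

#' Read a cooler-style binned matrix (bins + pixels tables)
#'
#' Accepts the cooler schema as two plain TSVs: a bins table
#' (`chrom`, `start`, `end`; 0-based half-open, defining its own absolute
#' anchoring) and an upper-triangle pixels table (`bin1_id`, `bin2_id`,
#' `count`; 0-based ids). Pixels absent from the table are zero.
#'
#' @param bins_path,pixels_path Paths to the two tables (with header lines).
#' @param assembly Genome build tag.
#' @param kind Value kind, default `"raw"`.
#' @return A [contact_matrix()].
#' @export
read_cooler_tsv <- function(bins_path, pixels_path, assembly = "mm10", kind = "raw") {
  bins <- utils::read.table(bins_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  px <- utils::read.table(pixels_path, header = TRUE, sep = "\t")
  stopifnot(all(c("chrom", "start", "end") %in% names(bins)),
            all(c("bin1_id", "bin2_id", "count") %in% names(px)))
  if (length(unique(bins$chrom)) != 1L) {
    stop("bins table must cover a single chromosome region", call. = FALSE)
  }
  bin_size <- max(bins$end - bins$start)
  region <- genomic_interval(bins$chrom[1L], min(bins$start), max(bins$end), assembly)
  binned <- binned_region(region, bin_size = bin_size,
                          anchor = if (bins$start[1L] %% bin_size == 0) "genome" else "region")
  n <- nrow(bins)
  if (binned$n_bins != n) {
    stop(sprintf("bins table has %d rows but region/bin size imply %d bins", n, binned$n_bins),
         call. = FALSE)
  }
  vm <- matrix(0, n, n)
  i <- px$bin1_id + 1L; j <- px$bin2_id + 1L
  if (any(i < 1L | i > n | j < 1L | j > n)) stop("pixel bin id out of range", call. = FALSE)
  vm[cbind(i, j)] <- px$count
  vm[cbind(j, i)] <- px$count
  contact_matrix(vm, binned, kind = kind)
}

#' Write a contact matrix in the cooler-style two-table layout
#'
#' @param M A [contact_matrix()].
#' @param bins_path,pixels_path Output paths.
#' @export
write_cooler_tsv <- function(M, bins_path, pixels_path) {
  stopifnot(inherits(M, "contact_matrix"))
  b <- bin_bounds(M$binned)
  bins <- data.frame(chrom = M$binned$region$chrom, start = b[, "start"], end = b[, "end"])
  utils::write.table(bins, bins_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cells <- matrix_cells(M, min_separation = 0L)
  cells <- cells[cells$value != 0, , drop = FALSE]
  px <- data.frame(bin1_id = cells$i - 1L, bin2_id = cells$j - 1L, count = cells$value)
  utils::write.table(px, pixels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pixels_path)
}
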