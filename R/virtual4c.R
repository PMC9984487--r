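#' Virtual 4C viewpoint profile
#'
#' Extracts the matrix row at the viewpoint bin (mean of rows when the
#' viewpoint spans several bins) and smooths it with a centred running
#' window (default 30 kb window sliding in 10 kb steps, i.e. a 3-bin box
#' filter truncated at the region edges).
#'
#' @param M A [contact_matrix()] of kind `"kr"` or `"quantile_normalized"`.
#' @param viewpoint A [genomic_interval()] inside the matrix region.
#' @param window Smoothing window in bp; must be an odd multiple of the bin
#'   size (default 3 bins).
#' @return An object of class `viewpoint_profile` with the smoothed `track`
#'   (one value per bin), the raw `base` track, the viewpoint bins, and the
#'   binning.
#' @export
viewpoint_profile <- function(M, viewpoint, window = 3L * M$binned$bin_size) {
  stopifnot(inherits(M, "contact_matrix"), inherits(viewpoint, "genomic_interval"))
  if (!M$kind %in% c("kr", "quantile_normalized")) {
    stop("viewpoint_profile expects a KR-balanced or quantile-normalized matrix",
         call. = FALSE)
  }
  w_bins <- window / M$binned$bin_size
  if (w_bins != round(w_bins) || w_bins %% 2 != 1) {
    stop("window must be an odd multiple of the bin size", call. = FALSE)
  }
  vp_bins <- interval_to_bins(viewpoint, M$binned)
  base <- if (length(vp_bins) == 1L) M$values[vp_bins, ] else colMeans(M$values[vp_bins, , drop = FALSE])
  n <- M$binned$n_bins
  half <- (w_bins - 1) / 2
  track <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    v <- base[lo:hi]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  structure(list(viewpoint = viewpoint, viewpoint_bins = vp_bins, base = base,
                 track = track, window = window, step = M$binned$bin_size,
                 binned = M$binned),
            class = "viewpoint_profile")
}

#' @export
print.viewpoint_profile <- function(x, ...) {
  cat(sprintf("<viewpoint_profile> viewpoint %s (bin %s) | %d bins | window %s bp\n",
              format_interval(x$viewpoint), paste(x$viewpoint_bins, collapse = ","),
              length(x$track), format(x$window, big.mark = ",")))
  invisible(x)
}

vp_excluded_bins <- function(profile) {
  n <- length(profile$track)
  sort(unique(pmin(pmax(rep(profile$viewpoint_bins, each = 3L) + (-1L):1L, 1L), n)))
}

#' Call high-frequency viewpoint contacts across two replicates
#'
#' A bin is called at a given percentile iff its smoothed profile value is
#' strictly above the `(100 - percentile)`-th percentile of that replicate's
#' own profile population in BOTH replicates. The viewpoint bin and its
#' immediate neighbours are excluded from the population and from calls.
#'
#' @param profile_rep1,profile_rep2 [viewpoint_profile()] objects for the
#'   same viewpoint and binning.
#' @param percentiles Percentile cut-offs (default `c(15, 25)`, the
#'   star/circle annotation convention).
#' @return Object of class `peak_calls`: a named list of sorted bin-index
#'   vectors (`top15`, `top25`, ...), plus the excluded bins.
#' @export
call_high_frequency <- function(profile_rep1, profile_rep2, percentiles = c(15, 25)) {
  stopifnot(inherits(profile_rep1, "viewpoint_profile"),
            inherits(profile_rep2, "viewpoint_profile"))
  if (length(profile_rep1$track) != length(profile_rep2$track) ||
      !identical(profile_rep1$viewpoint_bins, profile_rep2$viewpoint_bins)) {
    stop("replicate profiles must share viewpoint and binning", call. = FALSE)
  }
  n <- length(profile_rep1$track)
  excl <- vp_excluded_bins(profile_rep1)
  keep <- setdiff(seq_len(n), excl)
  calls <- list()
  for (p in sort(percentiles)) {
    called <- keep
    for (prof in list(profile_rep1, profile_rep2)) {
      pop <- prof$track[keep]
      pop <- pop[!is.na(pop)]
      if (length(pop) == 0L || max(pop) == min(pop)) {
        message(sprintf("call_high_frequency: flat profile, no %d%% calls", p))
        called <- integer(0)
        break
      }
      thr <- stats::quantile(pop, 1 - p / 100, names = FALSE)
      called <- called[!is.na(prof$track[called]) & prof$track[called] > thr]
    }
    calls[[paste0("top", p)]] <- sort(called)
  }
  structure(c(calls, list(excluded = excl, percentiles = sort(percentiles))),
            class = "peak_calls")
}

#' @export
print.peak_calls <- function(x, ...) {
  for (p in x$percentiles) {
    cat(sprintf("top%d%%: %d bins [%s]\n", p, length(x[[paste0("top", p)]]),
                paste(x[[paste0("top", p)]], collapse = ", ")))
  }
  invisible(x)
}

#' Compare peak calls between genotypes
#'
#' @param calls_a,calls_b `peak_calls` objects on the same binning.
#' @param percentile Which call set to compare (default 25).
#' @return List with `lost` (in A only), `gained` (in B only), `shared`.
#' @export
compare_peaks <- function(calls_a, calls_b, percentile = 25) {
  stopifnot(inherits(calls_a, "peak_calls"), inherits(calls_b, "peak_calls"))
  key <- paste0("top", percentile)
  if (is.null(calls_a[[key]]) || is.null(calls_b[[key]])) {
    stop(sprintf("no %s calls present in both inputs", key), call. = FALSE)
  }
  a <- calls_a[[key]]; b <- calls_b[[key]]
  list(lost = setdiff(a, b), gained = setdiff(b, a), shared = intersect(a, b))
}

#' Export a viewpoint profile as bedGraph
#'
#' @param profile A [viewpoint_profile()].
#' @param path Output path.
#' @export
write_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "viewpoint_profile"))
  b <- bin_bounds(profile$binned)
  keep <- !is.na(profile$track)
  df <- data.frame(chrom = profile$binned$region$chrom,
                   start = b[keep, "start"], end = b[keep, "end"],
                   value = profile$track[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
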