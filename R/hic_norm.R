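#' Knight-Ruiz matrix balancing
#'
#' Balances a raw symmetric contact matrix so that every unmasked row of
#' `D %*% M %*% D` sums to 1. Bins with zero marginal (and optionally the
#' lowest-coverage quantile) are masked before balancing. The core is the
#' Knight-Ruiz inner-outer Newton iteration; if it fails to converge, a
#' damped Sinkhorn fixed-point iteration is used as fallback.
#'
#' @param M A [contact_matrix()] of kind `"raw"`.
#' @param tol Convergence tolerance on the coefficient of variation of the
#'   balanced row sums (default 1e-6).
#' @param max_iter Iteration cap (default 3000).
#' @param drop_quantile Additional fraction of lowest-marginal bins to mask
#'   before balancing (default 0 = only zero-marginal bins).
#' @return A list: `matrix` (a [contact_matrix()] of kind `"kr"`) and
#'   `factors` (per-bin scaling, `NA` for masked bins).
#' @export
kr_balance <- function(M, tol = 1e-6, max_iter = 3000, drop_quantile = 0) {
  stopifnot(inherits(M, "contact_matrix"))
  if (M$kind != "raw") stop("kr_balance expects a raw contact matrix", call. = FALSE)
  n <- M$binned$n_bins
  vals <- M$values
  vals[is.na(vals)] <- 0
  marg <- rowSums(vals)
  mask <- M$mask & marg > 0
  if (drop_quantile > 0 && any(mask)) {
    thr <- stats::quantile(marg[mask], drop_quantile)
    mask <- mask & marg > thr
  }
  if (sum(mask) < 2L) stop("degenerate matrix: fewer than 2 unmasked bins", call. = FALSE)
  A <- vals[mask, mask, drop = FALSE]

  x <- kr_core(A, tol = tol, max_iter = max_iter)
  if (is.null(x)) x <- sinkhorn_core(A, tol = tol, max_iter = max_iter)
  if (is.null(x)) {
    rs <- rowSums(sweep(sweep(A, 1, sqrt(rowSums(A)), "/"), 2, sqrt(colSums(A)), "/"))
    stop(sprintf("KR balancing did not converge in %d iterations (residual CV %.3g)",
                 max_iter, stats::sd(rs) / mean(rs)), call. = FALSE)
  }

  B <- A * tcrossprod(x)
  out <- matrix(NA_real_, n, n)
  out[mask, mask] <- B
  factors <- rep(NA_real_, n)
  factors[mask] <- x
  list(matrix = contact_matrix(out, M$binned, kind = "kr", mask = mask),
       factors = factors)
}

# Knight-Ruiz algorithm (inner-outer Newton with CG inner solves), ported
# from the published pseudocode; returns scaling vector or NULL on failure.
kr_core <- function(A, tol = 1e-6, max_iter = 3000, delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9
  etamax <- 0.1
  eta <- etamax
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1
  rold <- rout
  MVP <- 0
  while (rout > rt && MVP < max_iter) {
    k <- 0
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > n) break
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    MVP <- MVP + k + 1
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), 0.5 * tol / res_norm)
    if (!all(is.finite(x)) || any(x <= 0)) return(NULL)
  }
  if (rout > rt) return(NULL)
  rs <- x * as.vector(A %*% x)
  if (stats::sd(rs) / mean(rs) > 10 * tol) return(NULL)
  x
}

# damped Sinkhorn fixed-point for symmetric matrices: x <- sqrt(x / (A x))
sinkhorn_core <- function(A, tol = 1e-6, max_iter = 3000) {
  n <- nrow(A)
  x <- rep(1 / sqrt(mean(rowSums(A))), n)
  for (it in seq_len(max_iter)) {
    Ax <- as.vector(A %*% x)
    if (any(Ax <= 0) || any(!is.finite(Ax))) return(NULL)
    x_new <- sqrt(x / Ax)
    x <- x_new
    rs <- x * as.vector(A %*% x)
    if (stats::sd(rs) / mean(rs) < tol) return(x)
  }
  NULL
}

#' Stratum-adjusted correlation coefficient (SCC)
#'
#' Distance-stratified replicate concordance: for each genomic separation
#' stratum `k` (in bins), the Pearson correlation between the two matrices'
#' stratum-`k` entries is computed and combined with weights proportional to
#' stratum size times the geometric mean of the two stratum standard
#' deviations. Used as the replicate merge gate (> 0.9).
#'
#' @param A,B [contact_matrix()] objects with identical binning and mask.
#' @param max_separation Largest bin separation included (default all).
#' @param min_pairs Strata with fewer pairs are skipped (default 3).
#' @return SCC score in `[-1, 1]`.
#' @export
scc <- function(A, B, max_separation = NULL, min_pairs = 3L) {
  stopifnot(inherits(A, "contact_matrix"), inherits(B, "contact_matrix"))
  n <- A$binned$n_bins
  if (B$binned$n_bins != n || B$binned$bin_size != A$binned$bin_size) {
    stop("matrices must share binning", call. = FALSE)
  }
  if (is.null(max_separation)) max_separation <- n - 1L
  mask <- A$mask & B$mask
  num <- 0; den <- 0; used <- 0L
  for (k in seq_len(max_separation)) {
    i <- seq_len(n - k)
    j <- i + k
    keep <- mask[i] & mask[j]
    if (sum(keep) < min_pairs) {
      message(sprintf("scc: stratum %d skipped (%d pairs < %d)", k, sum(keep), min_pairs))
      next
    }
    a <- A$values[cbind(i[keep], j[keep])]
    b <- B$values[cbind(i[keep], j[keep])]
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) next
    r <- stats::cor(a, b)
    w <- length(a) * sa * sb
    num <- num + w * r
    den <- den + w
    used <- used + 1L
  }
  if (used == 0L) stop("degenerate SCC: no usable strata", call. = FALSE)
  num / den
}

#' Merge replicate raw contact matrices
#'
#' Element-wise sum of raw counts; the mask of the result is the union of
#' the inputs' invalid bins.
#'
#' @param matrices List of [contact_matrix()] objects, identical binning,
#'   all kind `"raw"`.
#' @return A merged [contact_matrix()] of kind `"raw"`.
#' @export
merge_replicates <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("merge_replicates requires a non-empty list of matrices", call. = FALSE)
  }
  ref <- matrices[[1L]]
  stopifnot(inherits(ref, "contact_matrix"))
  n <- ref$binned$n_bins
  total <- matrix(0, n, n)
  mask <- rep(TRUE, n)
  for (M in matrices) {
    stopifnot(inherits(M, "contact_matrix"))
    if (M$kind != "raw") stop("all replicates must be raw counts", call. = FALSE)
    if (M$binned$n_bins != n || M$binned$bin_size != ref$binned$bin_size) {
      stop("replicates must share binning", call. = FALSE)
    }
    v <- M$values
    v[is.na(v)] <- 0
    total <- total + v
    mask <- mask & M$mask
  }
  contact_matrix(total, ref$binned, kind = "raw", mask = mask)
}

#' Quantile normalization against a null target distribution
#'
#' Replaces the unmasked upper-triangle values of `M` (at separation
#' `>= min_separation` bins) by the values of the null target distribution,
#' preserving ranks: the cell with rank r receives the r-th smallest target
#' value, ties receiving the mean of the target values they span. When the
#' cardinalities differ and `interpolate = TRUE`, the target's quantile
#' function is linearly interpolated. Cells below the separation cutoff and
#' masked cells are `NA` in the output.
#'
#' @param M A [contact_matrix()] (raw or KR-balanced).
#' @param target A [null_distribution()].
#' @param min_separation Minimum bin separation normalized; defaults to the
#'   target's own `min_separation`.
#' @param interpolate Allow cardinality mismatch via interpolation of target
#'   quantiles (default `FALSE`).
#' @return A [contact_matrix()] of kind `"quantile_normalized"`.
#' @export
quantile_normalize <- function(M, target, min_separation = NULL, interpolate = FALSE) {
  stopifnot(inherits(M, "contact_matrix"), inherits(target, "null_distribution"))
  if (is.null(min_separation)) min_separation <- target$min_separation
  cells <- matrix_cells(M, min_separation = min_separation)
  x <- cells$value
  tv <- target$values
  if (length(x) != length(tv)) {
    if (!interpolate) {
      stop(sprintf("cardinality mismatch: %d sample cells vs %d target values (set interpolate = TRUE)",
                   length(x), length(tv)), call. = FALSE)
    }
    if (length(tv) == 1L) {
      tv <- rep(tv, length(x))
    } else {
      p <- seq(0, 1, length.out = length(x))
      tv <- stats::approx(seq(0, 1, length.out = length(tv)), tv, xout = p)$y
    }
  }
  o <- order(x)
  mapped <- numeric(length(x))
  mapped[o] <- tv
  # ties receive the mean of the target values they span
  mapped <- stats::ave(mapped, match(x, x), FUN = mean)
  n <- M$binned$n_bins
  out <- matrix(NA_real_, n, n)
  out[cbind(cells$i, cells$j)] <- mapped
  out[cbind(cells$j, cells$i)] <- mapped
  contact_matrix(out, M$binned, kind = "quantile_normalized", mask = M$mask)
}

#' Difference map between two quantile-normalized matrices
#'
#' `A - B`, the pro-B-minus-reference construction used to expose
#' cell-type-specific contacts (stripes, corner dots, nested domains).
#'
#' @param A,B [contact_matrix()] objects of kind `"quantile_normalized"`
#'   with identical binning.
#' @return A [contact_matrix()] of kind `"difference"`; mask is the union
#'   of invalid bins.
#' @export
difference_map <- function(A, B) {
  stopifnot(inherits(A, "contact_matrix"), inherits(B, "contact_matrix"))
  if (A$kind != "quantile_normalized" || B$kind != "quantile_normalized") {
    stop("difference_map expects two quantile-normalized matrices", call. = FALSE)
  }
  n <- A$binned$n_bins
  if (B$binned$n_bins != n || B$binned$bin_size != A$binned$bin_size) {
    stop("matrices must share binning", call. = FALSE)
  }
  contact_matrix(A$values - B$values, A$binned, kind = "difference",
                 mask = A$mask & B$mask)
}

#' Export a difference map as a BEDPE-like cell list
#'
#' One row per unmasked upper-triangle cell: both bin intervals (printed
#' 1-based inclusive) and the difference value, for viewer import.
#'
#' @param M A [contact_matrix()].
#' @param path Output TSV path.
#' @param min_separation Minimum bin separation exported (default 2).
#' @export
write_cell_list <- function(M, path, min_separation = 2L) {
  stopifnot(inherits(M, "contact_matrix"))
  cells <- matrix_cells(M, min_separation = min_separation)
  cells <- cells[!is.na(cells$value), , drop = FALSE]
  b <- bin_bounds(M$binned)
  chrom <- M$binned$region$chrom
  df <- data.frame(chrom1 = chrom, start1 = b[cells$i, "start"] + 1, end1 = b[cells$i, "end"],
                   chrom2 = chrom, start2 = b[cells$j, "start"] + 1, end2 = b[cells$j, "end"],
                   value = cells$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
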