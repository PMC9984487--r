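# Independent oracles used across the suite. Everything here is written
# against the definitions directly (brute force, rejection sampling,
# fixed-point iteration to convergence) and never calls the code paths it
# checks.

# --- rejection-sampling oracle for confined self-avoiding tangent-sphere
#     chains: draws uniform over all feasible chains by construct-and-reject
oracle_reject_chains <- function(n_draws, n_beads, diameter = 51,
                                 confinement_radius, batch = 20000) {
  rmax <- confinement_radius - diameter / 2
  e2e <- numeric(0)
  cosang <- numeric(0)
  while (length(e2e) < n_draws) {
    B <- batch
    u <- stats::runif(B)
    r0 <- rmax * u^(1 / 3)
    d0 <- matrix(stats::rnorm(3 * B), B, 3)
    d0 <- d0 / sqrt(rowSums(d0^2))
    pos <- array(NA_real_, c(B, n_beads, 3))
    pos[, 1, ] <- r0 * d0
    for (k in 2:n_beads) {
      dk <- matrix(stats::rnorm(3 * B), B, 3)
      dk <- dk / sqrt(rowSums(dk^2))
      pos[, k, ] <- pos[, k - 1, ] + diameter * dk
    }
    ok <- rep(TRUE, B)
    for (k in 1:n_beads) ok <- ok & rowSums(pos[, k, ]^2) <= rmax^2
    if (n_beads >= 3) {
      for (i in 1:(n_beads - 2)) {
        for (j in (i + 2):n_beads) {
          ok <- ok & rowSums((pos[, i, ] - pos[, j, ])^2) >= diameter^2
        }
      }
    }
    idx <- which(ok)
    e2e <- c(e2e, sqrt(rowSums((pos[idx, n_beads, ] - pos[idx, 1, ])^2)))
    if (n_beads == 3) {
      v1 <- pos[idx, 1, ] - pos[idx, 2, ]
      v2 <- pos[idx, 3, ] - pos[idx, 2, ]
      cosang <- c(cosang, rowSums(v1 * v2) / diameter^2)
    }
  }
  list(e2e = e2e[seq_len(n_draws)],
       cos_angle = if (n_beads == 3) cosang[seq_len(n_draws)] else NULL)
}

# Kolmogorov-Smirnov distance between a weighted sample and an unweighted
# reference sample
weighted_ks <- function(x, w, y) {
  o <- order(x)
  cw <- cumsum(w[o] / sum(w))
  max(abs(cw - stats::ecdf(y)(x[o])))
}

# --- Sinkhorn iteration run to convergence: the balancing oracle
oracle_sinkhorn <- function(A, tol = 1e-12, max_iter = 100000) {
  r <- rep(1, nrow(A))
  c <- rep(1, ncol(A))
  for (i in seq_len(max_iter)) {
    r <- 1 / as.vector(A %*% c)
    c <- 1 / as.vector(crossprod(A, r))
    rs <- r * as.vector(A %*% c)
    if (max(abs(rs - 1)) < tol) break
  }
  # symmetrize the two-sided factors for a symmetric input
  x <- sqrt(r * c)
  A * tcrossprod(x)
}

# --- brute-force per-bp interval-to-bin membership scan
oracle_bins_bp_scan <- function(iv_start, iv_end, region_start, bin_size, n_bins) {
  bp <- seq.int(iv_start, iv_end - 1L)
  idx <- as.integer(floor((bp - region_start) / bin_size) + 1L)
  sort(unique(idx[idx >= 1L & idx <= n_bins]))
}

# --- literal restatement of the nine FISH configuration predicates
oracle_fish_category <- function(d12, d13, d23, tc = 0.3, tm = 0.5) {
  stopifnot(length(d12) == 1L)
  inC <- function(d) d <= tc
  if (inC(d12) && inC(d13) && inC(d23)) return("THREE_WAY")
  if (inC(d12) && inC(d13) && !inC(d23)) return("STRING_MID_1")
  if (inC(d12) && inC(d23) && !inC(d13)) return("STRING_MID_2")
  if (inC(d13) && inC(d23) && !inC(d12)) return("STRING_MID_3")
  if (inC(d12) && !inC(d13) && !inC(d23)) return("PAIR_12")
  if (inC(d13) && !inC(d12) && !inC(d23)) return("PAIR_13")
  if (inC(d23) && !inC(d12) && !inC(d13)) return("PAIR_23")
  mid <- function(d) d > tc && d <= tm
  if (mid(d12) && mid(d13) && mid(d23)) return("ALL_MID")
  if (d12 > tm && d13 > tm && d23 > tm) return("ALL_FAR")
  "OTHER"
}

# --- small helpers to build in-code fixtures
toy_binned <- function(n_bins, bin_size = 10000, chrom = "chr12", start = 0) {
  binned_region(genomic_interval(chrom, start, start + n_bins * bin_size), bin_size)
}

toy_matrix <- function(values, kind = "raw", bin_size = 10000, ...) {
  contact_matrix(values, toy_binned(nrow(values), bin_size), kind = kind, ...)
}

# --- planted-anchor virtual 4C study -----------------------------------
# Fixed fixture: 150-bin locus, viewpoint at bin 5 (near the region edge so
# the distance-decay flank does not exhaust the top-quartile quota), three
# dot anchors at 5x background. The noiseless expected matrix defines a
# deterministic reference: its own KR-balanced profile and threshold split
# bins into clear-signal, near-threshold, and clear-background strata;
# sensitivity is counted on the anchors, false positives on the
# clear-background stratum (anchor footprints = anchor +/- one smoothing
# bin).
v4c_planted_study <- function(n_sims, base_seed = 1000, percentile = 25) {
  n_bins <- 150L
  vp_bin <- 5L
  anchors <- c(30L, 40L, 50L)
  depth <- 400
  dots <- lapply(anchors, function(a) list(i = vp_bin, j = a, strength = 5))
  # deterministic reference from the expected-value matrix
  ref <- synth_contact_matrix(n_bins, depth = depth, dots = dots,
                              n_replicates = 1, seed = 1)
  lam <- attr(ref, "lambda")
  binned <- attr(ref, "binned")
  vp_iv <- local({
    b <- bin_bounds(binned)
    genomic_interval(binned$region$chrom, b[vp_bin, "start"], b[vp_bin, "end"],
                     binned$region$assembly)
  })
  det <- kr_balance(contact_matrix(lam, binned, kind = "raw"))$matrix
  pd <- viewpoint_profile(det, vp_iv)
  keep <- setdiff(seq_len(n_bins), (vp_bin - 1L):(vp_bin + 1L))
  thr_det <- stats::quantile(pd$track[keep], 1 - percentile / 100, names = FALSE)
  footprints <- sort(unique(as.vector(outer(anchors, -1L:1L, "+"))))
  clear_bg <- setdiff(keep[pd$track[keep] <= stats::quantile(pd$track[keep], 0.60)],
                      footprints)
  sens <- logical(n_sims)
  spurious <- integer(n_sims)
  for (s in seq_len(n_sims)) {
    reps <- synth_contact_matrix(n_bins, depth = depth, dots = dots,
                                 n_replicates = 2, seed = base_seed + s)
    profs <- lapply(reps, function(M) viewpoint_profile(kr_balance(M)$matrix, vp_iv))
    calls <- call_high_frequency(profs[[1]], profs[[2]],
                                 percentiles = percentile)[[paste0("top", percentile)]]
    sens[s] <- all(anchors %in% calls)
    spurious[s] <- length(intersect(calls, clear_bg))
  }
  list(sensitivity = mean(sens), spurious = spurious, anchors = anchors,
       vp_bin = vp_bin, footprints = footprints, clear_bg = clear_bg,
       thr_det = thr_det)
}

# hand-built ensemble from an explicit coordinate array (nm)
manual_ensemble <- function(coords_list, weights = NULL, bead_diameter = 51,
                            contact_threshold = 80, confinement_radius = 1e6) {
  n_beads <- nrow(coords_list[[1L]])
  n_chains <- length(coords_list)
  coords <- array(0, c(n_beads, 3L, n_chains))
  for (k in seq_len(n_chains)) coords[, , k] <- coords_list[[k]]
  if (is.null(weights)) weights <- rep(1 / n_chains, n_chains)
  p <- polymer_params(n_beads = n_beads, bead_diameter = bead_diameter,
                      confinement_radius = confinement_radius,
                      n_chains = n_chains, contact_threshold = contact_threshold)
  structure(list(coords = coords, weights = weights,
                 log_weights = log(weights), ess = 1 / sum(weights^2),
                 n_restarts = 0L, n_resamples = 0L, params = p),
            class = "polymer_ensemble")
}
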