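#' Radius of a sphere from its volume
#'
#' Inverts \eqn{V = (4/3)\pi r^3}. Used to convert a measured (or scaled)
#' nuclear volume into a spherical confinement radius for the polymer null
#' model.
#'
#' @param volume Volume, any cubic unit; must be positive.
#' @return Radius in the corresponding linear unit.
#' @examples
#' sphere_radius_from_volume(4 * pi / 3)  # 1
#' @export
sphere_radius_from_volume <- function(volume) {
  if (!is.numeric(volume) || any(!is.finite(volume)) || any(volume <= 0)) {
    stop("volume must be positive and finite", call. = FALSE)
  }
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Scale a nuclear volume to a chromatin segment
#'
#' Allocates to a locus the fraction of the nuclear volume equal to its
#' fraction of the genome, preserving constant base-pair density:
#' `locus_volume = nuclear_volume * locus_length / genome_length`.
#' The genome length is a required argument: published "scaled" volumes
#' cannot be reproduced without knowing the assumed genome size, so it is
#' never defaulted.
#'
#' @param nuclear_volume Nuclear volume (µm³).
#' @param locus_length Segment length (bp).
#' @param genome_length Genome length (bp); must be >= `locus_length`.
#' @return Locus confinement volume in µm³.
#' @export
scale_locus_volume <- function(nuclear_volume, locus_length, genome_length) {
  stopifnot(is.numeric(nuclear_volume), is.numeric(locus_length), is.numeric(genome_length))
  if (any(nuclear_volume <= 0) || any(locus_length <= 0) || any(genome_length <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  if (any(locus_length > genome_length)) {
    stop("locus_length must not exceed genome_length", call. = FALSE)
  }
  nuclear_volume * locus_length / genome_length
}

#' Confinement radius (nm) for a locus inside a nucleus
#'
#' Convenience composition of [scale_locus_volume()] and
#' [sphere_radius_from_volume()], returning nanometres to match bead units.
#'
#' @inheritParams scale_locus_volume
#' @return Confinement sphere radius in nm.
#' @export
confinement_radius_nm <- function(nuclear_volume, locus_length, genome_length) {
  v_um3 <- scale_locus_volume(nuclear_volume, locus_length, genome_length)
  sphere_radius_from_volume(v_um3) * 1000
}

#' Parameters of the confined self-avoiding polymer null model
#'
#' Beads are tangent hard spheres: one bead per 10 kb of chromatin, 51 nm in
#' diameter, bonded at exactly one diameter, self-avoiding, and wholly
#' contained in a confinement sphere. Two beads are in contact when their
#' centres are <= 80 nm apart (inclusive).
#'
#' @param n_beads Beads per chain (331 covers a 3.31 Mb locus at 10 kb/bead;
#'   2000 covers 20 Mb).
#' @param bead_diameter Bead diameter in nm (default 51).
#' @param bp_per_bead Chromatin per bead in bp (default 10,000, the Hi-C
#'   working resolution).
#' @param confinement_radius Confinement sphere radius in nm (see
#'   [confinement_radius_nm()]).
#' @param n_chains Chains in the ensemble. Default 2000 is the desk scale;
#'   300,000 chains is the full production scale and takes cluster-class
#'   resources.
#' @param contact_threshold Centre-to-centre contact distance in nm,
#'   inclusive (default 80).
#' @param n_candidates Trial directions per growth step of the Rosenbluth
#'   sampler (default 40).
#' @param retry_budget Whole-chain restarts allowed after growth dead-ends
#'   (default 100).
#' @param resample_threshold Ensembles are grown as a sequential Monte Carlo
#'   population: when the effective sample size falls below this fraction of
#'   `n_chains`, chains are resampled systematically by weight (default 0.5;
#'   0 disables resampling, giving fully independent Rosenbluth chains).
#' @param seed Integer seed; every draw from the ensemble is reproducible.
#' @return An object of class `polymer_params`.
#' @export
polymer_params <- function(n_beads = 331, bead_diameter = 51, bp_per_bead = 10000,
                           confinement_radius, n_chains = 2000,
                           contact_threshold = 80, n_candidates = 40,
                           retry_budget = 100, resample_threshold = 0.5, seed = 1L) {
  stopifnot(n_beads >= 1, n_chains >= 1, n_candidates >= 1, retry_budget >= 1,
            resample_threshold >= 0, resample_threshold < 1)
  if (bead_diameter <= 0) stop("bead_diameter must be > 0", call. = FALSE)
  if (contact_threshold < bead_diameter) {
    stop("contact_threshold must be >= bead_diameter", call. = FALSE)
  }
  if (confinement_radius <= bead_diameter) {
    stop("confinement_radius must exceed bead_diameter", call. = FALSE)
  }
  structure(list(n_beads = as.integer(n_beads), bead_diameter = bead_diameter,
                 bp_per_bead = bp_per_bead, confinement_radius = confinement_radius,
                 n_chains = as.integer(n_chains), contact_threshold = contact_threshold,
                 n_candidates = as.integer(n_candidates),
                 retry_budget = as.integer(retry_budget),
                 resample_threshold = resample_threshold, seed = as.integer(seed)),
            class = "polymer_params")
}

#' @export
print.polymer_params <- function(x, ...) {
  cat(sprintf(paste0("<polymer_params> %d beads x %d chains | bead %g nm, ",
                     "%s bp/bead | confinement R = %.1f nm | contact <= %g nm | seed %d\n"),
              x$n_beads, x$n_chains, x$bead_diameter,
              format(x$bp_per_bead, big.mark = ","), x$confinement_radius,
              x$contact_threshold, x$seed))
  invisible(x)
}

#' Sample one confined self-avoiding chain
#'
#' Sequential Rosenbluth growth: each bead is placed at bond length exactly
#' one diameter from its predecessor, in a direction drawn uniformly among
#' feasible trial directions; the chain weight is the product of per-step
#' feasible fractions, so weighted ensemble averages estimate expectations
#' under the uniform distribution over all geometrically feasible chains.
#'
#' @param params A [polymer_params()].
#' @return An object of class `polymer_chain`: `coords` (`n_beads` x 3, nm),
#'   `log_weight`, and the generating parameters.
#' @export
sample_chain <- function(params) {
  stopifnot(inherits(params, "polymer_params"))
  res <- cpp_sample_chains(1L, params$n_beads, params$bead_diameter,
                           params$confinement_radius, params$n_candidates,
                           params$retry_budget, 0)
  structure(list(coords = matrix(res$coords, params$n_beads, 3),
                 log_weight = res$log_weights[[1L]], params = params),
            class = "polymer_chain")
}

#' Sample the random ensemble of confined self-avoiding chains
#'
#' Draws `params$n_chains` independent chains (see [sample_chain()]) under
#' `params$seed` and normalizes their importance weights. Chains whose growth
#' dead-ends are restarted independently and never enter the ensemble.
#'
#' @param params A [polymer_params()].
#' @param strict If `TRUE`, an effective sample size below 1% of `n_chains`
#'   is an error instead of a warning.
#' @return An object of class `polymer_ensemble`: `coords`
#'   (`n_beads` x 3 x `n_chains` array, nm), normalized `weights`, `ess`
#'   (effective sample size `1 / sum(w^2)`), `n_restarts`, and `params`.
#' @export
sample_ensemble <- function(params, strict = FALSE) {
  stopifnot(inherits(params, "polymer_params"))
  set.seed(params$seed)
  res <- cpp_sample_chains(params$n_chains, params$n_beads, params$bead_diameter,
                           params$confinement_radius, params$n_candidates,
                           params$retry_budget, params$resample_threshold)
  lw <- res$log_weights
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  ess <- 1 / sum(w^2)
  if (ess < 0.01 * params$n_chains) {
    msg <- sprintf("degenerate importance weights: effective sample size %.1f (< 1%% of %d chains)",
                   ess, params$n_chains)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(list(coords = res$coords, weights = w, log_weights = lw,
                 ess = ess, n_restarts = res$n_restarts,
                 n_resamples = res$n_resamples, params = params),
            class = "polymer_ensemble")
}

#' @export
print.polymer_ensemble <- function(x, ...) {
  cat(sprintf("<polymer_ensemble> %d chains x %d beads | ESS %.1f (%.1f%%) | %d restarts | seed %d\n",
              x$params$n_chains, x$params$n_beads, x$ess,
              100 * x$ess / x$params$n_chains, x$n_restarts, x$params$seed))
  invisible(x)
}

#' Extract a random contiguous subsegment of a chain
#'
#' Start offset uniform over the `n_beads - length + 1` possibilities;
#' the importance weight is inherited unchanged.
#'
#' @param chain A `polymer_chain`.
#' @param length Number of consecutive beads to keep.
#' @return A `polymer_chain` of `length` beads.
#' @export
subsegment <- function(chain, length) {
  stopifnot(inherits(chain, "polymer_chain"))
  n <- nrow(chain$coords)
  if (length > n) stop(sprintf("subsegment length %d exceeds chain length %d", length, n),
                       call. = FALSE)
  start <- sample.int(n - length + 1L, 1L)
  p <- chain$params
  p$n_beads <- as.integer(length)
  structure(list(coords = chain$coords[start:(start + length - 1L), , drop = FALSE],
                 log_weight = chain$log_weight, params = p, offset = start),
            class = "polymer_chain")
}

#' Extract random contiguous subsegments across an ensemble
#'
#' Applies the subsegment draw of [subsegment()] independently to every
#' chain (the production recipe: grow long chains, then take a locus-sized
#' window from each).
#'
#' @param ensemble A `polymer_ensemble`.
#' @param length Beads per subsegment.
#' @return A `polymer_ensemble` of `length`-bead chains with inherited
#'   weights.
#' @export
subsegment_ensemble <- function(ensemble, length) {
  stopifnot(inherits(ensemble, "polymer_ensemble"))
  n <- ensemble$params$n_beads
  if (length > n) stop(sprintf("subsegment length %d exceeds chain length %d", length, n),
                       call. = FALSE)
  n_chains <- ensemble$params$n_chains
  starts <- sample.int(n - length + 1L, n_chains, replace = TRUE)
  coords <- array(0, dim = c(length, 3L, n_chains))
  for (k in seq_len(n_chains)) {
    coords[, , k] <- ensemble$coords[starts[k]:(starts[k] + length - 1L), , k]
  }
  p <- ensemble$params
  p$n_beads <- as.integer(length)
  structure(list(coords = coords, weights = ensemble$weights,
                 log_weights = ensemble$log_weights, ess = ensemble$ess,
                 n_restarts = ensemble$n_restarts, params = p, offsets = starts),
            class = "polymer_ensemble")
}

#' Expected contact matrix of a polymer ensemble
#'
#' For each bead pair `(i, j)`, the weighted fraction of chains in which the
#' centre-to-centre distance is at or below the contact threshold. Beads map
#' one-to-one onto bins; the diagonal is zero.
#'
#' @param ensemble A `polymer_ensemble`.
#' @param binned A [binned_region()] with `n_bins == n_beads`.
#' @return A [contact_matrix()] (kind `"raw"`) of weighted contact
#'   frequencies in `[0, 1]`.
#' @export
ensemble_contact_matrix <- function(ensemble, binned) {
  stopifnot(inherits(ensemble, "polymer_ensemble"), inherits(binned, "binned_region"))
  if (binned$n_bins != ensemble$params$n_beads) {
    stop(sprintf("region has %d bins but chains have %d beads (one bead per bin required)",
                 binned$n_bins, ensemble$params$n_beads), call. = FALSE)
  }
  vm <- cpp_contact_matrix(ensemble$coords, ensemble$weights,
                           ensemble$params$contact_threshold)
  contact_matrix(vm, binned, kind = "raw")
}

#' Null reference distribution for quantile normalization
#'
#' Sorted unmasked upper-triangle contact frequencies of the null-ensemble
#' matrix at genomic separation `>= min_separation` bins. Bonded neighbours
#' (`|i - j| = 1`) are in contact by construction and excluded by the
#' default `min_separation = 2`.
#'
#' @param null_matrix A [contact_matrix()] from [ensemble_contact_matrix()].
#' @param min_separation Minimum bin separation included (default 2).
#' @return An object of class `null_distribution` holding the sorted values.
#' @export
null_distribution <- function(null_matrix, min_separation = 2L) {
  stopifnot(inherits(null_matrix, "contact_matrix"))
  cells <- matrix_cells(null_matrix, min_separation = min_separation)
  v <- sort(cells$value)
  if (length(v) == 0L) {
    stop("degenerate null: no unmasked cells at the requested separation", call. = FALSE)
  }
  structure(list(values = v, min_separation = as.integer(min_separation)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d values in [%.4g, %.4g], min_separation %d\n",
              length(x$values), min(x$values), max(x$values), x$min_separation))
  invisible(x)
}

#' Distance-decay curve of an ensemble with sampling error
#'
#' Weighted mean contact frequency as a function of genomic separation
#' (in beads), with a standard error from the spread of block means over
#' `n_blocks` chain blocks.
#'
#' @param ensemble A `polymer_ensemble`.
#' @param n_blocks Number of chain blocks for the error estimate
#'   (default 20).
#' @param max_separation Largest separation reported (default all).
#' @return Data frame with `separation`, `frequency`, `se`.
#' @export
distance_decay <- function(ensemble, n_blocks = 20L, max_separation = NULL) {
  stopifnot(inherits(ensemble, "polymer_ensemble"))
  res <- cpp_decay_blocks(ensemble$coords, ensemble$weights,
                          ensemble$params$contact_threshold, n_blocks)
  bw <- res$block_weight
  bm <- res$block_sum / bw                    # block means per stratum
  freq <- colSums(res$block_sum)              # overall weighted mean (weights sum to 1)
  se <- apply(bm, 2L, stats::sd) / sqrt(n_blocks)
  out <- data.frame(separation = seq_len(ncol(bm)), frequency = freq, se = se)
  if (!is.null(max_separation)) out <- out[out$separation <= max_separation, , drop = FALSE]
  out
}

#' Per-chain physical invariants of an ensemble
#'
#' Fast summary used by validity checks: minimum non-bonded bead distance,
#' maximum bead-centre norm, and bond-length range, per chain.
#'
#' @param ensemble A `polymer_ensemble`.
#' @return Data frame with one row per chain.
#' @export
ensemble_invariants <- function(ensemble) {
  stopifnot(inherits(ensemble, "polymer_ensemble"))
  m <- cpp_chain_invariants(ensemble$coords)
  data.frame(min_nonbonded = m[, 1L], max_norm = m[, 2L],
             min_bond = m[, 3L], max_bond = m[, 4L])
}
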