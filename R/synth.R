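#' Synthetic binned Hi-C contact matrices with planted features
#'
#' Expected counts follow a power-law distance decay,
#' `Lambda[i, j] = depth * max(|i - j|, 1)^decay_exponent *
#' (1 + sum of feature multipliers)`, onto which stripes (one anchor bin
#' interacting with a run of bins in one direction), dots (focal `(i, j)`
#' enrichments, the corner-dot signature of persistent loops) and domains
#' (block enrichments, the self-interacting-domain signature) are planted.
#' Replicates are independent Poisson draws from `Lambda`.
#'
#' @param n_bins Matrix size.
#' @param region Optional [genomic_interval()]; default a synthetic
#'   `n_bins` x 10 kb region on chr12.
#' @param decay_exponent Power-law exponent (< 0; default -1, typical
#'   mammalian contact decay).
#' @param stripes List of `list(anchor =, to =, strength =)`: multiplier
#'   `strength` for cells `(anchor, j)` with `j` between `anchor` and `to`.
#' @param dots List of `list(i =, j =, strength =)`; a dot covers its cell
#'   and is the loop-anchor signature.
#' @param domains List of `list(from =, to =, strength =)` block
#'   enrichments.
#' @param depth Expected count at separation 1 with no features.
#' @param n_replicates Number of Poisson replicates.
#' @param seed Integer seed.
#' @return List of [contact_matrix()] (kind `"raw"`); the expected-value
#'   matrix is attached as attribute `"lambda"`.
#' @export
synth_contact_matrix <- function(n_bins, region = NULL, decay_exponent = -1,
                                 stripes = list(), dots = list(), domains = list(),
                                 depth = 100, n_replicates = 2, seed = 1L) {
  stopifnot(n_bins >= 3, decay_exponent < 0, depth > 0, n_replicates >= 1)
  if (is.null(region)) {
    region <- genomic_interval("chr12", 113215000, 113215000 + n_bins * 10000, "mm10")
  }
  binned <- binned_region(region, bin_size = ceiling(interval_length(region) / n_bins))
  if (binned$n_bins != n_bins) stop("region does not divide into n_bins bins", call. = FALSE)
  sep <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  lambda <- depth * pmax(sep, 1)^decay_exponent
  boost_pos <- matrix(0, n_bins, n_bins)
  boost_neg <- matrix(0, n_bins, n_bins)
  add_sym <- function(i, j, s) {
    m <- if (s >= 0) boost_pos else boost_neg
    m[cbind(i, j)] <- m[cbind(i, j)] + s
    m[cbind(j, i)] <- m[cbind(j, i)] + s
    if (s >= 0) boost_pos <<- m else boost_neg <<- m
  }
  for (st in stripes) {
    jj <- seq(min(st$anchor, st$to), max(st$anchor, st$to))
    jj <- setdiff(jj, st$anchor)
    check_bounds(c(st$anchor, jj), n_bins, "stripe")
    add_sym(rep(st$anchor, length(jj)), jj, st$strength)
  }
  for (dt in dots) {
    check_bounds(c(dt$i, dt$j), n_bins, "dot")
    add_sym(dt$i, dt$j, dt$strength)
  }
  for (dm in domains) {
    check_bounds(c(dm$from, dm$to), n_bins, "domain")
    idx <- dm$from:dm$to
    if (dm$strength >= 0) boost_pos[idx, idx] <- boost_pos[idx, idx] + dm$strength
    else boost_neg[idx, idx] <- boost_neg[idx, idx] + dm$strength
  }
  if (any(boost_pos > 0 & boost_neg < 0)) {
    warning("overlapping enrichment and depletion features composed additively on the multiplier scale",
            call. = FALSE)
  }
  boost <- boost_pos + boost_neg
  if (any(1 + boost <= 0)) {
    stop("feature depletions drive the expected contact rate to zero or below", call. = FALSE)
  }
  lambda <- lambda * (1 + boost)
  diag(lambda) <- depth
  set.seed(seed)
  reps <- lapply(seq_len(n_replicates), function(r) {
    ij <- upper_tri_idx(n_bins, 1L)
    counts <- stats::rpois(nrow(ij), lambda[ij])
    vm <- matrix(0, n_bins, n_bins)
    vm[ij] <- counts
    vm[ij[, c(2L, 1L)]] <- counts
    diag(vm) <- stats::rpois(n_bins, diag(lambda))
    contact_matrix(vm, binned, kind = "raw")
  })
  attr(reps, "lambda") <- lambda
  attr(reps, "binned") <- binned
  reps
}

#' Igh-like feature layout for synthetic Hi-C fixtures
#'
#' A fixed stand-in layout over a 283-bin (2.83 Mb at 10 kb) locus,
#' emulating the phenomenology of a pro-B Igh map: nested self-interacting
#' domains, architectural stripes emanating from the 3'RR- and IGCR1-like
#' anchors, and corner dots pairing the IGCR1-, enhancer- and
#' intermediate-gene-like anchors. Bin positions approximate the printed
#' element coordinates relative to a region starting at chr12:113,215,001.
#'
#' @param n_bins Locus size in bins (default 283); anchor bins are scaled
#'   proportionally for other sizes.
#' @return List with `domains`, `stripes`, `dots` (for
#'   [synth_contact_matrix()]) and the named `anchors`.
#' @export
igh_like_features <- function(n_bins = 283) {
  a <- function(b) max(1L, min(n_bins, as.integer(round(b * n_bins / 283))))
  anchors <- c(rr3 = a(2), emu = a(22), igcr1 = a(29), evh1 = a(97),
               j606 = a(120), evh2 = a(139), evh3 = a(200), evh4 = a(260))
  list(
    anchors = anchors,
    domains = list(
      list(from = anchors[["rr3"]], to = anchors[["evh1"]], strength = 1.5),
      list(from = anchors[["igcr1"]], to = anchors[["evh1"]], strength = 1.5),
      list(from = anchors[["evh1"]], to = anchors[["evh2"]], strength = 2),
      list(from = anchors[["evh2"]], to = anchors[["evh3"]], strength = 1),
      list(from = anchors[["evh3"]], to = anchors[["evh4"]], strength = 1)
    ),
    stripes = list(
      list(anchor = anchors[["rr3"]], to = anchors[["igcr1"]], strength = 3),
      list(anchor = anchors[["igcr1"]], to = anchors[["evh1"]], strength = 3),
      list(anchor = anchors[["evh1"]], to = anchors[["evh2"]], strength = 2)
    ),
    dots = list(
      list(i = anchors[["igcr1"]], j = anchors[["evh1"]], strength = 8),
      list(i = anchors[["igcr1"]], j = anchors[["evh2"]], strength = 6),
      list(i = anchors[["evh1"]], j = anchors[["evh2"]], strength = 6),
      list(i = anchors[["j606"]], j = anchors[["evh2"]], strength = 5)
    )
  )
}

check_bounds <- function(idx, n, what) {
  if (any(idx < 1L | idx > n)) {
    stop(sprintf("%s feature outside matrix bounds [1, %d]", what, n), call. = FALSE)
  }
  invisible(TRUE)
}

# band limits per distance category (µm)
fish_bands <- function(t_contact = 0.3, t_mid = 0.5, far_max = 1.0) {
  list(contact = c(0.05, t_contact), mid = c(t_contact + 1e-6, t_mid),
       far = c(t_mid + 1e-6, far_max))
}

# target distance bands (d12, d13, d23) per configuration category
category_bands <- function(t_contact = 0.3, t_mid = 0.5, far_max = 1.0) {
  b <- fish_bands(t_contact, t_mid, far_max)
  string_open <- c(t_contact + 1e-6, 2 * t_contact) # third side: > contact, within triangle reach
  list(
    THREE_WAY    = list(b$contact, b$contact, b$contact),
    STRING_MID_1 = list(b$contact, b$contact, string_open),  # contacts 1-2, 1-3
    STRING_MID_2 = list(b$contact, string_open, b$contact),  # contacts 1-2, 2-3
    STRING_MID_3 = list(string_open, b$contact, b$contact),  # contacts 1-3, 2-3
    PAIR_12      = list(b$contact, b$far, b$far),
    PAIR_13      = list(b$far, b$contact, b$far),
    PAIR_23      = list(b$far, b$far, b$contact),
    ALL_MID      = list(b$mid, b$mid, b$mid),
    ALL_FAR      = list(b$far, b$far, b$far),
    OTHER        = list(b$mid, b$far, b$far)
  )
}

runif_band <- function(n, band) stats::runif(n, band[1L], band[2L])

# place three points at given pairwise distances (p1 origin, p2 on x axis,
# p3 in the xy plane), then apply a uniform random rotation
triangle_points <- function(d12, d13, d23) {
  x3 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
  y3sq <- d13^2 - x3^2
  if (y3sq < -1e-12) return(NULL)
  p <- rbind(c(0, 0, 0), c(d12, 0, 0), c(x3, sqrt(max(y3sq, 0)), 0))
  # uniform rotation from a QR decomposition of a Gaussian matrix
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  p %*% q
}

#' Synthetic three-color FISH alleles from a configuration mixture
#'
#' Draws each allele's configuration category from `category_weights`,
#' samples pairwise distances inside that category's defining distance
#' bands (respecting the triangle inequality), embeds the triple in 3D with
#' a uniform random orientation, and adds isotropic Gaussian jitter,
#' re-drawing the jitter whenever it would move the allele out of its
#' category.
#'
#' @param category_weights Named non-negative weights over the ten
#'   categories (see [classify_configuration()]); normalized internally.
#' @param n_alleles Alleles to generate (404 per genotype is the
#'   experimental scale).
#' @param jitter_sd Isotropic jitter SD in µm (default 0.02).
#' @param labels Three probe labels (default `c("Emu", "SiteI3", "EVH1")`).
#' @param genotype Genotype tag.
#' @param t_contact,t_mid Classification thresholds in µm.
#' @param seed Integer seed.
#' @return List of [fish_allele()] objects; intended categories attached as
#'   attribute `"categories"`.
#' @export
synth_fish_alleles <- function(category_weights, n_alleles = 404, jitter_sd = 0.02,
                               labels = c("Emu", "SiteI3", "EVH1"),
                               genotype = "WT", t_contact = 0.3, t_mid = 0.5,
                               seed = 1L) {
  stopifnot(is.numeric(category_weights), all(category_weights >= 0),
            sum(category_weights) > 0)
  unknown <- setdiff(names(category_weights), CONFIG_LEVELS)
  if (length(unknown)) {
    stop(sprintf("unknown categories: %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  w <- category_weights / sum(category_weights)
  bands <- category_bands(t_contact, t_mid)
  set.seed(seed)
  cats <- sample(names(w), n_alleles, replace = TRUE, prob = w)
  alleles <- vector("list", n_alleles)
  for (k in seq_len(n_alleles)) {
    cat_k <- cats[k]
    bb <- bands[[cat_k]]
    ok <- FALSE
    for (try in 1:200) {
      d <- c(runif_band(1, bb[[1L]]), runif_band(1, bb[[2L]]), runif_band(1, bb[[3L]]))
      # triangle inequality on (d12, d13, d23)
      if (d[1L] > d[2L] + d[3L] || d[2L] > d[1L] + d[3L] || d[3L] > d[1L] + d[2L]) next
      p <- triangle_points(d[1L], d[2L], d[3L])
      if (is.null(p)) next
      # jitter, accepted only if it keeps the intended category
      for (jt in 1:50) {
        pj <- p + matrix(stats::rnorm(9, sd = jitter_sd), 3, 3)
        dj <- c(sqrt(sum((pj[1, ] - pj[2, ])^2)), sqrt(sum((pj[1, ] - pj[3, ])^2)),
                sqrt(sum((pj[2, ] - pj[3, ])^2)))
        if (as.character(classify_configuration(dj[1], dj[2], dj[3],
                                                t_contact, t_mid)) == cat_k) {
          p <- pj; ok <- TRUE; break
        }
      }
      if (ok) break
    }
    if (!ok) {
      stop(sprintf("cannot realise category %s within its distance bands (triangle inequality)",
                   cat_k), call. = FALSE)
    }
    center <- matrix(stats::runif(3, 0, 5), nrow = 3, ncol = 3, byrow = TRUE)
    alleles[[k]] <- fish_allele(sprintf("%s_%04d", genotype, k), labels,
                                p + center, genotype = genotype)
  }
  attr(alleles, "categories") <- cats
  alleles
}

#' Synthetic V_H usage table with a planted ZOI effect
#'
#' Places `n_genes` short genes in the region (uniformly, or in the
#' `"fig8d"` layout: 87 genes occupying exactly 82 distinct 10 kb bins,
#' five bins holding two genes). WT counts are negative binomial around a
#' per-gene lognormal baseline (repertoire data are overdispersed); KO
#' expected counts are multiplied by `zoi_effect` for genes inside the ZOI.
#'
#' @param n_genes Number of genes (default 87).
#' @param n_zoi_genes Genes placed inside the ZOI (default 20, matching the
#'   gene clustering of the proximal V_H families; the remainder are placed
#'   uniformly in the distal region). Ignored by the `"fig8d"` layout.
#' @param region A [genomic_interval()] (default a 3.31 Mb chr12 stand-in).
#' @param zoi A [genomic_interval()] inside `region`; default the central
#'   335 kb.
#' @param zoi_effect Multiplicative KO effect inside the ZOI (1 = null).
#' @param dispersion Negative binomial size parameter (default 10).
#' @param depth Mean baseline reads per gene (default 200).
#' @param gene_length Gene length in bp (default 300).
#' @param layout `"uniform"` or `"fig8d"` (87 genes / 82 occupied bins).
#' @param seed Integer seed.
#' @return A [vh_usage_table()]; the ZOI interval is attached as attribute
#'   `"zoi"`.
#' @export
synth_vh_usage <- function(n_genes = 87, n_zoi_genes = 20, region = NULL,
                           zoi = NULL, zoi_effect = 1,
                           dispersion = 10, depth = 200, gene_length = 300,
                           layout = c("uniform", "fig8d"), seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(zoi_effect > 0, dispersion > 0, depth > 0, n_zoi_genes < n_genes)
  if (is.null(region)) {
    region <- genomic_interval("chr12", 112735000, 116045000, "mm10") # 3.31 Mb
  }
  if (is.null(zoi)) {
    mid <- (region$start + region$end) / 2
    zoi <- genomic_interval(region$chrom, mid - 167500, mid + 167500, region$assembly)
  }
  if (zoi$start < region$start || zoi$end > region$end) {
    stop("zoi must lie inside the region", call. = FALSE)
  }
  set.seed(seed)
  bin_size <- 10000
  if (layout == "fig8d") {
    if (n_genes != 87) stop("fig8d layout is defined for 87 genes", call. = FALSE)
    n_bins <- floor(interval_length(region) / bin_size)
    occupied <- sort(sample.int(n_bins, 82L))
    doubled <- sample(occupied, 5L)
    gene_bins <- sort(c(occupied, doubled))
    offsets <- stats::runif(n_genes, 0, bin_size - gene_length)
    starts <- region$start + (gene_bins - 1L) * bin_size + floor(offsets)
  } else {
    zoi_starts <- stats::runif(n_zoi_genes, zoi$start, zoi$end - gene_length)
    # distal genes: uniform over the region with the ZOI excised
    left_len <- max(zoi$start - region$start - gene_length, 0)
    right_len <- max(region$end - zoi$end - gene_length, 0)
    u <- stats::runif(n_genes - n_zoi_genes, 0, left_len + right_len)
    distal_starts <- ifelse(u < left_len, region$start + u, zoi$end + (u - left_len))
    starts <- sort(floor(c(zoi_starts, distal_starts)))
  }
  in_zoi <- starts >= zoi$start & starts < zoi$end
  base_mu <- stats::rlnorm(n_genes, log(depth), 0.5)
  wt <- stats::rnbinom(n_genes, mu = base_mu, size = dispersion)
  ko <- stats::rnbinom(n_genes, mu = base_mu * ifelse(in_zoi, zoi_effect, 1),
                       size = dispersion)
  tab <- vh_usage_table(data.frame(
    gene_id = sprintf("VH_%03d", seq_len(n_genes)),
    chrom = region$chrom, start = starts, end = starts + gene_length,
    wt_reads = wt, ko_reads = ko), assembly = region$assembly)
  attr(tab, "zoi") <- zoi
  attr(tab, "region") <- region
  tab
}

#' Synthetic 3C qPCR panel with known crosslinking frequencies
#'
#' Signals carry multiplicative lognormal noise of the given coefficient of
#' variation around a construction in which [normalize_3c()] recovers
#' `true_x` exactly at `cv = 0`.
#'
#' @param true_x Vector of true relative crosslinking frequencies (> 0),
#'   one probe pair each.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param n_replicates Replicates per probe pair.
#' @param seed Integer seed.
#' @return Data frame (`probe_pair`, `replicate`, the four signals,
#'   `true_x`).
#' @export
synth_3c_panel <- function(true_x, cv = 0.1, n_replicates = 4, seed = 1L) {
  stopifnot(is.numeric(true_x), all(true_x > 0), n_replicates >= 1)
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  set.seed(seed)
  # each of the four signals carries a quarter of the log-variance so the
  # recovered X has coefficient of variation `cv`
  sdlog <- sqrt(log(1 + cv^2)) / 2
  noise <- function(n) stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  rows <- expand.grid(replicate = seq_len(n_replicates),
                      pair = seq_along(true_x))
  n <- nrow(rows)
  s_gd_sample <- 100 * noise(n)
  s_igh_control <- 80 * noise(n)
  s_gd_control <- 120 * noise(n)
  s_igh_sample <- true_x[rows$pair] * (100 * 80 / 120) * noise(n)
  data.frame(probe_pair = sprintf("pair_%02d", rows$pair),
             replicate = rows$replicate,
             s_igh_sample = s_igh_sample, s_gd_sample = s_gd_sample,
             s_igh_control = s_igh_control, s_gd_control = s_gd_control,
             true_x = true_x[rows$pair])
}
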