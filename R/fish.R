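#' Three-color DNA FISH spatial configurations
#'
#' Each allele carries three labelled probe positions in µm. Pairwise
#' distances are banded into contact (<= `t_contact`, default 0.3 µm),
#' intermediate (`(t_contact, t_mid]`, default 0.5 µm) and far
#' (> `t_mid`), and each allele is classified into one of nine spatial
#' configurations plus a catch-all:
#'
#' * `THREE_WAY` - all three pairs in contact (three-way overlap);
#' * `STRING_MID_1/2/3` - "beads on a string": exactly the two pairs
#'   sharing the named middle probe in contact;
#' * `PAIR_12/13/23` - exactly one pair in contact;
#' * `ALL_MID` - all three pairs intermediate;
#' * `ALL_FAR` - all three pairs far;
#' * `OTHER` - none of the above (e.g. mixed intermediate/far with no
#'   contact).
#'
#' @name fish_configurations
#' @keywords internal
NULL

CONFIG_LEVELS <- c("THREE_WAY", "STRING_MID_1", "STRING_MID_2", "STRING_MID_3",
                   "PAIR_12", "PAIR_13", "PAIR_23", "ALL_MID", "ALL_FAR", "OTHER")

#' Construct a FISH allele
#'
#' @param allele_id Identifier.
#' @param labels Character vector of three distinct probe labels, in the
#'   fixed label order used for distance reporting.
#' @param coords 3 x 3 numeric matrix of probe positions (rows follow
#'   `labels`; columns x, y, z in µm).
#' @param genotype Genotype tag.
#' @return Object of class `fish_allele`.
#' @export
fish_allele <- function(allele_id, labels, coords, genotype = NA_character_) {
  coords <- as.matrix(coords)
  stopifnot(length(labels) == 3L, nrow(coords) == 3L, ncol(coords) == 3L)
  if (anyDuplicated(labels)) stop("probe labels must be distinct", call. = FALSE)
  if (any(!is.finite(coords))) stop("probe coordinates must be finite", call. = FALSE)
  structure(list(allele_id = allele_id, labels = as.character(labels),
                 coords = coords, genotype = genotype),
            class = "fish_allele")
}

#' Pairwise probe distances of an allele
#'
#' @param allele A [fish_allele()].
#' @return Named numeric vector `c(d12, d13, d23)` in µm, ordered by the
#'   allele's fixed label order.
#' @export
pairwise_distances <- function(allele) {
  stopifnot(inherits(allele, "fish_allele"))
  p <- allele$coords
  c(d12 = sqrt(sum((p[1L, ] - p[2L, ])^2)),
    d13 = sqrt(sum((p[1L, ] - p[3L, ])^2)),
    d23 = sqrt(sum((p[2L, ] - p[3L, ])^2)))
}

#' Classify a distance triple into a spatial configuration
#'
#' Vectorized over triples. See the configuration definitions in
#' [fish_configurations]. Contacts are `<= t_contact`; the intermediate
#' band is `(t_contact, t_mid]`. With `pair_noncontact = "mid"` the pure
#' pairwise categories additionally require the two non-contacting pairs to
#' exceed `t_mid` (the stricter reading); the default only requires them to
#' exceed `t_contact`.
#'
#' @param d12,d13,d23 Pairwise distances in µm (vectors of equal length).
#' @param t_contact Contact threshold in µm (default 0.3).
#' @param t_mid Upper bound of the intermediate band in µm (default 0.5).
#' @param pair_noncontact `"contact"` (default) or `"mid"`.
#' @return Factor with levels `THREE_WAY`, `STRING_MID_1..3`,
#'   `PAIR_12/13/23`, `ALL_MID`, `ALL_FAR`, `OTHER`.
#' @examples
#' classify_configuration(0.1, 0.1, 0.1)    # THREE_WAY
#' classify_configuration(0.2, 0.6, 0.2)    # STRING_MID_2
#' classify_configuration(0.4, 0.6, 0.7)    # OTHER
#' @export
classify_configuration <- function(d12, d13, d23, t_contact = 0.3, t_mid = 0.5,
                                   pair_noncontact = c("contact", "mid")) {
  pair_noncontact <- match.arg(pair_noncontact)
  stopifnot(length(d12) == length(d13), length(d13) == length(d23),
            t_contact > 0, t_mid > t_contact)
  if (any(c(d12, d13, d23) < 0)) stop("distances must be non-negative", call. = FALSE)
  c12 <- d12 <= t_contact; c13 <- d13 <= t_contact; c23 <- d23 <= t_contact
  nc <- c12 + c13 + c23
  far_enough <- function(d) if (pair_noncontact == "mid") d > t_mid else d > t_contact
  out <- rep("OTHER", length(d12))
  out[nc == 3L] <- "THREE_WAY"
  # exactly two contacting pairs share one probe: that probe is the middle bead
  out[nc == 2L & !c23] <- "STRING_MID_1"   # 1-2 and 1-3 contact
  out[nc == 2L & !c13] <- "STRING_MID_2"   # 1-2 and 2-3 contact
  out[nc == 2L & !c12] <- "STRING_MID_3"   # 1-3 and 2-3 contact
  out[nc == 1L & c12 & far_enough(d13) & far_enough(d23)] <- "PAIR_12"
  out[nc == 1L & c13 & far_enough(d12) & far_enough(d23)] <- "PAIR_13"
  out[nc == 1L & c23 & far_enough(d12) & far_enough(d13)] <- "PAIR_23"
  mid12 <- d12 > t_contact & d12 <= t_mid
  mid13 <- d13 > t_contact & d13 <= t_mid
  mid23 <- d23 > t_contact & d23 <= t_mid
  out[nc == 0L & mid12 & mid13 & mid23] <- "ALL_MID"
  out[nc == 0L & d12 > t_mid & d13 > t_mid & d23 > t_mid] <- "ALL_FAR"
  factor(out, levels = CONFIG_LEVELS)
}

#' Classify a collection of FISH alleles
#'
#' @param alleles List of [fish_allele()] objects.
#' @param ... Passed to [classify_configuration()].
#' @return Data frame with allele_id, genotype, the three distances and the
#'   configuration category.
#' @export
classify_alleles <- function(alleles, ...) {
  stopifnot(is.list(alleles), length(alleles) >= 1L)
  d <- t(vapply(alleles, pairwise_distances, numeric(3)))
  data.frame(allele_id = vapply(alleles, function(a) as.character(a$allele_id), ""),
             genotype = vapply(alleles, function(a) as.character(a$genotype), ""),
             d12 = d[, 1L], d13 = d[, 2L], d23 = d[, 3L],
             category = classify_configuration(d[, 1L], d[, 2L], d[, 3L], ...))
}

#' Configuration frequency table and per-category genotype comparison
#'
#' Counts and proportions of each spatial configuration per genotype, with a
#' per-category two-tailed 2x2 chi-square test (category vs rest, genotype A
#' vs B); when any expected cell count falls below 1 the test falls back to
#' Fisher's exact test (noted in the output).
#'
#' @param classified Data frame from [classify_alleles()] (columns
#'   `genotype`, `category`).
#' @param genotypes Length-2 character vector selecting/ordering the two
#'   genotypes compared; default the two present.
#' @return List: `table` (per-genotype counts and proportions per category)
#'   and `tests` (per-category statistic, p-value, method).
#' @export
configuration_frequencies <- function(classified, genotypes = NULL) {
  stopifnot(is.data.frame(classified), all(c("genotype", "category") %in% names(classified)))
  if (is.null(genotypes)) genotypes <- unique(as.character(classified$genotype))
  if (length(genotypes) != 2L) stop("exactly two genotypes required", call. = FALSE)
  sub <- classified[classified$genotype %in% genotypes, , drop = FALSE]
  if (!all(table(sub$genotype)[genotypes] >= 1L)) {
    stop("each genotype needs at least one allele", call. = FALSE)
  }
  cat_f <- factor(as.character(sub$category), levels = CONFIG_LEVELS)
  counts <- table(category = cat_f, genotype = factor(sub$genotype, levels = genotypes))
  props <- prop.table(counts, margin = 2L)
  tests <- lapply(CONFIG_LEVELS, function(cg) {
    m <- rbind(in_cat = counts[cg, ], rest = colSums(counts) - counts[cg, ])
    if (sum(m) == 0L || all(m["in_cat", ] == 0L)) {
      return(data.frame(category = cg, statistic = NA_real_, p_value = NA_real_,
                        method = "none"))
    }
    exp_counts <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(exp_counts < 1)) {
      ft <- stats::fisher.test(m)
      message(sprintf("configuration_frequencies: expected count < 1 for %s; Fisher's exact test used", cg))
      data.frame(category = cg, statistic = NA_real_, p_value = ft$p.value,
                 method = "fisher")
    } else {
      ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
      data.frame(category = cg, statistic = unname(ct$statistic),
                 p_value = ct$p.value, method = "chisq")
    }
  })
  list(table = list(counts = counts, proportions = props),
       tests = do.call(rbind, tests))
}

#' Distance summary and rank test for one probe pair across genotypes
#'
#' @param classified Data frame from [classify_alleles()].
#' @param pair One of `"d12"`, `"d13"`, `"d23"`.
#' @param genotypes Length-2 character vector of genotypes to compare.
#' @return List with per-genotype `n`, `median`, `mean`, and the two-tailed
#'   Mann-Whitney U `p_value`.
#' @export
distance_summary <- function(classified, pair = c("d12", "d13", "d23"), genotypes = NULL) {
  pair <- match.arg(pair)
  if (is.null(genotypes)) genotypes <- unique(as.character(classified$genotype))
  if (length(genotypes) != 2L) stop("exactly two genotypes required", call. = FALSE)
  x <- classified[[pair]][classified$genotype == genotypes[1L]]
  y <- classified[[pair]][classified$genotype == genotypes[2L]]
  if (length(x) < 3L || length(y) < 3L) {
    stop("at least 3 alleles per genotype required", call. = FALSE)
  }
  if (length(unique(c(x, y))) == 1L) {
    message("distance_summary: all distances tied; p = 1")
    p <- 1
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))$p.value
  }
  summ <- data.frame(genotype = genotypes, n = c(length(x), length(y)),
                     median = c(stats::median(x), stats::median(y)),
                     mean = c(mean(x), mean(y)))
  list(pair = pair, summary = summ, p_value = p)
}

#' Compaction curve: mean spatial distance vs genomic separation
#'
#' For every probe paired with the anchor, the genomic separation is
#' computed 5'-start to 5'-start from the probe intervals and the mean (and
#' SEM) of the corresponding spatial distances is taken across alleles.
#'
#' @param alleles List of [fish_allele()] objects (all sharing the same
#'   probe label set).
#' @param anchor Anchor probe label.
#' @param probe_positions Named list of [genomic_interval()], one per probe
#'   label.
#' @param genotype Optional genotype filter.
#' @return Data frame (probe, separation_bp, mean_um, sem_um, n) sorted by
#'   separation.
#' @export
compaction_curve <- function(alleles, anchor, probe_positions, genotype = NULL) {
  stopifnot(is.list(alleles), length(alleles) >= 1L)
  labels <- alleles[[1L]]$labels
  if (!anchor %in% labels) stop(sprintf("anchor '%s' not among probe labels", anchor),
                                call. = FALSE)
  missing <- setdiff(labels, names(probe_positions))
  if (length(missing)) {
    stop(sprintf("no genomic coordinates for probe(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(genotype)) {
    alleles <- Filter(function(a) identical(as.character(a$genotype), genotype), alleles)
  }
  anchor_start <- probe_positions[[anchor]]$start
  rows <- lapply(labels, function(lb) {
    sep <- abs(probe_positions[[lb]]$start - anchor_start)
    d <- vapply(alleles, function(a) {
      p <- a$coords
      ai <- match(anchor, a$labels); bi <- match(lb, a$labels)
      sqrt(sum((p[ai, ] - p[bi, ])^2))
    }, numeric(1))
    data.frame(probe = lb, separation_bp = sep, mean_um = mean(d),
               sem_um = stats::sd(d) / sqrt(length(d)), n = length(d))
  })
  out <- do.call(rbind, rows)
  out[order(out$separation_bp), , drop = FALSE]
}

#' Read FISH probe coordinates from CSV
#'
#' Long format, three rows per allele: `allele_id, genotype, probe_label,
#' x_um, y_um, z_um`.
#'
#' @param path CSV path.
#' @return List of [fish_allele()] objects.
#' @export
read_fish_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("allele_id", "genotype", "probe_label", "x_um", "y_um", "z_um")
  if (!all(need %in% names(df))) {
    stop(sprintf("FISH CSV must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  split_df <- split(df, df$allele_id)
  out <- lapply(split_df, function(g) {
    if (nrow(g) != 3L) {
      stop(sprintf("allele %s has %d probe rows (3 required)", g$allele_id[1L], nrow(g)),
           call. = FALSE)
    }
    fish_allele(g$allele_id[1L], g$probe_label,
                as.matrix(g[, c("x_um", "y_um", "z_um")]),
                genotype = g$genotype[1L])
  })
  unname(out)
}

#' Write classified alleles and frequency table
#'
#' @param classified Data frame from [classify_alleles()].
#' @param path Output CSV path.
#' @export
write_fish_classification <- function(classified, path) {
  utils::write.csv(classified, path, row.names = FALSE)
  invisible(path)
}
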