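#' Relative crosslinking frequency from 3C qPCR signals
#'
#' Normalizes a 3C locus signal by a gene-desert (GD) reference and by a
#' control template mix:
#' `X = (S_igh_sample / S_gd_sample) / (S_igh_control / S_gd_control)`,
#' which sets the crosslinking frequency of the reference fragments to 1.
#' Vectorized over observations.
#'
#' @param s_igh_sample,s_gd_sample qPCR signals for the locus and reference
#'   primer pairs in the sample (must be > 0).
#' @param s_igh_control,s_gd_control The same signals in the control
#'   template mix.
#' @return Relative crosslinking frequency X (unitless).
#' @examples
#' normalize_3c(4, 2, 1, 1)  # 2
#' @export
normalize_3c <- function(s_igh_sample, s_gd_sample, s_igh_control, s_gd_control) {
  sig <- cbind(s_igh_sample, s_gd_sample, s_igh_control, s_gd_control)
  if (any(!is.finite(sig)) || any(sig <= 0)) {
    stop("all four qPCR signals must be positive and finite", call. = FALSE)
  }
  (s_igh_sample / s_gd_sample) / (s_igh_control / s_gd_control)
}

#' Read a 3C observation table and compute X per row
#'
#' CSV columns: `probe_pair, s_igh_sample, s_gd_sample, s_igh_control,
#' s_gd_control` (extra columns carried through).
#'
#' @param path CSV path.
#' @return The table with an added `x` column.
#' @export
read_3c_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe_pair", "s_igh_sample", "s_gd_sample", "s_igh_control", "s_gd_control")
  if (!all(need %in% names(df))) {
    stop(sprintf("3C CSV must have columns: %s", paste(need, collapse = ", ")), call. = FALSE)
  }
  df$x <- normalize_3c(df$s_igh_sample, df$s_gd_sample, df$s_igh_control, df$s_gd_control)
  df
}

#' V_H usage table constructor / validator
#'
#' @param genes Data frame with columns `gene_id, chrom, start, end,
#'   wt_reads, ko_reads`; `start`/`end` are 0-based half-open bp on one
#'   chromosome.
#' @param assembly Genome build tag.
#' @return The table sorted by `start`, classed `vh_usage_table`.
#' @export
vh_usage_table <- function(genes, assembly = "mm10") {
  need <- c("gene_id", "chrom", "start", "end", "wt_reads", "ko_reads")
  stopifnot(is.data.frame(genes), all(need %in% names(genes)))
  if (length(unique(genes$chrom)) != 1L) {
    stop("all genes must lie on one chromosome", call. = FALSE)
  }
  if (any(genes$wt_reads < 0) || any(genes$ko_reads < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (any(genes$end <= genes$start)) stop("gene intervals must have end > start", call. = FALSE)
  out <- genes[order(genes$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "assembly") <- assembly
  class(out) <- c("vh_usage_table", "data.frame")
  out
}

#' Read a V_H usage TSV
#'
#' @param path TSV with header `gene_id, chrom, start, end, wt_reads,
#'   ko_reads`.
#' @param assembly Genome build tag.
#' @return A [vh_usage_table()].
#' @export
read_usage_tsv <- function(path, assembly = "mm10") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  vh_usage_table(df, assembly = assembly)
}

#' Per-gene KO/WT usage ratio and log2 fold change
#'
#' `ratio = (ko + e) / (wt + e)` where the pseudocount `e` is applied only
#' when either count is zero, so non-zero ratios are unperturbed. Genes with
#' both counts zero are flagged and excluded from the returned fold changes.
#'
#' @param table A [vh_usage_table()].
#' @param pseudocount Pseudocount for zero counts (default 0.5).
#' @return The table with added columns `ratio`, `log2_fc`,
#'   `pseudocounted`, `excluded`.
#' @export
usage_fold_change <- function(table, pseudocount = 0.5) {
  stopifnot(inherits(table, "vh_usage_table"), nrow(table) > 0)
  wt <- table$wt_reads; ko <- table$ko_reads
  zero <- wt == 0 | ko == 0
  both_zero <- wt == 0 & ko == 0
  eps <- ifelse(zero, pseudocount, 0)
  ratio <- (ko + eps) / (wt + eps)
  ratio[both_zero] <- NA_real_
  if (any(both_zero)) {
    message(sprintf("usage_fold_change: %d gene(s) with zero counts in both genotypes excluded: %s",
                    sum(both_zero), paste(table$gene_id[both_zero], collapse = ", ")))
  }
  table$ratio <- ratio
  table$log2_fc <- log2(ratio)
  table$pseudocounted <- zero & !both_zero
  table$excluded <- both_zero
  table
}

#' Aggregate gene usage into fixed-width bins
#'
#' Every gene occupies each bin its interval overlaps; read counts are
#' split across overlapped bins proportional to overlap length (so per-bin
#' sums conserve the table totals; a sub-bin-sized gene inside one bin
#' contributes entirely to it).
#'
#' @param table A [vh_usage_table()].
#' @param binned A [binned_region()] covering all genes.
#' @return List: `bins` (data frame bin, wt_reads, ko_reads, n_genes) and
#'   `occupied` (number of bins overlapped by at least one gene).
#' @export
bin_usage <- function(table, binned) {
  stopifnot(inherits(table, "vh_usage_table"), inherits(binned, "binned_region"))
  region <- binned$region
  outside <- table$start < region$start | table$end > region$end |
    table$chrom != region$chrom
  if (any(outside)) {
    stop(sprintf("gene(s) outside the binned region: %s",
                 paste(table$gene_id[outside], collapse = ", ")), call. = FALSE)
  }
  n <- binned$n_bins
  b <- bin_bounds(binned)
  wt <- numeric(n); ko <- numeric(n); ngenes <- integer(n)
  for (g in seq_len(nrow(table))) {
    iv <- genomic_interval(table$chrom[g], table$start[g], table$end[g],
                           assembly = attr(table, "assembly") %||% "mm10")
    bins <- interval_to_bins(iv, binned)
    ov <- pmin(b[bins, "end"], iv$end) - pmax(b[bins, "start"], iv$start)
    frac <- ov / sum(ov)
    wt[bins] <- wt[bins] + table$wt_reads[g] * frac
    ko[bins] <- ko[bins] + table$ko_reads[g] * frac
    ngenes[bins] <- ngenes[bins] + 1L
  }
  list(bins = data.frame(bin = seq_len(n), wt_reads = wt, ko_reads = ko,
                         n_genes = ngenes),
       occupied = sum(ngenes > 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition genes or bins into ZOI vs distal
#'
#' @param starts Numeric vector of element 5' starts (bp, 0-based), or a
#'   [vh_usage_table()] (its `start` column is used).
#' @param zoi A [genomic_interval()]: the zone of influence.
#' @return Logical vector, `TRUE` for elements inside the ZOI.
#' @export
zoi_partition <- function(starts, zoi) {
  stopifnot(inherits(zoi, "genomic_interval"))
  if (inherits(starts, "vh_usage_table")) starts <- starts$start
  starts >= zoi$start & starts < zoi$end
}

#' Rank test of fold changes inside vs outside the ZOI
#'
#' Two-tailed Mann-Whitney U test comparing the fold-change distribution of
#' elements inside the zone of influence against the distal rest.
#'
#' @param values Per-gene or per-bin fold changes (log2 scale or ratios).
#' @param in_zoi Logical partition from [zoi_partition()].
#' @return List: `p_value`, per-group `n`, `median`, `mean`.
#' @export
zoi_test <- function(values, in_zoi) {
  stopifnot(length(values) == length(in_zoi))
  keep <- !is.na(values)
  values <- values[keep]; in_zoi <- in_zoi[keep]
  x <- values[in_zoi]; y <- values[!in_zoi]
  if (length(x) < 3L || length(y) < 3L) {
    stop(sprintf("each group needs >= 3 values (ZOI: %d, distal: %d)",
                 length(x), length(y)), call. = FALSE)
  }
  p <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))$p.value
  list(p_value = p,
       zoi = list(n = length(x), median = stats::median(x), mean = mean(x)),
       distal = list(n = length(y), median = stats::median(y), mean = mean(y)))
}

#' Concordance between usage and contact fold changes
#'
#' Descriptive pairing of per-bin usage log2 fold changes with per-bin
#' virtual-4C contact log2 fold changes: the fraction of within-ZOI bins
#' whose usage and contact changes have opposite signs, plus the Spearman
#' rank correlation over all shared bins and over ZOI bins.
#'
#' @param fc_usage,fc_contacts Named or positionally aligned numeric
#'   vectors, one value per bin (NA allowed).
#' @param in_zoi Logical vector, same length.
#' @return List: `n_shared`, `rho_all`, `rho_zoi`,
#'   `frac_opposite_sign_zoi`.
#' @export
contact_usage_concordance <- function(fc_usage, fc_contacts, in_zoi) {
  stopifnot(length(fc_usage) == length(fc_contacts),
            length(fc_usage) == length(in_zoi))
  shared <- !is.na(fc_usage) & !is.na(fc_contacts)
  if (sum(shared) < 2L) {
    stop(sprintf("only %d shared bin(s); at least 2 required", sum(shared)), call. = FALSE)
  }
  u <- fc_usage[shared]; v <- fc_contacts[shared]; z <- in_zoi[shared]
  rho_all <- stats::cor(u, v, method = "spearman")
  rho_zoi <- if (sum(z) >= 2L) stats::cor(u[z], v[z], method = "spearman") else NA_real_
  opp <- if (any(z)) mean(sign(u[z]) * sign(v[z]) < 0) else NA_real_
  list(n_shared = sum(shared), rho_all = rho_all, rho_zoi = rho_zoi,
       frac_opposite_sign_zoi = opp)
}
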