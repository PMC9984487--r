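#' Run the full conformation/repertoire pipeline from a YAML config
#'
#' Executes the stages in dependency order: synthetic (or file-based) Hi-C
#' input, replicate concordance gate and merge, polymer null ensemble,
#' quantile normalization, difference map, virtual 4C peak calls, FISH
#' classification, and ZOI statistics. Every run writes its artifacts, a
#' plain-text log (package version, config hash, seeds, per-stage timing)
#' and a machine-readable JSON summary into the output directory.
#'
#' The config schema (all top-level keys): `seed` (integer),
#' `output_dir` (path), and `stages`, a named list whose entries are any of
#' `hic` (fields `n_bins`, `depth`, optional `dots`/`stripes`/`domains`
#' feature lists), `null_model` (fields `n_chains`, `nuclear_volume_um3`,
#' `genome_length_bp`), `diffmap` (no fields), `virtual4c` (field
#' `viewpoint_bin`, optional `percentiles`), `fish` (fields `n_alleles`,
#' `weights_a`, `weights_b`), `zoi` (fields `zoi_effect`, optional
#' `n_genes`). Unknown stage names or missing required fields are config
#' errors naming the offending key; stages whose upstream stage is absent
#' are dependency errors.
#'
#' @param config Path to a YAML file or an equivalent nested list.
#' @param output_dir Optional override of the config's `output_dir`.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg_hash <- NA_character_
  if (is.character(config)) {
    cfg_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a list", call. = FALSE)
  for (key in c("seed", "stages")) {
    if (is.null(config[[key]])) {
      stop(sprintf("config error at '%s': key is required", key), call. = FALSE)
    }
  }
  out_dir <- output_dir %||% config$output_dir
  if (is.null(out_dir)) stop("config error at 'output_dir': key is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  known <- c("hic", "null_model", "diffmap", "virtual4c", "fish", "zoi")
  bad <- setdiff(names(config$stages), known)
  if (length(bad)) {
    stop(sprintf("config error at 'stages.%s': unknown stage (known: %s)",
                 bad[1L], paste(known, collapse = ", ")), call. = FALSE)
  }
  seed <- as.integer(config$seed)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat(sprintf("ighconform %s | %s\nconfig md5: %s | seed: %d\n",
              as.character(utils::packageVersion("ighconform")),
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), cfg_hash, seed),
      file = log_path)

  st <- config$stages
  summary <- list(package_version = as.character(utils::packageVersion("ighconform")),
                  config_md5 = cfg_hash, seed = seed, stages = list())
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    logf("stage %-10s %.2fs", name, proc.time()[["elapsed"]] - t0)
    res
  }
  reps <- NULL; merged <- NULL; qn <- list(); nullM <- NULL

  if (!is.null(st$hic)) {
    s <- st$hic
    if (is.null(s$n_bins)) stop("config error at 'stages.hic.n_bins': required", call. = FALSE)
    reps <- timed("hic", synth_contact_matrix(
      n_bins = s$n_bins, depth = s$depth %||% 100,
      dots = s$dots %||% list(), stripes = s$stripes %||% list(),
      domains = s$domains %||% list(), n_replicates = 2, seed = seed))
    gate <- scc(reps[[1L]], reps[[2L]])
    logf("SCC(rep1, rep2) = %.4f (merge gate > 0.9)", gate)
    merged <- merge_replicates(reps)
    write_contact_matrix(merged, file.path(out_dir, "merged_raw.tsv"))
    summary$stages$hic <- list(n_bins = s$n_bins, scc = gate,
                               artifact = "merged_raw.tsv")
  }
  if (!is.null(st$null_model)) {
    if (is.null(merged)) stop("dependency error: 'null_model' requires the 'hic' stage", call. = FALSE)
    s <- st$null_model
    for (k in c("nuclear_volume_um3", "genome_length_bp")) {
      if (is.null(s[[k]])) stop(sprintf("config error at 'stages.null_model.%s': required", k),
                                call. = FALSE)
    }
    n_bins <- merged$binned$n_bins
    params <- polymer_params(
      n_beads = n_bins,
      confinement_radius = confinement_radius_nm(s$nuclear_volume_um3,
                                                 n_bins * merged$binned$bin_size,
                                                 s$genome_length_bp),
      n_chains = s$n_chains %||% 2000, seed = seed)
    ens <- timed("null_model", sample_ensemble(params))
    nullM <- ensemble_contact_matrix(ens, merged$binned)
    write_contact_matrix(nullM, file.path(out_dir, "null_matrix.tsv"))
    target <- null_distribution(nullM)
    for (i in seq_along(reps)) {
      qn[[i]] <- quantile_normalize(reps[[i]], target, interpolate = TRUE)
    }
    summary$stages$null_model <- list(n_chains = params$n_chains, ess = ens$ess,
                                      artifact = "null_matrix.tsv")
  }
  if (!is.null(st$diffmap)) {
    if (length(qn) < 2L) stop("dependency error: 'diffmap' requires the 'null_model' stage", call. = FALSE)
    dm <- timed("diffmap", difference_map(qn[[1L]], qn[[2L]]))
    write_contact_matrix(dm, file.path(out_dir, "difference_map.tsv"))
    write_cell_list(dm, file.path(out_dir, "difference_cells.tsv"))
    summary$stages$diffmap <- list(artifact = "difference_map.tsv")
  }
  if (!is.null(st$virtual4c)) {
    if (is.null(reps)) stop("dependency error: 'virtual4c' requires the 'hic' stage", call. = FALSE)
    s <- st$virtual4c
    if (is.null(s$viewpoint_bin)) {
      stop("config error at 'stages.virtual4c.viewpoint_bin': required", call. = FALSE)
    }
    b <- bin_bounds(reps[[1L]]$binned)
    vp <- genomic_interval(reps[[1L]]$binned$region$chrom,
                           b[s$viewpoint_bin, "start"], b[s$viewpoint_bin, "end"])
    profs <- timed("virtual4c", lapply(reps, function(M) {
      viewpoint_profile(kr_balance(M)$matrix, vp)
    }))
    calls <- call_high_frequency(profs[[1L]], profs[[2L]],
                                 percentiles = unlist(s$percentiles %||% c(15, 25)))
    write_bedgraph(profs[[1L]], file.path(out_dir, "v4c_rep1.bedgraph"))
    write_bedgraph(profs[[2L]], file.path(out_dir, "v4c_rep2.bedgraph"))
    summary$stages$virtual4c <- list(viewpoint_bin = s$viewpoint_bin,
                                     top15 = calls$top15, top25 = calls$top25)
  }
  if (!is.null(st$fish)) {
    s <- st$fish
    n_alleles <- s$n_alleles %||% 404
    wa <- unlist(s$weights_a %||% c(THREE_WAY = 0.2, ALL_MID = 0.3, ALL_FAR = 0.5))
    wb <- unlist(s$weights_b %||% c(THREE_WAY = 0.05, ALL_MID = 0.3, ALL_FAR = 0.65))
    res <- timed("fish", {
      aa <- synth_fish_alleles(wa, n_alleles, genotype = "A", seed = seed)
      bb <- synth_fish_alleles(wb, n_alleles, genotype = "B", seed = seed + 1L)
      cls <- classify_alleles(c(aa, bb))
      configuration_frequencies(cls, genotypes = c("A", "B"))
    })
    utils::write.csv(res$tests, file.path(out_dir, "fish_tests.csv"), row.names = FALSE)
    summary$stages$fish <- list(n_alleles = n_alleles,
                                p_three_way = res$tests$p_value[res$tests$category == "THREE_WAY"])
  }
  if (!is.null(st$zoi)) {
    s <- st$zoi
    tab <- timed("zoi", synth_vh_usage(n_genes = s$n_genes %||% 87,
                                       zoi_effect = s$zoi_effect %||% 1, seed = seed))
    fc <- usage_fold_change(tab)
    zt <- zoi_test(fc$log2_fc, zoi_partition(fc, attr(tab, "zoi")))
    utils::write.table(fc, file.path(out_dir, "usage_fc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$stages$zoi <- list(p_value = zt$p_value,
                               zoi_median_log2fc = zt$zoi$median,
                               distal_median_log2fc = zt$distal$median)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
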