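# End-to-end orchestration: QC -> pairwise LD -> decay fits -> half-decay
# summaries -> informative fractions -> haplotype blocks -> population
# statistics -> Fst matrix and NJ tree, written as a TSV report bundle plus
# a machine-readable run manifest.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param genotypes,popmap,map input paths (VCF/TSV dialects of
#'   [read_genotypes()]); alternatively set `simulate` to generate inputs.
#' @param simulate optional list passed to [sim_config()] plus an optional
#'   `roster` data.frame; when present the dataset is simulated instead of
#'   read.
#' @param maf_levels MAF cutoffs; the first is the primary analysis level,
#'   a level of 0.1 (when present) drives the inflation column.
#' @param call_rate_min,dprime_threshold,r2_threshold,breaks_kb analysis
#'   parameters (see [apply_qc()], [solid_spine_blocks()],
#'   [informative_fractions()]).
#' @param scopes decay-fit scopes; `"Auto"` excludes the chromosome labeled
#'   `X`, `"All"` includes it, chromosome names fit single chromosomes.
#' @param combine named list: new label -> member populations to merge
#'   (e.g. `list(RB = c("ERB", "WRB"))`).
#' @param max_distance_kb half-decay search horizon (sentinel beyond).
#' @param seed run seed (simulation only; the analysis is deterministic).
#' @param write_ld_tables also write per-population LD tables (large).
#' @return config list of class `run_config`.
#' @export
run_config <- function(out_dir, genotypes = NULL, popmap = NULL, map = NULL,
                       simulate = NULL, maf_levels = c(0.05, 0.1),
                       call_rate_min = 0.80, dprime_threshold = 0.8,
                       r2_threshold = 0.8,
                       breaks_kb = c(0, 20, 40, 60, 80, 100, 200, 400, 600,
                                     1000),
                       scopes = c("Auto", "All"), combine = NULL,
                       max_distance_kb = 1000, seed = 1L,
                       write_ld_tables = FALSE) {
  cfg <- as.list(environment())
  if (is.null(cfg$simulate) &&
      (is.null(cfg$genotypes) || is.null(cfg$popmap)))
    stop("either input paths (genotypes + popmap) or `simulate` is required")
  class(cfg) <- "run_config"
  cfg
}

.load_run_config <- function(config) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    cfg <- do.call(run_config, raw)
  } else if (inherits(config, "run_config")) cfg <- config
  else cfg <- do.call(run_config, config)
  cfg
}

#' Run the full pipeline
#'
#' @param config a [run_config()], a plain list of its arguments, or a path
#'   to a YAML file holding them.
#' @return Invisibly, a list with the decay summary, per-scope fits, QC
#'   report, population statistics, Fst matrix, NJ tree and manifest. All
#'   tables are also written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[popld] ", ...)

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    roster <- sim_args$roster %||% cat_panel_roster()
    if (!is.null(sim_args$roster)) roster <- as.data.frame(sim_args$roster)
    sim_args$roster <- NULL
    sim_args$seed <- sim_args$seed %||% cfg$seed
    ds <- emulate_study(do.call(sim_config, sim_args), roster)
    log_msg("simulated ", nrow(ds$calls), " samples x ", ncol(ds$calls),
            " SNPs")
  } else {
    for (p in c(cfg$genotypes, cfg$popmap, cfg$map))
      if (!file.exists(p)) stop("input file not found: ", p)
    ds <- read_genotypes(cfg$genotypes, cfg$popmap, cfg$map)
  }
  if (!is.null(cfg$combine))
    for (label in names(cfg$combine)) {
      merged <- combine_populations(ds, cfg$combine[[label]], label)
      ds <- genotype_dataset(rbind(ds$calls, merged$calls),
                             rbind(ds$samples, data.frame(
                               sample_id = paste0(label, ".", merged$samples$sample_id),
                               population = label)),
                             ds$snps)
    }

  pops <- unique(ds$samples$population)
  maf_main <- cfg$maf_levels[1]
  qc_rows <- list(); fit_rows <- list(); summary_rows <- list()
  bg_rows <- list(); block_rows <- list(); hap_rows <- list()
  stats <- pop_summary(ds)

  for (pop in pops) {
    log_msg("population ", pop)
    qc <- apply_qc(ds, pop, cfg$call_rate_min, maf_main)
    qc_rows[[pop]] <- qc$report
    n_ind <- nrow(qc$dataset$calls)
    tab <- tryCatch(pairwise_ld_region(qc$dataset),
                    warning = function(w) NULL, error = function(e) NULL)
    if (cfg$write_ld_tables && !is.null(tab))
      write_ld_table(tab, file.path(cfg$out_dir,
                                    paste0("ld_", pop, ".tsv")))

    scope_set <- cfg$scopes
    if (any(scope_set == "per-chromosome"))
      scope_set <- c(setdiff(scope_set, "per-chromosome"),
                     unique(ds$snps$chromosome))
    fits <- list()
    for (sc in scope_set) {
      f <- tryCatch(fit_decay(scope_pairs(tab, sc), n_ind, sc),
                    error = function(e) NULL)
      if (!is.null(f)) {
        hd <- if (f$converged)
          half_decay(f, cfg$max_distance_kb) else NULL
        fits[[sc]] <- list(fit = f, hd = hd)
        fit_rows[[paste(pop, sc)]] <- data.frame(
          population = pop, scope = sc, n = n_ind,
          a_per_kb = f$a_per_kb, n_pairs = f$n_pairs, rss = f$rss,
          converged = f$converged,
          r2_at_half_decay = if (!is.null(hd)) hd$r2_level else NA_real_,
          dist_kb = if (!is.null(hd)) format_half_decay_distance(hd)
                    else NA_character_,
          stringsAsFactors = FALSE)
      }
    }

    # inflation from the secondary MAF level, on the Auto scope
    infl <- NA_real_
    if (length(cfg$maf_levels) > 1 && !is.null(fits[["Auto"]]) &&
        fits[["Auto"]]$fit$converged) {
      qc_hi <- apply_qc(ds, pop, cfg$call_rate_min, cfg$maf_levels[2])
      tab_hi <- tryCatch(pairwise_ld_region(qc_hi$dataset),
                         warning = function(w) NULL, error = function(e) NULL)
      fit_hi <- tryCatch(fit_decay(scope_pairs(tab_hi, "Auto"),
                                   nrow(qc_hi$dataset$calls), "Auto"),
                         error = function(e) NULL)
      if (!is.null(fit_hi) && fit_hi$converged) {
        d_lo <- half_decay(fits[["Auto"]]$fit, 1e9)$distance_kb
        d_hi <- half_decay(fit_hi, 1e9)$distance_kb
        infl <- maf_inflation_pct(d_lo, d_hi)
      }
    }

    frac4060 <- NA_real_
    if (!is.null(tab)) {
      fr <- informative_fractions(tab, cfg$r2_threshold, cfg$breaks_kb)
      sel <- fr$lo_kb == 40 & fr$hi_kb == 60
      if (any(sel)) frac4060 <- fr$fraction[sel]
    }

    bg <- tryCatch(background_ld(qc$dataset, maf_min = max(cfg$maf_levels)),
                   error = function(e) NULL)
    if (!is.null(bg))
      bg_rows[[pop]] <- data.frame(population = pop, mean_r2 = bg$mean_r2,
                                   n_pairs = bg$n_pairs)

    blocks <- tryCatch(
      solid_spine_blocks(qc$dataset, maf_min = maf_main,
                         dprime_threshold = cfg$dprime_threshold),
      error = function(e) list())
    for (b in blocks) {
      bid <- paste0(pop, "_", b$region, "_", b$start_bp)
      block_rows[[bid]] <- data.frame(
        population = pop, region = b$region, start_bp = b$start_bp,
        end_bp = b$end_bp, n_markers = b$n_markers,
        n_haplotypes = nrow(b$haplotypes),
        major_freq = b$haplotypes$frequency[1], stringsAsFactors = FALSE)
      hap_rows[[bid]] <- data.frame(
        block_id = bid, haplotype = b$haplotypes$haplotype,
        frequency = b$haplotypes$frequency, class = b$haplotypes$class,
        stringsAsFactors = FALSE)
    }

    auto <- fits[["Auto"]]
    summary_rows[[pop]] <- data.frame(
      population = pop, n = n_ind,
      pct_snps_included = qc$report$pct_retained,
      r2_at_half_decay = if (!is.null(auto) && !is.null(auto$hd))
        auto$hd$r2_level else NA_real_,
      dist_kb = if (!is.null(auto) && !is.null(auto$hd))
        format_half_decay_distance(auto$hd) else NA_character_,
      pct_inflation_maf10 = infl,
      fraction_r2ge0.8_40_60kb = frac4060,
      stringsAsFactors = FALSE)
  }

  bind <- function(rows) if (length(rows)) do.call(rbind, rows) else NULL
  decay_summary <- bind(summary_rows); rownames(decay_summary) <- NULL
  out <- list(decay_summary = decay_summary, fits = bind(fit_rows),
              qc = bind(qc_rows), background = bind(bg_rows),
              blocks = bind(block_rows), haplotypes = bind(hap_rows),
              stats = stats)
  for (nm in c("decay_summary", "fits", "qc", "background", "blocks",
               "haplotypes", "stats"))
    if (!is.null(out[[nm]]))
      write_tsv(out[[nm]], file.path(cfg$out_dir, paste0(nm, ".tsv")))

  out$fst <- tryCatch(fst_matrix(ds), error = function(e) NULL)
  if (!is.null(out$fst)) {
    fst_df <- data.frame(population = rownames(out$fst),
                         as.data.frame(unclass(out$fst)[, , drop = FALSE]),
                         check.names = FALSE)
    write_tsv(fst_df, file.path(cfg$out_dir, "fst_matrix.tsv"))
    if (nrow(out$fst) >= 3) {
      out$tree <- nj_tree(out$fst)
      ape::write.tree(out$tree, file.path(cfg$out_dir, "nj_tree.nwk"))
    }
  }

  manifest <- list(
    package = "popld",
    version = as.character(utils::packageVersion("popld")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    outputs = list.files(cfg$out_dir))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(out)
}
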