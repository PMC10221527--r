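write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

matrix_to_df <- function(m, id_col = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  df
}

df_to_matrix <- function(df, id_col = "sample_id") {
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(m) <- df[[id_col]]
  m
}

#' Write a simulated cohort to plain-text files
#'
#' Writes per-location taxa tables, the metabolite feature matrix (with
#' `injection_order` and `is_qc` columns), the feature annotation table,
#' sample metadata and the implanted-effect truth list.
#'
#' @param sim a cohort from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (loc in names(sim$taxa)) {
    f <- file.path(dir, sprintf("taxa_%s.tsv", loc))
    write_tsv(matrix_to_df(sim$taxa[[loc]]$abundance), f)
    files <- c(files, f)
  }
  m <- sim$metabolites
  mdf <- matrix_to_df(m$intensity)
  mdf <- cbind(mdf[1], injection_order = m$injection_order,
               is_qc = m$is_qc, mdf[-1])
  files <- c(files, write_tsv(mdf, file.path(dir, "metabolites.tsv")))
  if (!is.null(m$annotation)) {
    files <- c(files,
               write_tsv(m$annotation, file.path(dir, "annotation.tsv")))
  }
  files <- c(files, write_tsv(sim$metadata, file.path(dir, "metadata.tsv")))
  truth <- lapply(sim$truth, unclass)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(dir, "truth.json"))
  invisible(files)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return list with `taxa`, `metabolites`, `metadata`, `truth` in the
#'   same shape [simulate_cohort()] returns.
#' @export
read_cohort <- function(dir) {
  taxa_files <- list.files(dir, pattern = "^taxa_.*\\.tsv$",
                           full.names = TRUE)
  taxa <- list()
  for (f in taxa_files) {
    loc <- sub("^taxa_(.*)\\.tsv$", "\\1", basename(f))
    df <- utils::read.delim(f, check.names = FALSE)
    taxa[[loc]] <- taxa_table(df_to_matrix(df), location = loc,
                              level = "ASV")
  }
  mdf <- utils::read.delim(file.path(dir, "metabolites.tsv"),
                           check.names = FALSE)
  ann_path <- file.path(dir, "annotation.tsv")
  ann <- if (file.exists(ann_path)) utils::read.delim(ann_path) else NULL
  meta_cols <- c("sample_id", "injection_order", "is_qc")
  metabolites <- metabo_matrix(
    df_to_matrix(mdf[, setdiff(names(mdf), c("injection_order", "is_qc"))]),
    injection_order = mdf$injection_order,
    is_qc = mdf$is_qc,
    annotation = ann
  )
  metadata <- utils::read.delim(file.path(dir, "metadata.tsv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    lapply(jsonlite::read_json(truth_path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE),
           function(e) {
             structure(list(taxon = as.integer(e$taxon),
                            metabolite = as.integer(e$metabolite),
                            binary_effect = e$binary_effect,
                            quant_effect = e$quant_effect,
                            locations = unlist(e$locations)),
                       class = "implanted_effect")
           })
  } else list()
  list(taxa = taxa, metabolites = metabolites, metadata = metadata,
       truth = truth)
}

#' Regenerate the packaged demonstration cohort
#'
#' Writes a small, fully deterministic cohort (60 animals, 40 taxa per
#' location, 30 metabolite features, 3 gut locations, 5 implanted
#' taxon-metabolite effects and 4 fatness-marker metabolites) used by
#' the examples and the end-to-end tests.
#'
#' @param dir output directory.
#' @param seed integer seed (default 42).
#' @return invisibly, the files written.
#' @export
regenerate_fixtures <- function(dir, seed = 42L) {
  effects <- list(
    implanted_effect(1, 5, binary_effect = 1.0, quant_effect = 0.8),
    implanted_effect(2, 6, binary_effect = 1.2, quant_effect = 0),
    implanted_effect(3, 7, binary_effect = 0, quant_effect = 1.0,
                     locations = "cecum"),
    implanted_effect(4, 8, binary_effect = 0.9, quant_effect = 0.6,
                     locations = c("ileum", "cecum")),
    implanted_effect(5, 9, binary_effect = -1.0, quant_effect = -0.8,
                     locations = "faeces")
  )
  cfg <- sim_config(n_samples = 60, n_taxa = 40, n_metabolites = 30,
                    effect_table = effects,
                    fatness_effects = c("1" = 1.5, "2" = 1.5,
                                        "3" = -1.5, "4" = -1.5),
                    drift_slope = 0.002, qc_every = 8, seed = seed)
  write_cohort(simulate_cohort(cfg), dir)
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "gutlink_out",
    fixture_dir = NULL,         # read a written cohort ...
    sim = NULL,                 # ... or simulate one (sim_config args)
    rarefy_depth = NULL,        # only meaningful for count tables
    min_mean_relabund = 5e-4,
    min_prevalence = 0.05,
    max_qc_rsd = 0.30,
    max_test_missing = 0.80,
    max_qc_missing = 0.50,
    min_test_presence = 0.50,
    msi_levels = c(1, 2),
    fdr = 0.05,
    anosim_permutations = 199,
    varexp_rounds = 20,
    varexp_metabolites = 3,     # number of top-associated metabolites
    vip_threshold = 1.0,
    p_threshold = 0.05
  )
}

#' Run the full association pipeline
#'
#' Executes, in order: taxa preprocessing and community summaries
#' (filtering, alpha diversity, Bray-Curtis ordination, ANOSIM across
#' locations), metabolite QC (missingness filter, drift correction, RSD
#' filter, annotation selection), the two-part association scan per
#' location with Spearman validation, cross-validated
#' variance-explained estimation, cross-location shared-association
#' detection, and the fatness biomarker workflow. All stage outputs are
#' written as TSV/JSON under `out_dir` together with a run manifest
#' (configuration plus md5 checksum per output file); a rerun with the
#' same configuration and seed is byte-identical.
#'
#' @param config a named list overriding the defaults (see
#'   `gutlink:::default_pipeline_config()`), or the path of a YAML file
#'   holding one. Provide the input either as `fixture_dir` (a cohort
#'   written by [write_cohort()]) or as `sim` (arguments for
#'   [sim_config()]).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  add <- function(f) outputs <<- c(outputs, f)

  # --- input ------------------------------------------------------------
  if (!is.null(cfg$fixture_dir)) {
    cohort <- read_cohort(cfg$fixture_dir)
  } else {
    sim_args <- if (is.null(cfg$sim)) list() else cfg$sim
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    cohort <- simulate_cohort(do.call(sim_config, sim_args))
  }
  covars <- cohort$metadata[, c("sample_id", "sex", "batch")]

  # --- micro: filtering, diversity, ordination -------------------------
  taxa <- list()
  for (loc in names(cohort$taxa)) {
    tt <- cohort$taxa[[loc]]
    if (!is.null(cfg$rarefy_depth) && !is_proportions(tt)) {
      tt <- rarefy(tt, cfg$rarefy_depth, seed = cfg$seed)
    }
    tt <- filter_taxa(tt, cfg$min_mean_relabund, cfg$min_prevalence)
    taxa[[loc]] <- tt
    add(write_tsv(alpha_diversity(tt),
                  file.path(out, sprintf("alpha_%s.tsv", loc))))
  }
  all_taxa <- sort(unique(unlist(lapply(taxa, function(t)
    colnames(t$abundance)))))
  stacked <- do.call(rbind, lapply(names(taxa), function(loc) {
    m <- matrix(0, nrow(taxa[[loc]]$abundance), length(all_taxa),
                dimnames = list(paste(loc, rownames(taxa[[loc]]$abundance),
                                      sep = ":"), all_taxa))
    m[, colnames(taxa[[loc]]$abundance)] <- taxa[[loc]]$abundance
    m
  }))
  loc_group <- sub(":.*$", "", rownames(stacked))
  d <- bray_curtis(stacked)
  ord <- pcoa(d, k = 2)
  ord_df <- data.frame(sample = rownames(stacked), location = loc_group,
                       ord$points)
  names(ord_df)[3:ncol(ord_df)] <- paste0("PCo", seq_len(ncol(ord_df) - 2))
  add(write_tsv(ord_df, file.path(out, "ordination.tsv")))
  an <- anosim_test(d, loc_group, n_perm = cfg$anosim_permutations,
                    seed = cfg$seed)
  jsonlite::write_json(an, file.path(out, "anosim.json"),
                       auto_unbox = TRUE, digits = NA)
  add(file.path(out, "anosim.json"))

  # --- metabo QC chain --------------------------------------------------
  mm <- cohort$metabolites
  mm <- missingness_filter(mm, cfg$max_test_missing, cfg$max_qc_missing,
                           cfg$min_test_presence)
  mm <- drift_correct(mm)
  mm <- rsd_filter(mm, cfg$max_qc_rsd)
  if (!is.null(mm$annotation)) mm <- select_annotated(mm, cfg$msi_levels)
  if (ncol(mm$intensity) == 0) stop("no metabolite feature survived QC")
  qcdf <- matrix_to_df(mm$intensity)
  qcdf <- cbind(qcdf[1], injection_order = mm$injection_order,
                is_qc = mm$is_qc, qcdf[-1])
  add(write_tsv(qcdf, file.path(out, "metabolites_qc.tsv")))

  # --- two-part association scans + Spearman validation ----------------
  scans <- list()
  for (loc in names(taxa)) {
    scan <- run_association_scan(taxa[[loc]], mm, covariates = covars)
    scans[[loc]] <- scan
    add(write_tsv(as.data.frame(scan),
                  file.path(out, sprintf("associations_%s.tsv", loc))))
    rep_ <- validate_with_spearman(scan, taxa[[loc]], mm,
                                   covariates = covars,
                                   q_threshold = cfg$fdr)
    jsonlite::write_json(
      list(location = loc, n_significant = rep_$n_significant,
           n_replicated = rep_$n_replicated,
           replication_fraction = rep_$replication_fraction),
      file.path(out, sprintf("spearman_replication_%s.json", loc)),
      auto_unbox = TRUE, digits = NA)
    add(file.path(out, sprintf("spearman_replication_%s.json", loc)))
  }

  # --- variance explained (top-associated metabolites per location) ----
  ve_rows <- list()
  for (loc in names(taxa)) {
    scan <- scans[[loc]]
    tops <- unique(scan$metabolite_id)[
      seq_len(min(cfg$varexp_metabolites, length(unique(scan$metabolite_id))))]
    for (mid in tops) {
      ve <- tryCatch(
        variance_explained(mid, taxa[[loc]], metabolites = mm,
                           covariates = covars,
                           n_rounds = cfg$varexp_rounds,
                           seed = cfg$seed),
        error = function(e) NULL)
      if (!is.null(ve)) {
        ve_rows[[length(ve_rows) + 1]] <- data.frame(
          metabolite_id = ve$metabolite_id, location = loc,
          r2_cv = ve$r2_cv, n_rounds = ve$n_rounds)
      }
    }
  }
  if (length(ve_rows)) {
    add(write_tsv(do.call(rbind, ve_rows),
                  file.path(out, "variance_explained.tsv")))
  }

  # --- cross-location sharing ------------------------------------------
  if (length(scans) >= 2) {
    rep_cl <- shared_associations(scans, q_threshold = cfg$fdr)
    add(write_tsv(rep_cl$shared, file.path(out, "shared_pairs.tsv")))
    jsonlite::write_json(
      list(per_location_counts = as.list(rep_cl$per_location_counts),
           venn = rep_cl$venn),
      file.path(out, "venn_counts.json"), auto_unbox = TRUE, digits = NA)
    add(file.path(out, "venn_counts.json"))
  }

  # --- fatness biomarker workflow --------------------------------------
  if ("fatness_group" %in% names(cohort$metadata)) {
    X <- study_intensity(mm)
    grp <- stats::setNames(cohort$metadata$fatness_group,
                           cohort$metadata$sample_id)[rownames(X)]
    diff_tab <- differential_metabolites(X, grp,
                                         vip_threshold = cfg$vip_threshold,
                                         p_threshold = cfg$p_threshold)
    add(write_tsv(as.data.frame(diff_tab),
                  file.path(out, "differential_metabolites.tsv")))
    cands <- diff_tab$metabolite_id[diff_tab$selected]
    if (length(cands) >= 2) {
      panel <- stepwise_logistic(X, grp, candidates = cands)
      jsonlite::write_json(
        list(members = panel$members,
             coefficients = as.list(panel$coefficients),
             panel_auc = panel$panel_auc,
             loo_auc = panel$loo_auc,
             single_aucs = as.list(panel$single_aucs),
             ridge_fallback = panel$ridge_fallback),
        file.path(out, "biomarker_panel.json"), auto_unbox = TRUE,
        digits = NA)
      add(file.path(out, "biomarker_panel.json"))
      add(write_tsv(roc_curve(panel$scores, grp),
                    file.path(out, "roc_panel.tsv")))
    }
  }

  # --- manifest ---------------------------------------------------------
  sums <- tools::md5sum(sort(outputs))
  manifest <- list(config = cfg[order(names(cfg))],
                   outputs = as.list(sums))
  names(manifest$outputs) <- basename(names(sums))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
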