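#' Read a per-subject regional feature table
#'
#' Reads a delimited table with regions as rows and the nine named feature
#' columns (FreeSurfer `aparc.stats` column convention), validates it against
#' the atlas region list and normalizes row and column order to canonical
#' atlas/feature order. Accepts the tables written by [write_cohort()] as
#' well as equivalently shaped aparcstats exports.
#'
#' @param path Path to a TSV/CSV file with a `region` column.
#' @param atlas The `atlas_spec` the table must cover.
#' @return Regions x 9 numeric matrix in atlas region order.
#' @export
read_feature_table <- function(path, atlas) {
  stopifnot(inherits(atlas, "atlas_spec"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!"region" %in% names(df)) stop("no 'region' column in ", path)
  missing_r <- setdiff(atlas$regions, df$region)
  if (length(missing_r))
    stop("missing region(s) in ", path, ": ",
         paste(utils::head(missing_r, 5), collapse = ", "))
  missing_f <- setdiff(all_features(), names(df))
  if (length(missing_f))
    stop("missing feature column(s) in ", path, ": ",
         paste(missing_f, collapse = ", "))
  df <- df[match(atlas$regions, df$region), , drop = FALSE]
  X <- as.matrix(df[, all_features(), drop = FALSE])
  rownames(X) <- atlas$regions
  storage.mode(X) <- "double"
  X
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir Directory holding `*.aparcstats.tsv` files plus `metadata.tsv`.
#' @param atlas The `atlas_spec` to validate against.
#' @return A `cohort_features` object.
#' @export
read_cohort <- function(dir, atlas) {
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"),
                            stringsAsFactors = FALSE)
  files <- file.path(dir, paste0(meta$subject_id, ".aparcstats.tsv"))
  features <- lapply(files, read_feature_table, atlas = atlas)
  names(features) <- meta$subject_id
  structure(list(subjects = meta$subject_id, features = features,
                 age = meta$age, sex = meta$sex, iq = meta$IQ,
                 atlas = atlas, blocks = NULL),
            class = "cohort_features")
}

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline with recorded defaults.
#' The resolved configuration is echoed verbatim into the output manifest.
#'
#' @param atlas_name `"DKA"` or `"DA"`.
#' @param feature_sets Subset of `c("9f", "5f", "4v", "4c")`.
#' @param n_subjects Cohort size when simulating.
#' @param effect,noise_sd Synthetic-cohort generator parameters.
#' @param n_trees Orthogonal spanning trees in the threshold.
#' @param gamma,omega Multilayer resolution and coupling.
#' @param n_samples Optimizer restarts per stack.
#' @param n_boot Bootstraps per ordering.
#' @param orderings Layer orderings to run.
#' @param hub_pct Hub tail fraction.
#' @param seed Master seed.
#' @param input_dir Optional directory of pre-existing cohort tables; when
#'   NULL a synthetic cohort is generated.
#' @param out_dir Optional output directory; when NULL nothing is written.
#' @return A `run_config` list.
#' @export
run_config <- function(atlas_name = "DKA",
                       feature_sets = c("9f", "5f", "4v", "4c"),
                       n_subjects = 198L, effect = 0.6, noise_sd = 1.0,
                       n_trees = 4L, gamma = 1.0, omega = 1.0,
                       n_samples = 1000L, n_boot = 500L,
                       orderings = c("random", "age", "IQ"),
                       hub_pct = 0.05, seed = 1L,
                       input_dir = NULL, out_dir = NULL) {
  bad <- setdiff(feature_sets, feature_set_ids())
  if (length(bad))
    stop("unknown feature set(s): ", paste(bad, collapse = ", "))
  bad_ord <- setdiff(orderings, c("random", "age", "IQ"))
  if (length(bad_ord))
    stop("unknown ordering(s): ", paste(bad_ord, collapse = ", "))
  structure(list(atlas_name = atlas_name, feature_sets = feature_sets,
                 n_subjects = n_subjects, effect = effect,
                 noise_sd = noise_sd, n_trees = n_trees, gamma = gamma,
                 omega = omega, n_samples = n_samples, n_boot = n_boot,
                 orderings = orderings, hub_pct = hub_pct, seed = seed,
                 input_dir = input_dir, out_dir = out_dir),
            class = "run_config")
}

# Write a tidy table stamped with the manifest hash as a comment header.
write_stamped <- function(df, path, manifest_md5) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# manifest_md5: ", manifest_md5), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full MSN flexibility pipeline
#'
#' Orchestrates cohort (synthetic or read from disk) -> outlier replacement
#' -> per-subject MSNs for each feature set -> multilayer stacks per layer
#' ordering -> flexibility, lobe and cognitive-network aggregates, hub tables
#' -> nonparametric group statistics. With both atlases and all four feature
#' sets this is 8 MSNs per subject; a single call runs one atlas.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `cohort`, `msns` (per feature set),
#'   `partitions`, `flexibility` (tidy table), `lobe_means`, `network_means`,
#'   `hubs`, `stats`, `edge_weight_cor`, `manifest`. When `config$out_dir` is
#'   set, all tables are also written as TSV (stamped with the manifest md5)
#'   plus a YAML manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  atlas <- generate_atlas(config$atlas_name)
  cohort <- if (is.null(config$input_dir)) {
    generate_cohort(n_subjects = config$n_subjects, atlas = atlas,
                    seed = config$seed, effect = config$effect,
                    noise_sd = config$noise_sd)
  } else {
    read_cohort(config$input_dir, atlas)
  }
  cohort <- replace_outliers(cohort)
  meta <- data.frame(subject_id = cohort$subjects, age = cohort$age,
                     IQ = cohort$iq, stringsAsFactors = FALSE)

  msns <- list(); partitions <- list(); profiles <- list()
  flex_rows <- list(); lobe_rows <- list(); net_rows <- list()
  stat_rows <- list(); ew_rows <- list()
  for (fs in config$feature_sets) {
    ms <- lapply(seq_along(cohort$subjects), function(s)
      build_msn(cohort$features[[s]], set_id = fs,
                subject = cohort$subjects[s], atlas_name = atlas$name,
                n_trees = config$n_trees))
    names(ms) <- cohort$subjects
    msns[[fs]] <- ms
    mw <- do.call(rbind, lapply(ms, function(m)
      as.data.frame(mean_signed_weights(m))))
    mw$age <- cohort$age
    mw$IQ <- cohort$iq
    for (cv in c("age", "IQ")) {
      ec <- correlate_edge_weights(mw, cv)
      ec$feature_set <- fs
      ec$covariate <- cv
      ew_rows[[paste(fs, cv)]] <- ec
    }
    for (ord in config$orderings) {
      idx <- switch(ord,
        random = with_seed(derive_seed(config$seed, 7L),
                           sample(length(ms))),
        age = order(cohort$age, cohort$subjects),
        IQ = order(cohort$iq, cohort$subjects))
      stack <- multilayer_stack(ms[idx], gamma = config$gamma,
                                omega = config$omega, ordering = ord,
                                covariate = switch(ord, age = cohort$age[idx],
                                                   IQ = cohort$iq[idx]))
      part <- sample_best_partition(stack, n_samples = config$n_samples,
                                    seed = derive_seed(config$seed, 11L))
      part$feature_set <- fs
      partitions[[paste(fs, ord, sep = ".")]] <- part
      prof <- nodal_flexibility(part)
      prof$feature_set <- fs
      profiles[[paste(fs, ord, sep = ".")]] <- prof
      flex_rows[[paste(fs, ord)]] <-
        flexibility_table(prof, atlas, feature_set = fs, ordering = ord)
      lb <- aggregate_flexibility(prof, atlas, "lobe")
      lb$feature_set <- fs; lb$ordering <- ord
      lobe_rows[[paste(fs, ord)]] <- lb
      nw <- aggregate_flexibility(prof, atlas, "cognitive_network")
      nw$feature_set <- fs; nw$ordering <- ord
      net_rows[[paste(fs, ord)]] <- nw
      # nonparametric comparison of nodal flexibility across lobes;
      # degenerate (constant) flexibility yields NA statistics
      by_lobe <- split(prof$f, atlas$lobe)
      by_lobe <- by_lobe[vapply(by_lobe, length, 0L) >= 2L]
      kw <- kruskal_wallis(by_lobe, posthoc = FALSE)
      ks <- if (stats::sd(prof$f) > 0) ks_normality(prof$f)
            else list(statistic = NA_real_, p_value = NA_real_)
      stat_rows[[paste(fs, ord)]] <- data.frame(
        feature_set = fs, ordering = ord,
        ks_D = ks$statistic, ks_p = ks$p_value,
        kw_lobe_chisq = kw$statistic, kw_lobe_df = kw$df,
        kw_lobe_p = kw$p_value, stringsAsFactors = FALSE)
    }
  }
  hub_input <- lapply(config$feature_sets, function(fs)
    profiles[[paste(fs, config$orderings[1], sep = ".")]])
  names(hub_input) <- config$feature_sets
  hubs <- rank_hubs(hub_input, pct = config$hub_pct)

  out <- list(cohort = cohort, msns = msns, partitions = partitions,
              flexibility = do.call(rbind, c(flex_rows,
                                             make.row.names = FALSE)),
              lobe_means = do.call(rbind, c(lobe_rows,
                                            make.row.names = FALSE)),
              network_means = do.call(rbind, c(net_rows,
                                               make.row.names = FALSE)),
              hubs = hubs,
              stats = do.call(rbind, c(stat_rows, make.row.names = FALSE)),
              edge_weight_cor = do.call(rbind, c(ew_rows,
                                                 make.row.names = FALSE)),
              iq_groups = make_iq_groups(meta),
              age_bins = make_age_bins(meta))

  # paths are excluded so the manifest (and its hash) identifies the
  # computation, not where it was written
  cfg_echo <- unclass(config)
  cfg_echo$out_dir <- NULL
  cfg_echo$input_dir <- NULL
  manifest <- list(config = cfg_echo,
                   atlas = atlas$name, n_regions = atlas$N,
                   n_subjects = length(cohort$subjects),
                   package_version = as.character(
                     utils::packageVersion("msnflex")))
  out$manifest <- manifest

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    mpath <- file.path(config$out_dir, "manifest.yaml")
    yaml::write_yaml(manifest, mpath)
    md5 <- unname(tools::md5sum(mpath))
    for (nm in c("flexibility", "lobe_means", "network_means", "stats",
                 "edge_weight_cor", "iq_groups", "age_bins"))
      write_stamped(out[[nm]], file.path(config$out_dir, paste0(nm, ".tsv")),
                    md5)
    write_stamped(out$hubs$flexible,
                  file.path(config$out_dir, "hubs_flexible.tsv"), md5)
    write_stamped(out$hubs$inflexible,
                  file.path(config$out_dir, "hubs_inflexible.tsv"), md5)
    out$manifest_md5 <- md5
  }
  invisible(out)
}
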