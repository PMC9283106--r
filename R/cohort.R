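# Realistic per-feature scales (location, spread) for the nine FreeSurfer-style
# surface features; generation happens on these scales so that downstream
# z-normalization is exercised on commensurate-but-raw input.
feature_scales <- function() {
  data.frame(
    feature = all_features(),
    mu    = c(2000, 1500, 4000, 2.5, 0.6, 0.13, 0.025, 15, 2.5),
    sigma = c(500,  400,  1200, 0.25, 0.1, 0.03, 0.010, 8,  1.5),
    stringsAsFactors = FALSE
  )
}

# Orthonormal block signatures: columns of Q from the QR decomposition of a
# Gaussian n_features x n_blocks matrix, scaled to norm sqrt(n_features) so
# loadings have ~unit variance across features. Orthogonality keeps the
# cross-block correlation baseline near zero, making `effect` interpretable
# as the within-block correlation strength.
block_signatures <- function(n_blocks, n_features = 9L) {
  if (n_blocks > n_features)
    stop("at most ", n_features, " blocks supported (orthogonal signatures)")
  G <- matrix(stats::rnorm(n_features * n_blocks), n_features, n_blocks)
  Q <- qr.Q(qr(G))[, seq_len(n_blocks), drop = FALSE]
  Q * sqrt(n_features)
}

#' Generate a synthetic morphometry cohort
#'
#' Draws a cohort of subjects with a complete regions x 9 morphometric feature
#' matrix each, plus age, sex and IQ metadata. Regions belonging to the same
#' block of `block_structure` share a latent feature signature, so that the
#' per-subject morphometric similarity networks carry a planted, recoverable
#' community structure; independent noise on top makes networks differ between
#' subjects. Defaults emulate the study cohort the pipeline is designed for:
#' 198 subjects aged 6-83 with IQ ~ Normal(100, 15).
#'
#' @param n_subjects Number of subjects (>= 2). Default 198.
#' @param atlas An [generate_atlas()] specification.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @param block_structure Block (module) label per region; defaults to the
#'   atlas lobe assignment (the planted lobe-aligned structure).
#' @param effect Within-block correlation strength in \[0, 1).
#' @param noise_sd Positive noise scale on the standardized feature deviations.
#' @param age_range Length-2 numeric, uniform age range in years.
#' @param iq_mean_sd Length-2 numeric, IQ mean and s.d. (standard score);
#'   values are truncated to \[55, 145\].
#' @return A `cohort_features` object: list with `subjects`, `features` (named
#'   list of regions x 9 matrices), `age`, `sex`, `iq`, `atlas`, `blocks`.
#' @examples
#' atlas <- generate_atlas("DKA")
#' coh <- generate_cohort(n_subjects = 10, atlas = atlas, seed = 1)
#' range(coh$age)
#' @export
generate_cohort <- function(n_subjects = 198L, atlas, seed = 1L,
                            block_structure = NULL, effect = 0.6,
                            noise_sd = 1.0, age_range = c(6, 83),
                            iq_mean_sd = c(100, 15)) {
  stopifnot(inherits(atlas, "atlas_spec"))
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (!is.numeric(effect) || effect < 0 || effect >= 1)
    stop("effect must lie in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(block_structure)) block_structure <- atlas$lobe
  if (length(block_structure) != atlas$N)
    stop("block_structure must assign every region a block")
  blocks <- as.integer(factor(block_structure))
  n_blocks <- max(blocks)
  feats <- all_features()
  sc <- feature_scales()

  with_seed(seed, {
    G <- block_signatures(n_blocks)              # 9 x B
    ids <- sprintf("sub-%03d", seq_len(n_subjects))
    age <- stats::runif(n_subjects, age_range[1], age_range[2])
    sex <- ifelse(stats::runif(n_subjects) < 80 / 198, "F", "M")
    iq <- pmin(pmax(stats::rnorm(n_subjects, iq_mean_sd[1], iq_mean_sd[2]),
                    55), 145)
    signal <- sqrt(effect) * t(G[, blocks, drop = FALSE])  # N x 9
    features <- lapply(seq_len(n_subjects), function(t) {
      E <- matrix(stats::rnorm(atlas$N * 9L, sd = noise_sd), atlas$N, 9L)
      dev <- signal + sqrt(1 - effect) * E
      X <- sweep(sweep(dev, 2L, sc$sigma, "*"), 2L, sc$mu, "+")
      dimnames(X) <- list(atlas$regions, feats)
      X
    })
    names(features) <- ids
    structure(list(subjects = ids, features = features, age = age, sex = sex,
                   iq = iq, atlas = atlas, blocks = blocks, seed = seed,
                   effect = effect, noise_sd = noise_sd),
              class = "cohort_features")
  })
}

#' @export
print.cohort_features <- function(x, ...) {
  cat("<cohort_features> ", length(x$subjects), " subjects, atlas ",
      x$atlas$name, " (", x$atlas$N, " regions x 9 features)\n", sep = "")
  cat(sprintf("  age %.1f-%.1f, IQ %.0f-%.0f, %d F / %d M\n",
              min(x$age), max(x$age), min(x$iq), max(x$iq),
              sum(x$sex == "F"), sum(x$sex == "M")))
  invisible(x)
}

#' Inject artificial outliers into a cohort
#'
#' Displaces a random subset of (subject, region, feature) cells by
#' `magnitude` group standard deviations (random sign), recording which cells
#' were touched so tests can assert on the outlier-replacement stage.
#'
#' @param cohort A `cohort_features` object.
#' @param rate Per-cell displacement probability, at most 0.1 (fixture guard).
#' @param magnitude Displacement in units of the (region, feature) group s.d.
#' @param seed Integer seed.
#' @return The modified cohort; the displaced cells are recorded in
#'   `attr(, "outlier_cells")` as a data frame (subject, region, feature).
#' @export
inject_outliers <- function(cohort, rate, magnitude = 8, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_features"))
  if (!is.numeric(rate) || rate < 0 || rate > 0.1)
    stop("rate must lie in [0, 0.1]")
  if (rate == 0) {
    attr(cohort, "outlier_cells") <-
      data.frame(subject = character(), region = character(),
                 feature = character(), stringsAsFactors = FALSE)
    return(cohort)
  }
  n_sub <- length(cohort$subjects)
  N <- cohort$atlas$N
  # group s.d. per (region, feature) cell across subjects
  arr <- simplify2array(cohort$features)          # N x 9 x n_sub
  sds <- apply(arr, c(1, 2), stats::sd)
  cells <- with_seed(seed, {
    hit <- which(stats::runif(n_sub * N * 9L) < rate)
    sign <- sample(c(-1, 1), length(hit), replace = TRUE)
    list(hit = hit, sign = sign)
  })
  if (length(cells$hit)) {
    idx <- arrayInd(cells$hit, c(N, 9L, n_sub))
    for (k in seq_along(cells$hit)) {
      r <- idx[k, 1]; f <- idx[k, 2]; s <- idx[k, 3]
      cohort$features[[s]][r, f] <-
        cohort$features[[s]][r, f] + cells$sign[k] * magnitude * sds[r, f]
    }
    rec <- data.frame(subject = cohort$subjects[idx[, 3]],
                      region = cohort$atlas$regions[idx[, 1]],
                      feature = all_features()[idx[, 2]],
                      stringsAsFactors = FALSE)
  } else {
    rec <- data.frame(subject = character(), region = character(),
                      feature = character(), stringsAsFactors = FALSE)
  }
  attr(cohort, "outlier_cells") <- rec
  cohort
}

#' Generate a planted drifting multilayer cohort
#'
#' Builds per-layer feature matrices with a planted block structure in which a
#' fixed set of `n_switchers` regions changes block membership between every
#' consecutive pair of layers (cycling through the blocks), while all other
#' regions keep their block. Under good recovery the switching regions have
#' nodal flexibility 1 and the rest 0, so the expected global flexibility is
#' `n_switchers / n_regions`.
#'
#' @param n_regions,n_layers,n_blocks Problem dimensions.
#' @param n_switchers Number of regions that switch block at every step.
#' @param effect,noise_sd As in [generate_cohort()].
#' @param seed Integer seed.
#' @return A `drifting_cohort` object: list with `features` (list of
#'   regions x 9 matrices, one per layer), `block_labels` (regions x layers),
#'   `switchers` (region indices).
#' @export
generate_drifting_cohort <- function(n_regions = 30L, n_layers = 10L,
                                     n_blocks = 3L, n_switchers = 3L,
                                     effect = 0.9, noise_sd = 0.1,
                                     seed = 1L) {
  stopifnot(n_regions >= n_blocks, n_blocks >= 2L, n_layers >= 2L,
            n_switchers >= 0L, n_switchers <= n_regions)
  if (effect < 0 || effect >= 1) stop("effect must lie in [0, 1)")
  feats <- all_features()
  sc <- feature_scales()
  with_seed(seed, {
    G <- block_signatures(n_blocks)
    base <- rep_len(seq_len(n_blocks), n_regions)
    switchers <- sample.int(n_regions, n_switchers)
    labels <- matrix(base, n_regions, n_layers)
    for (s in seq_len(n_layers - 1L)) {
      labels[, s + 1L] <- labels[, s]
      labels[switchers, s + 1L] <- (labels[switchers, s] %% n_blocks) + 1L
    }
    features <- lapply(seq_len(n_layers), function(s) {
      signal <- sqrt(effect) * t(G[, labels[, s], drop = FALSE])
      E <- matrix(stats::rnorm(n_regions * 9L, sd = noise_sd), n_regions, 9L)
      X <- sweep(sweep(signal + sqrt(1 - effect) * E, 2L, sc$sigma, "*"),
                 2L, sc$mu, "+")
      dimnames(X) <- list(sprintf("r%03d", seq_len(n_regions)), feats)
      X
    })
    structure(list(features = features, block_labels = labels,
                   switchers = sort(switchers), n_blocks = n_blocks,
                   seed = seed),
              class = "drifting_cohort")
  })
}

#' Write a cohort to FreeSurfer-style delimited tables
#'
#' Writes one TSV per subject (regions as rows, the 9 named feature columns),
#' a cohort metadata table (subject_id, age, sex, IQ) and the atlas lookup
#' table (region, hemisphere, lobe, cognitive_network, gyrus_sulcus).
#'
#' @param cohort A `cohort_features` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_features"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in seq_along(cohort$subjects)) {
    df <- data.frame(region = cohort$atlas$regions,
                     cohort$features[[s]], check.names = FALSE,
                     stringsAsFactors = FALSE)
    p <- file.path(dir, paste0(cohort$subjects[s], ".aparcstats.tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- data.frame(subject_id = cohort$subjects, age = cohort$age,
                     sex = cohort$sex, IQ = cohort$iq,
                     stringsAsFactors = FALSE)
  pm <- file.path(dir, "metadata.tsv")
  utils::write.table(meta, pm, sep = "\t", quote = FALSE, row.names = FALSE)
  at <- with(cohort$atlas,
             data.frame(region = regions, hemisphere = hemisphere, lobe = lobe,
                        cognitive_network = cognitive_network,
                        gyrus_sulcus = gyrus_sulcus, stringsAsFactors = FALSE))
  pa <- file.path(dir, "atlas_lookup.tsv")
  utils::write.table(at, pa, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, pm, pa))
}
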