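#' Bootstrap ensemble of multilayer flexibility profiles
#'
#' Generates `n_boot` bootstrap resamples of the cohort (with replacement, at
#' cohort size), orders the resampled layers either randomly or by ascending
#' age/IQ (ties broken by subject id), builds each multilayer stack, optimizes
#' its partition and stores the flexibility profile. Fully reproducible from
#' the master seed.
#'
#' @param msns Named list of per-subject `sparse_msn` objects.
#' @param metadata Data frame with `subject_id`, `age`, `IQ` columns covering
#'   the subjects in `msns`.
#' @param n_boot Number of bootstraps (default 500).
#' @param ordering `"random"`, `"age"` or `"IQ"`.
#' @param seed Master seed.
#' @param gamma,omega Passed to [multilayer_stack()].
#' @param n_samples Optimizer restarts per bootstrap (default 1000; reduce for
#'   exploratory runs).
#' @return A `bootstrap_ensemble`: list with `profiles` (list of
#'   `flexibility_profile`), `F` (per-bootstrap global flexibility),
#'   `f_matrix` (n_boot x N nodal flexibility), `resamples`, `ordering`,
#'   `seed`.
#' @export
bootstrap_ensemble <- function(msns, metadata, n_boot = 500L,
                               ordering = c("random", "age", "IQ"),
                               seed = 1L, gamma = 1.0, omega = 1.0,
                               n_samples = 1000L) {
  ordering <- match.arg(ordering)
  stopifnot(is.list(msns), length(msns) >= 2L)
  if (n_boot < 1L) stop("n_boot must be >= 1")
  ids <- names(msns)
  if (is.null(ids)) stop("msns must be a named list (subject ids)")
  meta <- metadata[match(ids, metadata$subject_id), , drop = FALSE]
  if (ordering != "random") {
    cov_col <- if (ordering == "age") "age" else "IQ"
    cov <- meta[[cov_col]]
    if (any(is.na(cov)))
      stop("missing ", cov_col, " for subject(s): ",
           paste(ids[is.na(cov)], collapse = ", "))
  }
  n <- length(msns)
  resamples <- vector("list", n_boot)
  profiles <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    boot_seed <- derive_seed(seed, b)
    idx <- with_seed(boot_seed, sample.int(n, n, replace = TRUE))
    ord <- if (ordering == "random") {
      with_seed(boot_seed + 1, sample.int(n))
    } else {
      order(cov[idx], ids[idx])
    }
    idx <- idx[ord]
    stack <- multilayer_stack(msns[idx], gamma = gamma, omega = omega,
                              ordering = ordering,
                              covariate = if (ordering == "random") NULL
                                          else cov[idx])
    part <- sample_best_partition(stack, n_samples = n_samples,
                                  seed = boot_seed + 2)
    profiles[[b]] <- nodal_flexibility(part)
    resamples[[b]] <- idx
  }
  f_matrix <- do.call(rbind, lapply(profiles, function(p) p$f))
  structure(list(profiles = profiles,
                 F = vapply(profiles, function(p) p$F, 0),
                 f_matrix = f_matrix, resamples = resamples,
                 ordering = ordering, n_boot = n_boot, seed = seed),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("<bootstrap_ensemble> %d bootstraps (%s ordering), F = %.3f +/- %.3f\n",
              x$n_boot, x$ordering, mean(x$F), stats::sd(x$F)))
  invisible(x)
}

#' Split subjects into three IQ groups around the mean
#'
#' Group 1: IQ below mean - 1 s.d.; group 3: IQ above mean + 1 s.d.; group 2:
#' everyone else. Subjects exactly at a boundary fall into group 2 ("away
#' from the mean" read strictly). With `balance = TRUE` the middle group is
#' randomly subsampled (seeded) to the size of the larger tail group, so that
#' the three groups are comparable in the group tests.
#'
#' @param metadata Data frame with `subject_id` and `IQ`.
#' @param balance Subsample group 2 to match the larger tail group.
#' @param seed Seed for the balancing draw.
#' @return Data frame with `subject_id`, `IQ`, `group` (1, 2, 3); balanced-out
#'   subjects are dropped when `balance = TRUE`.
#' @export
make_iq_groups <- function(metadata, balance = FALSE, seed = 1L) {
  iq <- metadata$IQ
  if (any(is.na(iq))) stop("IQ missing for some subjects")
  s <- stats::sd(iq)
  if (s == 0) stop("IQ standard deviation is zero")
  m <- mean(iq)
  group <- ifelse(iq < m - s, 1L, ifelse(iq > m + s, 3L, 2L))
  out <- data.frame(subject_id = metadata$subject_id, IQ = iq, group = group,
                    stringsAsFactors = FALSE)
  if (balance) {
    target <- max(sum(group == 1L), sum(group == 3L))
    mid <- which(out$group == 2L)
    if (length(mid) > target) {
      keep <- with_seed(seed, sample(mid, target))
      out <- out[sort(c(which(out$group != 2L), keep)), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}

#' Assign subjects to the 12 age bins
#'
#' Bins 1-10 are half-open 5-year intervals from age 6 (\[6,11), \[11,16),
#' ..., \[51,56)); bin 11 spans \[56,65) (containing the conventional 60-65
#' anchor) and bin 12 is \[65,85\]. Every subject falls in exactly one bin.
#'
#' @param metadata Data frame with `subject_id` and `age` in \[6, 85\].
#' @return Data frame with `subject_id`, `age`, `bin` (1-12).
#' @export
make_age_bins <- function(metadata) {
  age <- metadata$age
  bad <- which(is.na(age) | age < 6 | age > 85)
  if (length(bad))
    stop("age outside [6, 85] for subject(s): ",
         paste(metadata$subject_id[bad], collapse = ", "))
  breaks <- c(seq(6, 56, by = 5), 65, 85)
  bin <- cut(age, breaks = breaks, right = FALSE, include.lowest = TRUE,
             labels = FALSE)
  data.frame(subject_id = metadata$subject_id, age = age, bin = as.integer(bin),
             stringsAsFactors = FALSE)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Studentizes the sample and tests it against the standard normal with the
#' one-sample KS test.
#'
#' @param values Numeric sample, n >= 5, non-constant.
#' @return A `group_test_result`: list with `test`, `statistic`, `p_value`,
#'   `n`.
#' @export
ks_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5L) stop("need at least 5 values")
  s <- stats::sd(values)
  if (s == 0) stop("constant sample")
  z <- (values - mean(values)) / s
  kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
  structure(list(test = "KS", statistic = unname(kt$statistic),
                 p_value = kt$p.value, n = length(values)),
            class = "group_test_result")
}

#' Kruskal-Wallis test across groups, with optional pairwise follow-up
#'
#' Rank-based one-way analysis of variance: the H statistic with tie
#' correction is referred to a chi-squared distribution with (g - 1) degrees
#' of freedom. When H is significant at `alpha` and `posthoc = TRUE`, a
#' Holm-adjusted pairwise rank-sum follow-up is run.
#'
#' @param groups List of >= 2 numeric samples, each with n >= 2.
#' @param posthoc Run the pairwise follow-up when significant.
#' @param alpha Significance level gating the follow-up (default 0.05).
#' @return A `group_test_result`: `test = "KW"`, `statistic` (chi-squared
#'   scale), `df`, `p_value`, `group_sizes`, and `pairwise` (matrix of
#'   Holm-adjusted p-values, or NULL).
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$statistic  # 7.2
#' @export
kruskal_wallis <- function(groups, posthoc = TRUE, alpha = 0.05) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("each group needs at least 2 values")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  kt <- stats::kruskal.test(x, g)
  pairwise <- NULL
  if (posthoc && length(groups) > 2L && isTRUE(kt$p.value < alpha)) {
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(x, g, p.adjust.method = "holm"))
    pairwise <- pw$p.value
  }
  structure(list(test = "KW", statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p_value = kt$p.value,
                 group_sizes = vapply(groups, length, 0L),
                 pairwise = pairwise),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  if (x$test == "KW")
    cat(sprintf("Kruskal-Wallis: chi-squared = %.4g, df = %d, p = %.4g (groups: %s)\n",
                x$statistic, x$df, x$p_value,
                paste(x$group_sizes, collapse = "/")))
  else
    cat(sprintf("One-sample KS vs normal: D = %.4g, p = %.4g (n = %d)\n",
                x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Correlate mean signed edge weights with a covariate
#'
#' Pearson correlation (with two-sided p-value) between each subject's mean
#' positive — and, separately, mean negative — retained edge weight and a
#' covariate such as age or IQ.
#'
#' @param weights Data frame with columns `mean_positive`, `mean_negative`
#'   and the covariate column (one row per subject), e.g. built by applying
#'   [mean_signed_weights()] across a cohort.
#' @param covariate Name of the covariate column (e.g. `"age"`, `"IQ"`).
#' @return Data frame with `sign`, `r`, `p`, `n` (NA rows when a sign class
#'   is absent for some subjects).
#' @export
correlate_edge_weights <- function(weights, covariate) {
  stopifnot(is.data.frame(weights), covariate %in% names(weights))
  if (nrow(weights) < 3L) stop("need at least 3 subjects")
  cv <- weights[[covariate]]
  if (stats::sd(cv) == 0) stop("zero-variance covariate: ", covariate)
  one <- function(col, sign) {
    w <- weights[[col]]
    ok <- !is.na(w)
    if (sum(ok) < 3L)
      return(data.frame(sign = sign, r = NA_real_, p = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    ct <- stats::cor.test(w[ok], cv[ok])
    data.frame(sign = sign, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  }
  rbind(one("mean_positive", "positive"), one("mean_negative", "negative"))
}
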