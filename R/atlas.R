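#' Cortical parcellation specifications
#'
#' Builds an atlas specification for one of the two supported cortical
#' parcellations: the gyral-based Desikan-Killiany atlas (`"DKA"`, 34 regions
#' per hemisphere, 68 in total) or the finer Destrieux atlas (`"DA"`, 74
#' labels per hemisphere, 148 in total). Each region carries a hemisphere
#' (`L`/`R`), one of six lobes (cingulate, frontal, insular, occipital,
#' parietal, temporal), an optional cognitive-network membership (DMN, SN,
#' VIS, CEN or `"none"`), and a gyrus/sulcus flag. Lobe and cognitive-network
#' maps are packaged lookup tables under `inst/extdata`; the cognitive-network
#' assignment is the package's own documented configuration, exposed so users
#' can substitute their own.
#'
#' @param name Atlas label, `"DKA"` or `"DA"`.
#' @return An object of class `atlas_spec`: a list with elements `name`,
#'   `regions` (ordered labels, `lh_`/`rh_` prefixed), `hemisphere`, `lobe`,
#'   `cognitive_network`, `gyrus_sulcus` (all parallel to `regions`) and `N`.
#' @examples
#' atlas <- generate_atlas("DKA")
#' atlas$N            # 68
#' table(atlas$lobe)  # six lobes
#' @export
generate_atlas <- function(name) {
  supported <- c("DKA", "DA")
  if (!is.character(name) || length(name) != 1L || !name %in% supported)
    stop("unknown atlas '", paste(name, collapse = ","),
         "'; supported atlases: ", paste(supported, collapse = ", "))
  file <- if (name == "DKA") "atlas_dka_base.tsv" else "atlas_da_base.tsv"
  path <- system.file("extdata", file, package = "msnflex", mustWork = TRUE)
  base <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  n_hemi <- nrow(base)
  structure(list(
    name              = name,
    regions           = c(paste0("lh_", base$region), paste0("rh_", base$region)),
    hemisphere        = rep(c("L", "R"), each = n_hemi),
    lobe              = rep(base$lobe, 2L),
    cognitive_network = rep(base$cognitive_network, 2L),
    gyrus_sulcus      = rep(base$gyrus_sulcus, 2L),
    N                 = 2L * n_hemi
  ), class = "atlas_spec")
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat("<atlas_spec> ", x$name, ": ", x$N, " regions (",
      sum(x$hemisphere == "L"), " per hemisphere)\n", sep = "")
  cat("  lobes: ", paste(names(table(x$lobe)), table(x$lobe) / 2,
                         sep = "=", collapse = ", "),
      " (per hemisphere)\n", sep = "")
  invisible(x)
}

# Names of the nine FreeSurfer-style morphometric features, in canonical order.
#' Morphometric feature sets
#'
#' Returns the ordered feature names for one of the four feature combinations
#' used to build morphometric similarity networks: all nine surface features
#' (`"9f"`), a five-feature volumetric/curvature mix (`"5f"`), the four
#' volumetric features (`"4v"`), or the four curvature features (`"4c"`).
#' Feature names follow the FreeSurfer `aparc.stats` column convention.
#'
#' @param id One of `"9f"`, `"5f"`, `"4v"`, `"4c"`.
#' @return Character vector of feature (column) names.
#' @examples
#' feature_set("4v")
#' @export
feature_set <- function(id) {
  sets <- list(
    "9f" = c("NumVert", "SurfArea", "GrayVol", "ThickAvg", "ThickStd",
             "MeanCurv", "GausCurv", "FoldInd", "CurvInd"),
    "5f" = c("GrayVol", "SurfArea", "ThickAvg", "GausCurv", "FoldInd"),
    "4v" = c("GrayVol", "SurfArea", "ThickAvg", "ThickStd"),
    "4c" = c("MeanCurv", "GausCurv", "FoldInd", "CurvInd")
  )
  if (!is.character(id) || length(id) != 1L || !id %in% names(sets))
    stop("unknown feature set '", paste(id, collapse = ","),
         "'; supported: ", paste(names(sets), collapse = ", "))
  sets[[id]]
}

all_features <- function() feature_set("9f")

feature_set_ids <- function() c("9f", "5f", "4v", "4c")
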