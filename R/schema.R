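# Feature schemas for the three modalities.
#
# The structural-MRI schema mirrors a FreeSurfer-style morphometric export:
# 52 subcortical volumes plus 8 statistics for each of 68 cortical
# parcellations (34 per hemisphere, Desikan-Killiany naming), 596 features in
# all. The diffusion schema covers 76 white-matter tracts x 4 tensor-derived
# measures (FA, MD, longitudinal and radial diffusivity), 304 features.
# Subcortical structure and tract name lists are a deterministic emulation of
# such exports (the study's own supplementary tables are not distributed);
# counts, uniqueness and grouping are the contract.

.ganest_subcortical <- c(
  "thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala",
  "accumbens_area", "ventral_dc", "lateral_ventricle", "inf_lat_ventricle",
  "cerebellum_cortex", "cerebellum_white_matter", "cerebral_white_matter",
  "choroid_plexus", "vessel", "wm_hypointensities", "claustrum",
  "nucleus_basalis", "habenula", "subthalamic_nucleus", "red_nucleus",
  "substantia_nigra", "mammillary_body", "septal_nuclei",
  "olfactory_tubercle", "basal_forebrain"
)

.ganest_parcellations <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
)

# surface area (mm^2), gray-matter volume (mm^3), mean/sd cortical thickness
# (mm), integrated rectified mean (mm^-1) and gaussian (mm^-2) curvature,
# folding index and intrinsic curvature index (unitless)
.ganest_cortical_stats <- c(
  "surfarea", "grayvol", "thickavg", "thickstd",
  "meancurv", "gauscurv", "foldind", "curvind"
)

.ganest_tracts <- c(
  "arcuate_fasciculus", "uncinate_fasciculus",
  "superior_longitudinal_fasciculus_1", "superior_longitudinal_fasciculus_2",
  "superior_longitudinal_fasciculus_3", "inferior_longitudinal_fasciculus",
  "inferior_fronto_occipital_fasciculus", "frontal_aslant_tract",
  "cingulum_dorsal", "cingulum_ventral", "fornix", "stria_terminalis",
  "optic_radiation", "acoustic_radiation", "corticospinal_tract",
  "corticobulbar_tract", "frontopontine_tract", "parietopontine_tract",
  "occipitopontine_tract", "temporopontine_tract",
  "thalamic_radiation_anterior", "thalamic_radiation_superior",
  "thalamic_radiation_posterior", "cc_dlpfc", "cc_frontal_pole", "cc_motor",
  "cc_premotor", "cc_parietal", "cc_temporal", "cc_occipital",
  "frontostriatal_dlpfc", "frontostriatal_motor",
  "frontostriatal_orbitofrontal", "extreme_capsule", "medial_lemniscus",
  "central_tegmental_tract", "dentatorubrothalamic_tract",
  "middle_longitudinal_fasciculus"
)

.ganest_diffusion_measures <- c("fa", "md", "ld", "rd")

.ganest_clinical_default <- c(
  "age", "sex", "disease_duration", "weight", "cfs_baseline",
  "pain_vas", "hads_depression", "hads_anxiety"
)

#' Build the feature schema for one modality
#'
#' Constructs the named, ordered feature list a modality's subject-by-feature
#' table must conform to: \code{"smri"} has 596 features (52 subcortical
#' volumes followed by 68 parcellations x 8 morphometric statistics),
#' \code{"dti"} has 304 (76 tracts x 4 diffusion measures), and
#' \code{"clinical"} takes a user-supplied variable list (default: age, sex,
#' disease duration, weight, baseline Chalder Fatigue Scale score, daily pain
#' VAS, and HADS depression/anxiety).
#'
#' Each feature carries a group tag (structure, parcellation, tract, or the
#' variable itself) used by the synthetic-cohort generator to correlate
#' features of the same anatomical unit, as real morphometrics are.
#'
#' @param modality One of `"smri"`, `"dti"`, `"clinical"`.
#' @param clinical_names Character vector of clinical variable names; only
#'   used (and only allowed to vary) for `modality = "clinical"`.
#' @return An object of class `feature_schema`: a list with `modality`,
#'   `feature_names` and `group_tags`.
#' @examples
#' length(build_schema("smri")$feature_names)  # 596
#' length(build_schema("dti")$feature_names)   # 304
#' @export
build_schema <- function(modality = c("smri", "dti", "clinical"),
                         clinical_names = NULL) {
  modality <- match.arg(modality)
  if (modality == "smri") {
    sub_names <- unlist(lapply(.ganest_subcortical, function(s)
      paste(c("lh", "rh"), s, "volume", sep = "_")))
    sub_tags <- rep(.ganest_subcortical, each = 2)
    cort <- expand.grid(stat = .ganest_cortical_stats,
                        parc = .ganest_parcellations,
                        hemi = c("lh", "rh"), stringsAsFactors = FALSE)
    cort_names <- paste(cort$hemi, cort$parc, cort$stat, sep = "_")
    cort_tags <- paste(cort$hemi, cort$parc, sep = "_")
    names <- c(sub_names, cort_names)
    tags <- c(sub_tags, cort_tags)
  } else if (modality == "dti") {
    dti <- expand.grid(measure = .ganest_diffusion_measures,
                       hemi = c("l", "r"),
                       tract = .ganest_tracts, stringsAsFactors = FALSE)
    names <- paste(dti$tract, dti$hemi, dti$measure, sep = "_")
    tags <- paste(dti$tract, dti$hemi, sep = "_")
  } else {
    names <- clinical_names %||% .ganest_clinical_default
    if (!is.character(names) || length(names) < 1) {
      stop_ganest("clinical_names must be a non-empty character vector")
    }
    if (anyDuplicated(names)) {
      stop_ganest("duplicate clinical feature names: ",
                  paste(unique(names[duplicated(names)]), collapse = ", "))
    }
    tags <- names
  }
  if (modality != "clinical" && !is.null(clinical_names)) {
    stop_ganest("clinical_names is only meaningful for modality = 'clinical'")
  }
  stopifnot(!anyDuplicated(names))
  structure(list(modality = modality,
                 feature_names = names,
                 group_tags = tags),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> modality '%s': %d features, %d groups\n",
              x$modality, length(x$feature_names), length(unique(x$group_tags))))
  invisible(x)
}

#' @export
length.feature_schema <- function(x) length(x$feature_names)
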