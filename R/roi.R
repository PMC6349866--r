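#' The 90-region cerebral parcellation labels
#'
#' Region labels of the standard 90-region automated anatomical labeling
#' (AAL) cerebral parcellation, left/right interleaved and ordered by the
#' conventional atlas numbering.  Any atlas with unique labels may be used
#' throughout the package; this is the default for simulation and for the
#' region-pooling map.
#'
#' @return Character vector of 90 labels.
#' @export
aal90_labels <- function() {
  base <- c("Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
            "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
            "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
            "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
            "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
            "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
            "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
            "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
            "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
            "Pallidum", "Thalamus", "Heschl", "Temporal_Sup",
            "Temporal_Pole_Sup", "Temporal_Mid", "Temporal_Pole_Mid",
            "Temporal_Inf")
  as.vector(rbind(paste0(base, "_L"), paste0(base, "_R")))
}

#' Region-pooling map: 30 retrieval-related ROIs into 7 bilateral regions
#'
#' The memory-retrieval ROI set pooled into seven large bilateral regions:
#' hippocampus; parahippocampus; prefrontal cortex (inferior frontal
#' triangularis, superior medial frontal, superior frontal, middle frontal,
#' middle orbital frontal); parietal lobe (supramarginal, angular, superior
#' parietal); temporal lobe (superior, middle and inferior temporal);
#' posterior cingulum; anterior cingulum.
#'
#' @return A data frame with columns `roi` (atlas label) and `region`.
#' @export
region_pooling_map <- function() {
  groups <- list(
    hippocampus        = "Hippocampus",
    parahippocampus    = "ParaHippocampal",
    prefrontal         = c("Frontal_Inf_Tri", "Frontal_Sup_Medial",
                           "Frontal_Sup", "Frontal_Mid", "Frontal_Mid_Orb"),
    parietal           = c("SupraMarginal", "Angular", "Parietal_Sup"),
    temporal           = c("Temporal_Sup", "Temporal_Mid", "Temporal_Inf"),
    posterior_cingulum = "Cingulum_Post",
    anterior_cingulum  = "Cingulum_Ant"
  )
  df <- do.call(rbind, lapply(names(groups), function(g)
    data.frame(roi = as.vector(rbind(paste0(groups[[g]], "_L"),
                                     paste0(groups[[g]], "_R"))),
               region = g, stringsAsFactors = FALSE)))
  df
}
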