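#' The 90 cerebral regions of the AAL atlas
#'
#' Region names of the Automated Anatomical Labelling (AAL) parcellation
#' restricted to the 90 cerebral nodes (cerebellum and vermis excluded, as is
#' standard for structural connectome work in small vessel disease). Node ids
#' are 1-based positions in this vector; connectome matrices use the same
#' order for rows and columns. The list also ships as a plain-text resource
#' at `system.file("extdata", "aal90_regions.csv", package = "apathynet")`.
#'
#' @return character vector of length 90.
#' @export
#' @examples
#' length(aal90_labels())
#' aal90_labels()[73:74]  # bilateral putamen
aal90_labels <- function() {
  c("Precentral_L", "Precentral_R", "Frontal_Sup_L", "Frontal_Sup_R",
    "Frontal_Sup_Orb_L", "Frontal_Sup_Orb_R", "Frontal_Mid_L",
    "Frontal_Mid_R", "Frontal_Mid_Orb_L", "Frontal_Mid_Orb_R",
    "Frontal_Inf_Oper_L", "Frontal_Inf_Oper_R", "Frontal_Inf_Tri_L",
    "Frontal_Inf_Tri_R", "Frontal_Inf_Orb_L", "Frontal_Inf_Orb_R",
    "Rolandic_Oper_L", "Rolandic_Oper_R", "Supp_Motor_Area_L",
    "Supp_Motor_Area_R", "Olfactory_L", "Olfactory_R",
    "Frontal_Sup_Medial_L", "Frontal_Sup_Medial_R", "Frontal_Med_Orb_L",
    "Frontal_Med_Orb_R", "Rectus_L", "Rectus_R", "Insula_L", "Insula_R",
    "Cingulum_Ant_L", "Cingulum_Ant_R", "Cingulum_Mid_L", "Cingulum_Mid_R",
    "Cingulum_Post_L", "Cingulum_Post_R", "Hippocampus_L", "Hippocampus_R",
    "ParaHippocampal_L", "ParaHippocampal_R", "Amygdala_L", "Amygdala_R",
    "Calcarine_L", "Calcarine_R", "Cuneus_L", "Cuneus_R", "Lingual_L",
    "Lingual_R", "Occipital_Sup_L", "Occipital_Sup_R", "Occipital_Mid_L",
    "Occipital_Mid_R", "Occipital_Inf_L", "Occipital_Inf_R", "Fusiform_L",
    "Fusiform_R", "Postcentral_L", "Postcentral_R", "Parietal_Sup_L",
    "Parietal_Sup_R", "Parietal_Inf_L", "Parietal_Inf_R", "SupraMarginal_L",
    "SupraMarginal_R", "Angular_L", "Angular_R", "Precuneus_L",
    "Precuneus_R", "Paracentral_Lobule_L", "Paracentral_Lobule_R",
    "Caudate_L", "Caudate_R", "Putamen_L", "Putamen_R", "Pallidum_L",
    "Pallidum_R", "Thalamus_L", "Thalamus_R", "Heschl_L", "Heschl_R",
    "Temporal_Sup_L", "Temporal_Sup_R", "Temporal_Pole_Sup_L",
    "Temporal_Pole_Sup_R", "Temporal_Mid_L", "Temporal_Mid_R",
    "Temporal_Pole_Mid_L", "Temporal_Pole_Mid_R", "Temporal_Inf_L",
    "Temporal_Inf_R")
}

#' Define a sub-network over the AAL-90 parcellation
#'
#' Resolves a set of AAL region names to node ids, checking that every name
#' exists in the 90-region list and that the set is non-empty and free of
#' duplicates.
#'
#' @param name label for the sub-network (e.g. `"reward"`).
#' @param node_names character vector of AAL-90 region names.
#' @return an object of class `subnetwork_def` with fields `name`,
#'   `node_names` and resolved 1-based `node_ids`.
#' @export
subnetwork <- function(name, node_names) {
  labels <- aal90_labels()
  if (length(node_names) == 0) stop("sub-network node list is empty")
  if (anyDuplicated(node_names)) {
    stop("duplicate region names in sub-network: ",
         paste(unique(node_names[duplicated(node_names)]), collapse = ", "))
  }
  ids <- match(node_names, labels)
  if (anyNA(ids)) {
    stop("unknown AAL-90 region name(s): ",
         paste(node_names[is.na(ids)], collapse = ", "))
  }
  structure(list(name = name, node_names = node_names, node_ids = ids),
            class = "subnetwork_def")
}

#' Built-in a-priori sub-networks: reward, motor, visual
#'
#' The three anatomically pre-defined sub-networks used to test whether
#' reward-circuit connectivity specifically explains apathy, with motor and
#' visual networks as experimental controls.
#'
#' Region-name conventions: "anterior cingulate cortex" maps to AAL
#' `Cingulum_Ant`; "superior medial cortex" to `Frontal_Sup_Medial`;
#' "inferior/medial orbitofrontal cortex" to `Frontal_Inf_Orb` /
#' `Frontal_Med_Orb`; "superior/middle temporal pole" to
#' `Temporal_Pole_Sup` / `Temporal_Pole_Mid`; "parietal superior cortex" to
#' `Parietal_Sup`. AAL-90 has no separate nucleus accumbens node; the
#' putamen node incorporates it. All sub-networks are bilateral. The reward
#' network has 16 nodes, motor 6, visual 10; reward and motor share the
#' bilateral putamen.
#'
#' @return named list of three `subnetwork_def` objects
#'   (`reward`, `motor`, `visual`).
#' @export
#' @examples
#' sn <- builtin_subnetworks()
#' length(sn$reward$node_ids)  # 16
#' intersect(sn$reward$node_names, sn$motor$node_names)
builtin_subnetworks <- function() {
  bilateral <- function(stems) as.vector(t(outer(stems, c("_L", "_R"), paste0)))
  list(
    reward = subnetwork("reward", bilateral(c(
      "Cingulum_Ant", "Putamen", "Frontal_Inf_Orb", "Frontal_Med_Orb",
      "Frontal_Sup_Medial", "Amygdala", "Temporal_Pole_Sup",
      "Temporal_Pole_Mid"))),
    motor = subnetwork("motor", bilateral(c(
      "Precentral", "Supp_Motor_Area", "Putamen"))),
    visual = subnetwork("visual", bilateral(c(
      "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
      "Parietal_Sup")))
  )
}

#' Read custom sub-network definitions from a YAML file
#'
#' The file maps sub-network names to lists of AAL-90 region names, e.g.
#' `limbic: [Hippocampus_L, Hippocampus_R, Amygdala_L, Amygdala_R]`.
#'
#' @param path YAML file path.
#' @return named list of `subnetwork_def`.
#' @export
read_subnetworks <- function(path) {
  defs <- yaml::read_yaml(path)
  if (!is.list(defs) || is.null(names(defs))) {
    stop("sub-network file must be a named mapping of name -> region list")
  }
  stats::setNames(
    lapply(names(defs), function(nm) subnetwork(nm, unlist(defs[[nm]]))),
    names(defs))
}
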