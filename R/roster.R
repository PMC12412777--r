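#' Canonical organ-at-risk roster
#'
#' The fixed, ordered list of the 44 head-and-neck structures the channel
#' assembly reserves slots for. Channel order in every assembly follows this
#' roster, so tensors are comparable across patients regardless of which
#' structures were actually contoured. The list covers the body contour,
#' paired and combined salivary/masticatory structures, the optic apparatus,
#' swallowing structures, the spinal cord/canal, temporal lobes and the
#' posterior neck region.
#'
#' @return A character vector of 44 unique structure names in canonical order.
#' @examples
#' length(oar_roster()) # 44
#' @export
oar_roster <- function() {
  c(
    "body",
    "brachial_plexus_left", "brachial_plexus_right",
    "brain", "brainstem",
    "cerebellum_left", "cerebellum_right",
    "cochlea_left", "cochlea_right",
    "constrictor_superior", "constrictor_middle", "constrictor_inferior",
    "constrictor_combined",
    "esophagus", "larynx", "mandible",
    "masseter_left", "masseter_right", "masseter_combined",
    "oral_cavity", "postarytenoid_cricoid_space",
    "parotid_left", "parotid_right", "parotid_combined",
    "submandibular_left", "submandibular_right",
    "lacrimal_left", "lacrimal_right",
    "optic_nerve_left", "optic_nerve_right",
    "optic_chiasm", "optic_pathway",
    "eye_left", "eye_right",
    "thyroid", "spinal_cord", "spinal_canal",
    "soft_palate", "epiglottis",
    "temporal_lobe_left", "temporal_lobe_right",
    "superior_parotid_left", "superior_parotid_right",
    "posterior_neck"
  )
}

#' Position of structures in the canonical roster
#'
#' @param names Character vector of structure names.
#' @return Integer positions in [oar_roster()] order; an error if any name is
#'   not a roster member.
#' @export
roster_index <- function(names) {
  idx <- match(names, oar_roster())
  if (anyNA(idx)) {
    fail_validation(paste0(
      "unknown structure name(s): ",
      paste(names[is.na(idx)], collapse = ", ")
    ))
  }
  idx
}
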