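#' Biomarker definitions
#'
#' A `biomarker_defs` object describes the biomarker panel the progression
#' model operates on: one row per biomarker with its direction of progression
#' and the candidate z-score events considered for it. Directions follow the
#' clinical convention: `+1` for biomarkers that increase with severity
#' (pain scores, osteophyte and sclerosis grades) and `-1` for biomarkers
#' that decrease (joint space width, cartilage thickness). During z-scoring
#' decreasing biomarkers are sign-flipped so that every z-score grows as the
#' disease progresses.
#'
#' @param name character vector of biomarker identifiers (unique).
#' @param direction integer vector of `+1` / `-1`, recycled if length 1.
#' @param candidate_events list of strictly increasing numeric vectors, each
#'   a non-empty subset of `c(1, 2, 3, 5)`; recycled if a single vector is
#'   given.
#' @return A data frame of class `biomarker_defs` with columns `name`,
#'   `direction`, and list-column `candidate_events`.
#' @examples
#' biomarker_defs(c("pain", "jsw"), c(1, -1), list(c(1, 2, 3), c(1, 2)))
#' @export
biomarker_defs <- function(name, direction, candidate_events = list(c(1, 2, 3, 5))) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop_("biomarker names must be unique")
  if (length(direction) == 1L) direction <- rep(direction, length(name))
  if (is.numeric(candidate_events)) candidate_events <- list(candidate_events)
  if (length(candidate_events) == 1L) {
    candidate_events <- rep(candidate_events, length(name))
  }
  if (length(direction) != length(name) || length(candidate_events) != length(name)) {
    stop_("name, direction and candidate_events lengths disagree")
  }
  if (!all(direction %in% c(-1, 1))) stop_("direction must be +1 or -1")
  for (i in seq_along(candidate_events)) {
    ev <- candidate_events[[i]]
    if (length(ev) == 0L) stop_("candidate_events empty for biomarker '", name[i], "'")
    if (is.unsorted(ev, strictly = TRUE)) {
      stop_("candidate_events must be strictly increasing for biomarker '", name[i], "'")
    }
    if (!all(ev %in% c(1, 2, 3, 5))) {
      stop_("candidate_events must be a subset of {1,2,3,5} for biomarker '", name[i], "'")
    }
  }
  out <- data.frame(name = name, direction = as.integer(direction),
                    stringsAsFactors = FALSE)
  out$candidate_events <- candidate_events
  class(out) <- c("biomarker_defs", "data.frame")
  out
}

#' Maximum z-score input for a largest retained event
#'
#' The linear z-score model needs a plateau value for each biomarker: the
#' z-score it tends to at the final stage. Per the event-to-plateau mapping,
#' a biomarker whose largest retained event is z = 1, 2, 3 or 5 is assigned a
#' maximum z of 2, 3, 5 or 7 respectively.
#'
#' @param largest_event numeric vector with values in `c(1, 2, 3, 5)`.
#' @return numeric vector of maximum z values.
#' @examples
#' max_z_for(c(1, 2, 3, 5)) # 2 3 5 7
#' @export
max_z_for <- function(largest_event) {
  map <- c(`1` = 2, `2` = 3, `3` = 5, `5` = 7)
  key <- as.character(largest_event)
  if (any(!key %in% names(map))) {
    stop_("largest retained event must be one of 1, 2, 3, 5")
  }
  unname(map[key])
}

#' The 13-biomarker knee-osteoarthritis panel
#'
#' The default panel used throughout the package: WOMAC pain, medial minimum
#' joint space width, four osteophyte compartments, two sclerosis
#' compartments, and five cartilage-thickness subregions. The panel carries
#' 32 z-score events in total; events are the first k candidates of
#' {1, 2, 3, 5} for a biomarker with k events.
#'
#' @return A `biomarker_defs` object with 13 rows.
#' @examples
#' panel <- koa_biomarker_panel()
#' sum(lengths(panel$candidate_events)) # 32
#' @export
koa_biomarker_panel <- function() {
  nm <- c("womac_pain", "min_jsw_medial",
          "osteophytes_tibia_medial", "osteophytes_tibia_lateral",
          "osteophytes_femur_lateral", "osteophytes_femur_medial",
          "sclerosis_femur_medial", "sclerosis_tibia_medial",
          "cartilage_cmf_external", "cartilage_cmf_center",
          "cartilage_cmf_internal", "cartilage_clf_internal",
          "cartilage_clf_external")
  dir <- c(1, -1, 1, 1, 1, 1, 1, 1, -1, -1, -1, -1, -1)
  n_events <- c(3, 3, 3, 2, 3, 2, 2, 1, 3, 3, 2, 2, 3)
  cand <- lapply(n_events, function(k) c(1, 2, 3, 5)[seq_len(k)])
  biomarker_defs(nm, dir, cand)
}
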