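#' Z-score event sets
#'
#' An `event_set` enumerates the atomic units of progression: each event is a
#' biomarker crossing a fixed z-score threshold relative to controls. The
#' total number of events S defines the stage axis: a subject at stage k has
#' had exactly the first k events of its subtype's sequence occur.
#'
#' @name event_set
NULL

new_event_set <- function(events, max_z, defs) {
  # events: data.frame(biomarker, z) ordered by biomarker then z
  stopifnot(is.data.frame(events), all(c("biomarker", "z") %in% names(events)))
  for (bm in unique(events$biomarker)) {
    zz <- events$z[events$biomarker == bm]
    if (is.unsorted(zz, strictly = TRUE)) {
      stop_("event thresholds must strictly increase within biomarker '", bm, "'")
    }
    if (max_z[[bm]] <= max(zz)) {
      stop_("max_z must exceed the largest retained event for biomarker '", bm, "'")
    }
  }
  structure(
    list(events = events, max_z = max_z, defs = defs, S = nrow(events)),
    class = "event_set"
  )
}

#' Build the full event set implied by a biomarker panel
#'
#' Uses every candidate event of every biomarker, without the data-driven
#' occupancy filter of [build_event_set()]. Useful for simulation, where the
#' ground-truth event set is a modelling choice rather than a data property.
#'
#' @param defs a [biomarker_defs()] object.
#' @return An `event_set`.
#' @export
event_set_from_defs <- function(defs) {
  stopifnot(inherits(defs, "biomarker_defs"))
  events <- do.call(rbind, lapply(seq_len(nrow(defs)), function(i) {
    data.frame(biomarker = defs$name[i], z = defs$candidate_events[[i]],
               stringsAsFactors = FALSE)
  }))
  rownames(events) <- NULL
  max_z <- vapply(seq_len(nrow(defs)),
                  function(i) max_z_for(max(defs$candidate_events[[i]])),
                  numeric(1))
  names(max_z) <- defs$name
  new_event_set(events, max_z, defs)
}

#' @export
print.event_set <- function(x, ...) {
  cat("Z-score event set:", x$S, "events across",
      length(unique(x$events$biomarker)), "biomarkers\n")
  counts <- table(factor(x$events$biomarker, levels = unique(x$events$biomarker)))
  for (bm in names(counts)) {
    zz <- x$events$z[x$events$biomarker == bm]
    cat(sprintf("  %-28s events z = %-10s max z = %g\n",
                bm, paste(zz, collapse = ","), x$max_z[[bm]]))
  }
  invisible(x)
}

#' Validate an event sequence
#'
#' A sequence is a permutation of the event set's S events (positions 1..S).
#' Because the events of one biomarker are ordered z-thresholds, a valid
#' sequence must place them in strictly increasing z order.
#'
#' @param seq integer vector: `seq[p]` is the event index at position `p`.
#' @param eventset an `event_set`.
#' @return `seq`, invisibly, if valid; otherwise an error.
#' @export
validate_sequence <- function(seq, eventset) {
  S <- eventset$S
  if (length(seq) != S || !setequal(seq, seq_len(S))) {
    stop_("sequence must be a permutation of the ", S, " event indices")
  }
  if (!sequence_is_valid(seq, eventset)) {
    stop_("within-biomarker events must appear in increasing z order")
  }
  invisible(seq)
}

#' @rdname validate_sequence
#' @export
sequence_is_valid <- function(seq, eventset) {
  bm <- eventset$events$biomarker[seq]
  z <- eventset$events$z[seq]
  for (b in unique(bm)) {
    if (is.unsorted(z[bm == b], strictly = TRUE)) return(FALSE)
  }
  TRUE
}

#' Draw a uniformly random valid event sequence
#'
#' Samples a uniform random permutation of positions and then forces each
#' biomarker's events into increasing z order within the positions it
#' received; this yields the uniform distribution over valid sequences.
#'
#' @param eventset an `event_set`.
#' @return An integer sequence vector.
#' @export
random_sequence <- function(eventset) {
  S <- eventset$S
  perm <- sample.int(S)
  bm <- eventset$events$biomarker
  out <- integer(S)
  for (b in unique(bm)) {
    idx <- which(bm == b)                  # event ids of this biomarker, z-sorted
    pos <- sort(which(bm[perm] == b))      # positions allotted to it
    out[pos] <- idx
  }
  validate_sequence(out, eventset)
  out
}
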