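# Round-trip evaluation: does classification of simulated observables
# recover the generating events?

#' Score class recovery of ground-truth events
#'
#' Matches each ground-truth event record from [simulateClone()] against a
#' [classifySample()] report.  Simple events must be recovered exactly: a
#' deletion by a `deletion_type` junction at its flanks, a tandem
#' duplication by a `duplication_type` junction at its bounds, an
#' inversion by a junction pair assigned `inversion` at its bounds.  A
#' templated insertion is recovered when a detected event reproduces its
#' template interval to within `tol` bp; a breakage-fusion-bridge event
#' when a BFB event is called; a chromothripsis event when a called
#' shattered region overlaps the true region.
#'
#' @param events Ground-truth event list (`simulateClone()$events`).
#' @param report A [SampleReport-class].
#' @param tol Position tolerance in bp for templated-insertion templates.
#' @return `data.frame` with columns `eventClass` and `recovered`.
#' @export
eventRecovery <- function(events, report, tol = 1) {
  stopifnot(is(report, "SampleReport"))
  j <- report@junctions@junctions
  asg <- report@assignment
  evClass <- vapply(report@events, function(e) e$eventClass, character(1))
  rec <- vapply(events, function(ev) {
    cls <- ev$eventClass
    if (cls == "deletion") {
      iv <- ev$params$interval
      any(asg == "deletion_type" & j$posA == iv[1L] - 1 & j$posB == iv[2L])
    } else if (cls == "tandem_duplication") {
      iv <- ev$params$interval
      any(asg == "duplication_type" & j$posA == iv[1L] & j$posB == iv[2L] - 1)
    } else if (cls == "inversion") {
      iv <- ev$params$interval
      any(asg == "inversion" &
            ((j$posA == iv[1L] - 1 & j$posB == iv[2L] - 1) |
             (j$posA == iv[1L] & j$posB == iv[2L])))
    } else if (cls == "templated_insertion") {
      t0 <- ev$params$templateStart
      t1 <- t0 + ev$params$templateLen
      any(vapply(report@events, function(e)
        e$eventClass == "templated_insertion" &&
          abs(e$template[1L] - t0) <= tol &&
          abs(e$template[2L] - t1) <= tol, logical(1)))
    } else if (cls == "bfb") {
      "bfb" %in% evClass
    } else if (cls == "chromothripsis") {
      iv <- ev$params$region
      any(vapply(report@events, function(e)
        e$eventClass == "chromothripsis" &&
          e$region[1L] < iv[2L] && iv[1L] < e$region[2L], logical(1)))
    } else FALSE
  }, logical(1))
  data.frame(eventClass = vapply(events, function(e) e$eventClass,
                                 character(1)),
             recovered = rec, stringsAsFactors = FALSE)
}
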