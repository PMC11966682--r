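# Valence isomers of a reduced [4Fe4S]1+ cubane: enumeration of the six
# mixed-valence/ferrous pair partitions and their classification from
# broken-symmetry site spin populations.

#' Connectivity of a [4Fe4S] cubane
#'
#' Four Fe sites and four sulfide bridges in the standard cubane
#' arrangement: bridge `i` caps the face opposite Fe site `i`, so every Fe
#' is adjacent to the three bridges it does not face.
#'
#' @param sites Four Fe site labels.
#' @param bridges Four sulfide bridge labels.
#' @param planes Optional named character vector mapping pair keys
#'   (`"site1+site2"`, sites in `sites` order) to plane/layer labels used
#'   in conformer depictions. If given it must cover all 6 pairs.
#' @return An object of class `cubane_topology`.
#' @export
cubane_topology <- function(sites = c("Fe1", "Fe2", "Fe3", "Fe4"),
                            bridges = c("S1", "S2", "S3", "S4"),
                            planes = NULL) {
  if (length(sites) != 4L || anyDuplicated(sites))
    stop("a cubane has exactly 4 distinct Fe sites")
  if (length(bridges) != 4L || anyDuplicated(bridges))
    stop("a cubane has exactly 4 distinct sulfide bridges")
  adj <- lapply(seq_len(4L), function(i) bridges[-i])
  names(adj) <- sites
  if (!is.null(planes)) {
    keys <- apply(utils::combn(sites, 2), 2, paste, collapse = "+")
    if (!setequal(names(planes), keys))
      stop("planes must map all 6 site pairs (keys: ",
           paste(keys, collapse = ", "), ")")
  }
  structure(list(sites = sites, bridges = bridges, adjacency = adj,
                 planes = planes),
            class = "cubane_topology")
}

# pair key in canonical site order
.pair_key <- function(pair, sites) {
  paste(sites[sort(match(pair, sites))], collapse = "+")
}

#' One valence-isomer assignment
#'
#' @param mixed_valence Two site labels carrying the delocalised
#'   Fe2.5+-Fe2.5+ pair (majority spin, positive spin populations).
#' @param ferrous The two Fe2+ sites (minority spin, negative spin
#'   populations).
#' @param margin Classification confidence: the population gap between the
#'   two groups (`NA` for enumerated assignments).
#' @param plane_label Optional plane label from the topology's pair map.
#' @return An object of class `valence_assignment`.
#' @export
valence_assignment <- function(mixed_valence, ferrous, margin = NA_real_,
                               plane_label = NULL) {
  if (length(mixed_valence) != 2L || length(ferrous) != 2L)
    stop("each pair must contain exactly two sites")
  if (length(intersect(mixed_valence, ferrous)) > 0)
    stop("mixed-valence and ferrous pairs must be disjoint")
  structure(list(mixed_valence = as.character(mixed_valence),
                 ferrous = as.character(ferrous), margin = margin,
                 plane_label = plane_label),
            class = "valence_assignment")
}

#' @export
print.valence_assignment <- function(x, ...) {
  cat(sprintf("<valence_assignment> mixed-valence {%s} | ferrous {%s}%s%s\n",
              paste(x$mixed_valence, collapse = ","),
              paste(x$ferrous, collapse = ","),
              if (!is.na(x$margin)) sprintf(", margin %.3g", x$margin) else "",
              if (!is.null(x$plane_label)) paste0(" [", x$plane_label, "]")
              else ""))
  invisible(x)
}

#' Enumerate the valence isomers of a cubane
#'
#' A reduced \[4Fe4S\]1+ cluster partitions its four Fe sites into a
#' delocalised mixed-valence pair and a ferrous pair; choosing the
#' mixed-valence pair fixes the ferrous pair, giving the six energetically
#' inequivalent electronic states. Assignments are returned in
#' lexicographic order of the mixed-valence pair (site order of the
#' topology).
#'
#' @param topology A [cubane_topology()].
#' @return List of 6 [valence_assignment()] objects.
#' @examples
#' length(enumerate_valence_isomers(cubane_topology()))  # 6
#' @export
enumerate_valence_isomers <- function(topology = cubane_topology()) {
  stopifnot(inherits(topology, "cubane_topology"))
  sites <- topology$sites
  pairs <- utils::combn(4L, 2L)
  lapply(seq_len(ncol(pairs)), function(j) {
    mv <- sites[pairs[, j]]
    fe <- setdiff(sites, mv)
    valence_assignment(mv, fe,
                       plane_label = if (!is.null(topology$planes))
                         unname(topology$planes[.pair_key(mv, sites)])
                       else NULL)
  })
}

#' Classify the valence-isomer partition from site spin populations
#'
#' In a broken-symmetry description of the S = 1/2 ground state the
#' delocalised mixed-valence pair carries the majority (positive) spin
#' populations and the antiferromagnetically coupled ferrous pair the
#' minority (negative) ones. The two most positive populations therefore
#' define the mixed-valence pair; the classification requires the
#' physically meaningful 2-positive/2-negative sign pattern and is
#' scale-invariant.
#'
#' @param populations Four signed site spin populations (unpaired-electron
#'   units), named by site or matched positionally to `topology$sites`.
#' @param topology A [cubane_topology()].
#' @param sum_warn_threshold Warn when `|sum(populations)|` exceeds this
#'   value (default 2): an S = 1/2 state should have a modest net spin
#'   population, but broken-symmetry sums vary by population scheme, so
#'   this is a warning, never an error.
#' @return A [valence_assignment()] with `margin` set to the gap between
#'   the smallest mixed-valence and the largest ferrous population.
#' @section Errors: A sign pattern other than 2 positive / 2 negative
#'   raises a condition of class `eprmix_ambiguous_valence`; an exact tie
#'   at the group boundary raises `eprmix_valence_tie` whose condition
#'   carries both candidate partitions (`candidates` field).
#' @examples
#' classify_valence(c(Fe1 = 3.05, Fe2 = 3.10, Fe3 = -2.90, Fe4 = -2.95))
#' @export
classify_valence <- function(populations, topology = cubane_topology(),
                             sum_warn_threshold = 2) {
  stopifnot(inherits(topology, "cubane_topology"))
  if (length(populations) != 4L || any(!is.finite(populations)))
    stop("need exactly 4 finite site spin populations")
  sites <- topology$sites
  if (!is.null(names(populations))) {
    if (!setequal(names(populations), sites))
      stop("population names must match the topology's sites")
    populations <- populations[sites]
  } else names(populations) <- sites

  if (sum(populations > 0) != 2L || sum(populations < 0) != 2L)
    stop(structure(class = c("eprmix_ambiguous_valence", "error",
                             "condition"),
                   list(message = paste0(
                     "sign pattern is not 2 positive / 2 negative (",
                     paste(sprintf("%+.3g", populations), collapse = ", "),
                     "); no antiferromagnetic pair structure"),
                     call = sys.call(-1))))
  if (abs(sum(populations)) > sum_warn_threshold)
    warning("net spin population ", sprintf("%.3g", sum(populations)),
            " is large for an S = 1/2 state; check the population scheme")

  o <- order(populations, decreasing = TRUE)
  if (populations[o[2]] == populations[o[3]]) {
    cand <- list(
      valence_assignment(sites[sort(o[1:2])], sites[sort(o[3:4])]),
      valence_assignment(sites[sort(o[c(1, 3)])], sites[sort(o[c(2, 4)])]))
    stop(structure(class = c("eprmix_valence_tie", "error", "condition"),
                   list(message = "tie at the group boundary; partition is ambiguous",
                        call = sys.call(-1), candidates = cand)))
  }
  mv <- sites[sort(o[1:2])]
  fe <- sites[sort(o[3:4])]
  valence_assignment(mv, fe,
                     margin = unname(populations[o[2]] - populations[o[3]]),
                     plane_label = if (!is.null(topology$planes))
                       unname(topology$planes[.pair_key(mv, sites)])
                     else NULL)
}

#' Relate two valence-isomer assignments
#'
#' @param a,b [valence_assignment()] objects on the same topology.
#' @param topology A [cubane_topology()] whose sites both assignments use.
#' @return `"identical"` (same partition, same roles),
#'   `"plane_interchange"` (same partition, mixed-valence and ferrous roles
#'   swapped) or `"plane_reorientation"` (different partition).
#' @export
compare_assignments <- function(a, b, topology = cubane_topology()) {
  stopifnot(inherits(a, "valence_assignment"),
            inherits(b, "valence_assignment"))
  sa <- c(a$mixed_valence, a$ferrous)
  sb <- c(b$mixed_valence, b$ferrous)
  if (!setequal(sa, topology$sites) || !setequal(sb, topology$sites))
    stop("assignments do not live on the given topology's sites")
  if (setequal(a$mixed_valence, b$mixed_valence)) return("identical")
  if (setequal(a$mixed_valence, b$ferrous)) return("plane_interchange")
  "plane_reorientation"
}
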