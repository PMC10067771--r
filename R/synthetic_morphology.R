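# Synthetic CA1-like morphologies: soma + tapered apical trunk + oblique
# branches + basal stub + axon. Stands in for a 3D reconstruction so the full
# pipeline runs offline; it does not emulate full branching statistics.

#' Specification for a synthetic morphology
#'
#' @param trunk_length Apical trunk extent from the soma (um).
#' @param trunk_diam Proximal and distal trunk diameter (um), linear taper.
#' @param n_oblique Number of oblique side branches off the trunk.
#' @param oblique_length,oblique_diam Oblique geometry (um).
#' @param soma_L,soma_diam Soma cylinder (um).
#' @param n_basal,basal_length,basal_diam Basal dendrites (um).
#' @param axon_length,axon_diam Axon (um); the initial segment is designated
#'   at model-build time.
#' @param step Spacing of digitized points along neurites (um).
#' @return Named list of class `morph_spec`.
#' @export
morphology_spec <- function(trunk_length = 425, trunk_diam = c(4, 1),
                            n_oblique = 3, oblique_length = 60,
                            oblique_diam = 0.8,
                            soma_L = 20, soma_diam = 20,
                            n_basal = 2, basal_length = 150, basal_diam = 1.5,
                            axon_length = 100, axon_diam = 1, step = 10) {
  spec <- list(trunk_length = trunk_length, trunk_diam = trunk_diam,
               n_oblique = n_oblique, oblique_length = oblique_length,
               oblique_diam = oblique_diam, soma_L = soma_L,
               soma_diam = soma_diam, n_basal = n_basal,
               basal_length = basal_length, basal_diam = basal_diam,
               axon_length = axon_length, axon_diam = axon_diam, step = step)
  stopifnot(all(unlist(spec[c("trunk_length", "oblique_length", "soma_L",
                              "soma_diam", "basal_length", "axon_length",
                              "step")]) > 0),
            all(trunk_diam > 0))
  class(spec) <- c("morph_spec", "list")
  spec
}

.line_points <- function(from, dir, length, d_from, d_to, step) {
  n <- max(2L, ceiling(length / step) + 1L)
  s <- seq(0, length, length.out = n)
  dir <- dir / sqrt(sum(dir^2))
  pts <- cbind(from[1] + dir[1] * s, from[2] + dir[2] * s, from[3] + dir[3] * s,
               d_from + (d_to - d_from) * s / length)
  colnames(pts) <- c("x", "y", "z", "diam")
  pts
}

#' Generate a synthetic morphology
#'
#' Builds a soma plus tapered apical trunk (split into sections at oblique
#' attachment points), randomly placed obliques, basal dendrites, and an
#' axon. Oblique attachment positions and branch directions are drawn from
#' the seeded RNG; the trunk itself is deterministic. The result round-trips
#' through [write_swc()] / [load_swc()] losslessly.
#'
#' @param spec A [morphology_spec()].
#' @param seed Integer seed for oblique placement.
#' @return A `neuro_morphology`.
#' @export
make_morphology <- function(spec = morphology_spec(), seed = 1) {
  stopifnot(inherits(spec, "morph_spec"))
  set.seed(seed)
  soma_r <- spec$soma_diam / 2
  sections <- list()
  sid <- 0L
  add <- function(region, parent, pts) {
    sid <<- sid + 1L
    sections[[sid]] <<- list(id = sid, region = region, parent = parent,
                             points = pts)
    sid
  }
  # trunk arc so that the terminal path distance from the soma center equals
  # trunk_length (path distance starts at soma_L/2 at the soma surface)
  arc <- spec$trunk_length - soma_r
  stopifnot(arc > 0)
  # oblique attachment fractions along the trunk (sorted, interior)
  fr <- if (spec$n_oblique > 0) sort(runif(spec$n_oblique, 0.15, 0.7)) else numeric(0)
  cuts <- unique(c(0, fr, 1)) * arc
  trunk_d <- function(s) spec$trunk_diam[1] +
    (spec$trunk_diam[2] - spec$trunk_diam[1]) * s / arc
  prev <- 0L
  trunk_secs <- integer(0)
  for (i in seq_len(length(cuts) - 1)) {
    a <- cuts[i]; b <- cuts[i + 1]
    from <- c(0, soma_r + a, 0)
    pts <- .line_points(from, c(0, 1, 0), b - a, trunk_d(a), trunk_d(b),
                        spec$step)
    if (prev > 0L) {   # include branch point row shared with the parent end
      parent_pts <- sections[[prev]]$points
      pts <- rbind(parent_pts[nrow(parent_pts), , drop = FALSE], pts[-1, , drop = FALSE])
      pts[, 4] <- c(trunk_d(a), pts[-1, 4])
    }
    prev <- add("apical", prev, pts)
    trunk_secs <- c(trunk_secs, prev)
  }
  # obliques off the trunk section ends at the attachment fractions
  for (k in seq_along(fr)) {
    att_sec <- trunk_secs[k]
    att <- sections[[att_sec]]$points
    bp <- att[nrow(att), ]
    ang <- runif(1, 0, 2 * pi)
    dir <- c(cos(ang), 0.25, sin(ang))
    pts <- .line_points(bp[1:3], dir, spec$oblique_length,
                        spec$oblique_diam, spec$oblique_diam, spec$step)
    pts[1, 4] <- bp[4]   # branch point keeps trunk diameter
    add("apical", att_sec, pts)
  }
  for (k in seq_len(spec$n_basal)) {
    ang <- pi + (k - 0.5) * pi / (spec$n_basal + 1)
    dir <- c(sin(ang), cos(ang), 0)
    pts <- .line_points(c(0, -soma_r, 0), dir, spec$basal_length,
                        spec$basal_diam, spec$basal_diam, spec$step)
    add("basal", 0L, pts)
  }
  pts <- .line_points(c(0, -soma_r, 0), c(0, -1, 0), spec$axon_length,
                      spec$axon_diam, spec$axon_diam, spec$step)
  add("axon", 0L, pts)
  structure(list(soma = list(L = spec$soma_L, diam = spec$soma_diam,
                             center = c(0, 0, 0)),
                 sections = sections),
            class = "neuro_morphology")
}
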