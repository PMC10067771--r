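# Morphology input, distance-dependent passive properties, and d_lambda
# compartmentalization.
#
# A morphology is a list of unbranched sections. Each section holds a matrix
# of 3D points with per-point diameter; sections attached to the soma start
# at their first own point (the soma is collapsed to an equivalent-area
# cylinder), sections attached to another dendrite include the branch point
# as their first row.

.swc_region <- c(`1` = "soma", `2` = "axon", `3` = "basal", `4` = "apical")

#' Read an SWC morphology file
#'
#' Parses a standard 7-column SWC reconstruction ('#' comments allowed),
#' validates node parentage and radii, collapses the soma to a single
#' cylindrical section of equivalent membrane area, and splits the neurites
#' into unbranched sections tagged by region (soma, axon, basal, apical).
#'
#' @param path Path to an SWC file.
#' @return An object of class `neuro_morphology`: a list with `sections`
#'   (each: `id`, `region`, `parent` section id, 0 attaching to the soma,
#'   `points` matrix with columns x, y, z, diam in um) and `soma` geometry.
#' @export
load_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  raw <- lines[keep]
  lineno <- which(keep)
  if (length(raw) == 0) stop("SWC parse error: no data rows in ", path)
  fields <- strsplit(trimws(raw), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7)
  if (length(bad)) {
    stop("SWC parse error at line ", lineno[bad[1]], ": expected 7 columns")
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    r <- which(apply(m, 1, anyNA))[1]
    stop("SWC parse error at line ", lineno[r], ": non-numeric field")
  }
  id <- as.integer(m[, 1]); type <- as.integer(m[, 2])
  xyz <- m[, 3:5, drop = FALSE]; radius <- m[, 6]; par <- as.integer(m[, 7])
  if (any(radius <= 0)) {
    r <- which(radius <= 0)[1]
    stop("SWC parse error at line ", lineno[r], ": non-positive radius")
  }
  if (anyDuplicated(id)) stop("SWC parse error: duplicate node ids")
  seen <- logical(max(id))
  for (r in seq_along(id)) {
    if (par[r] != -1) {
      if (par[r] < 1 || par[r] > max(id) || !seen[par[r]]) {
        stop("SWC parse error at line ", lineno[r],
             ": parent id ", par[r], " not defined before use")
      }
    }
    seen[id[r]] <- TRUE
  }
  if (any(!type %in% c(1:4))) {
    r <- which(!type %in% 1:4)[1]
    stop("SWC parse error at line ", lineno[r], ": unsupported type code ",
         type[r])
  }
  idx <- match(seq_len(max(id)), id)           # node id -> row
  is_soma <- type == 1
  if (!any(is_soma)) stop("SWC parse error: no soma (type 1) node")

  # soma: equivalent-area cylinder with L = diam
  soma_rows <- which(is_soma)
  if (length(soma_rows) == 1) {
    area <- 4 * pi * radius[soma_rows]^2          # sphere
  } else {
    area <- 0
    for (r in soma_rows) {
      p <- par[r]
      if (p != -1 && is_soma[idx[p]]) {
        pr <- idx[p]
        h <- sqrt(sum((xyz[r, ] - xyz[pr, ])^2))
        dr <- radius[r] - radius[pr]
        area <- area + pi * (radius[r] + radius[pr]) * sqrt(h^2 + dr^2)
      }
    }
    if (area <= 0) area <- 4 * pi * max(radius[soma_rows])^2
  }
  soma_d <- sqrt(area / pi)
  soma_center <- colMeans(xyz[soma_rows, , drop = FALSE])

  nchild <- integer(nrow(m))
  for (r in seq_len(nrow(m))) {
    p <- par[r]
    if (p != -1) nchild[idx[p]] <- nchild[idx[p]] + 1L
  }
  # section starts: non-soma nodes whose parent is soma, absent, a branch
  # point, or of a different region
  starts <- which(!is_soma & vapply(seq_len(nrow(m)), function(r) {
    p <- par[r]
    if (p == -1) return(TRUE)
    pr <- idx[p]
    is_soma[pr] || nchild[pr] > 1 || type[pr] != type[r]
  }, TRUE))

  sections <- list()
  sec_of_node <- integer(nrow(m))   # section id holding each node as its tail
  sid <- 0L
  for (s in starts) {
    sid <- sid + 1L
    chain <- s
    r <- s
    while (nchild[r] == 1L) {
      child <- which(par == id[r] & !is_soma)
      if (length(child) != 1 || type[child] != type[r]) break
      chain <- c(chain, child)
      r <- child
    }
    p <- par[s]
    pr <- if (p == -1) NA_integer_ else idx[p]
    if (!is.na(pr) && !is_soma[pr]) {
      pts <- rbind(cbind(xyz[pr, , drop = FALSE], 2 * radius[pr]),
                   cbind(xyz[chain, , drop = FALSE], 2 * radius[chain]))
      parent_sec <- sec_of_node[pr]
    } else {
      pts <- cbind(xyz[chain, , drop = FALSE], 2 * radius[chain])
      parent_sec <- 0L
    }
    colnames(pts) <- c("x", "y", "z", "diam")
    sections[[sid]] <- list(id = sid, region = .swc_region[[as.character(type[s])]],
                            parent = parent_sec, points = pts)
    for (nd in chain) sec_of_node[nd] <- sid
  }
  # order parents before children
  ord <- order(vapply(sections, `[[`, 0L, "parent"))
  remap <- integer(length(sections)); remap[ord] <- seq_along(sections)
  sections <- sections[ord]
  for (i in seq_along(sections)) {
    sections[[i]]$id <- i
    if (sections[[i]]$parent > 0) sections[[i]]$parent <- remap[sections[[i]]$parent]
  }
  structure(list(soma = list(L = soma_d, diam = soma_d, center = soma_center),
                 sections = sections),
            class = "neuro_morphology")
}

#' Write a morphology as SWC
#'
#' Serializes a `neuro_morphology` to standard 7-column SWC. The soma is
#' written as a single node whose sphere area equals the equivalent-cylinder
#' area, so a write/read round trip is lossless.
#'
#' @param m A `neuro_morphology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "neuro_morphology"))
  rows <- list()
  nid <- 1L
  rows[[1]] <- c(1, 1, m$soma$center, m$soma$diam / 2, -1)
  type_of <- c(soma = 1, axon = 2, basal = 3, apical = 4)
  tail_node <- integer(length(m$sections))  # node id of each section's last point
  for (s in m$sections) {
    pts <- s$points
    first <- if (s$parent > 0) 2L else 1L   # branch point row belongs to parent
    parent_node <- if (s$parent > 0) tail_node[s$parent] else 1L
    for (r in first:nrow(pts)) {
      nid <- nid + 1L
      rows[[length(rows) + 1]] <- c(nid, type_of[[s$region]],
                                    pts[r, 1:3], pts[r, 4] / 2, parent_node)
      parent_node <- nid
    }
    tail_node[s$id] <- nid
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC written by hplast", con)
  writeLines(apply(tab, 1, function(r) {
    sprintf("%d %d %.8g %.8g %.8g %.8g %d", r[1], r[2], r[3], r[4], r[5], r[6], r[7])
  }), con)
  invisible(path)
}

#' Default passive membrane parameters
#'
#' Specific membrane capacitance, the somatic (max) and distal-trunk (min)
#' values of membrane and axial resistivity, and the sigmoid midpoints/slopes
#' of their somato-apical gradients.
#'
#' @param Ra_k Slope of the axial-resistivity gradient (um). The source model
#'   lists two values for this constant; 50 um (the value shared with the
#'   membrane-resistivity gradient) is the default, 14 um is selectable.
#' @return Named list: `Cm` (uF/cm2), `Rm_max`, `Rm_min` (kOhm cm2),
#'   `Ra_max`, `Ra_min` (Ohm cm), `Rm_d`, `Rm_k`, `Ra_d`, `Ra_k` (um).
#' @export
passive_params <- function(Ra_k = 50) {
  list(Cm = 1, Rm_max = 125, Rm_min = 85, Ra_max = 120, Ra_min = 70,
       Rm_d = 300, Rm_k = 50, Ra_d = 300, Ra_k = Ra_k)
}

#' Distance-dependent passive resistivity
#'
#' Sigmoidal somato-apical gradient of membrane resistivity Rm (kOhm cm2) or
#' axial resistivity Ra (Ohm cm):
#' `R(x) = R_max + (R_min - R_max)/(1 + exp((d - x)/k))`.
#' Basal and axonal compartments take the somatic value, i.e. `x = 0`.
#'
#' @param x Path distance from the soma center (um), `>= 0`, vectorized.
#' @param params Passive parameters from [passive_params()].
#' @param which `"Rm"` or `"Ra"`.
#' @return Resistivity at `x`.
#' @export
assign_passive <- function(x, params = passive_params(), which = c("Rm", "Ra")) {
  which <- match.arg(which)
  stopifnot(all(x >= 0))
  p <- params
  if (which == "Rm") {
    p$Rm_max + (p$Rm_min - p$Rm_max) / (1 + exp((p$Rm_d - x) / p$Rm_k))
  } else {
    p$Ra_max + (p$Ra_min - p$Ra_max) / (1 + exp((p$Ra_d - x) / p$Ra_k))
  }
}

# AC length constant at frequency f (Hz), in um; d um, Ra Ohm cm, Cm uF/cm2
.lambda_f <- function(d, f, Ra, Cm) 1e5 * sqrt(d / (4 * pi * f * Ra * Cm))

# frustum areas (um2) and arc lengths (um) between consecutive points
.frusta <- function(pts) {
  n <- nrow(pts)
  if (n < 2) stop("section with fewer than 2 points")
  h <- sqrt(rowSums((pts[-1, 1:3, drop = FALSE] - pts[-n, 1:3, drop = FALSE])^2))
  r1 <- pts[-n, 4] / 2; r2 <- pts[-1, 4] / 2
  list(len = h, area = pi * (r1 + r2) * sqrt(h^2 + (r1 - r2)^2),
       d1 = pts[-n, 4], d2 = pts[-1, 4])
}

#' Discretize a morphology into compartments (d_lambda rule)
#'
#' Splits every section into the smallest odd number of equal-length
#' compartments such that each is shorter than `d_lambda` times the AC length
#' constant at `f` Hz, computed from local diameter and the
#' distance-dependent Rm/Ra (two passes: section midpoints set the
#' compartment count, then final per-compartment values are assigned at
#' compartment midpoints). Path distance x is measured along the neurites
#' from the soma center (x = 0).
#'
#' @param m A `neuro_morphology`.
#' @param p Passive parameters, see [passive_params()].
#' @param d_lambda Fraction of the AC length constant, in (0, 1].
#' @param f Reference frequency (Hz).
#' @return Object of class `compartment_tree`: a list with `comps` (one row
#'   per compartment: id, section, region, x um, L um, diam um, area cm2,
#'   Rm kOhm cm2, Ra Ohm cm, Cm uF/cm2, parent compartment id) and the input
#'   morphology and parameters.
#' @export
compartmentalize <- function(m, p = passive_params(), d_lambda = 0.1, f = 100) {
  stopifnot(inherits(m, "neuro_morphology"),
            d_lambda > 0, d_lambda <= 1, f > 0)
  rows <- list()
  # soma: one compartment, x = 0 at its center
  soma <- data.frame(id = 1L, section = 0L, region = "soma", x = 0,
                     L = m$soma$L, diam = m$soma$diam,
                     area = pi * m$soma$diam * m$soma$L * 1e-8,
                     Rm = assign_passive(0, p, "Rm"),
                     Ra = assign_passive(0, p, "Ra"),
                     Cm = p$Cm, parent = 0L)
  rows[[1]] <- soma
  sec_end_comp <- integer(length(m$sections))
  sec_end_x <- numeric(length(m$sections))
  next_id <- 2L
  for (s in m$sections) {
    fr <- .frusta(s$points)
    L <- sum(fr$len)
    if (L <= 0) stop("zero-length section ", s$id)
    x0 <- if (s$parent > 0) sec_end_x[s$parent] else m$soma$L / 2
    apical_like <- s$region %in% c("soma", "apical")
    # pass 1: coarse midpoint distance sets the compartment count
    xm <- if (apical_like) x0 + L / 2 else 0
    dbar <- sum((fr$d1 + fr$d2) / 2 * fr$len) / L
    lam <- .lambda_f(dbar, f, assign_passive(xm, p, "Ra"), p$Cm)
    ratio <- L / (d_lambda * lam)
    nseg <- max(1L, as.integer(2 * ceiling((ratio - 1) / 2 - 1e-9) + 1))
    if (nseg %% 2L == 0L) nseg <- nseg + 1L
    # pass 2: per-compartment geometry and passive values
    cum <- c(0, cumsum(fr$len))
    bounds <- seq(0, L, length.out = nseg + 1)
    parent_comp <- if (s$parent > 0) sec_end_comp[s$parent] else 1L
    for (k in seq_len(nseg)) {
      a <- bounds[k]; b <- bounds[k + 1]
      # integrate frusta over [a, b]
      area_um2 <- 0; dint <- 0
      for (j in seq_along(fr$len)) {
        lo <- max(a, cum[j]); hi <- min(b, cum[j + 1])
        if (hi <= lo) next
        t1 <- (lo - cum[j]) / fr$len[j]; t2 <- (hi - cum[j]) / fr$len[j]
        dA <- fr$d1[j] + (fr$d2[j] - fr$d1[j]) * t1
        dB <- fr$d1[j] + (fr$d2[j] - fr$d1[j]) * t2
        h <- hi - lo
        area_um2 <- area_um2 + pi * (dA + dB) / 2 * sqrt(h^2 + ((dB - dA) / 2)^2)
        dint <- dint + (dA + dB) / 2 * h
      }
      xk <- x0 + (a + b) / 2
      xeff <- if (apical_like) xk else 0
      rows[[length(rows) + 1]] <- data.frame(
        id = next_id, section = s$id, region = s$region, x = xk,
        L = b - a, diam = dint / (b - a), area = area_um2 * 1e-8,
        Rm = assign_passive(xeff, p, "Rm"),
        Ra = assign_passive(xeff, p, "Ra"),
        Cm = p$Cm, parent = parent_comp)
      parent_comp <- next_id
      next_id <- next_id + 1L
    }
    sec_end_comp[s$id] <- next_id - 1L
    sec_end_x[s$id] <- x0 + L
  }
  comps <- do.call(rbind, rows)
  rownames(comps) <- NULL
  structure(list(comps = comps, morphology = m, passive = p,
                 d_lambda = d_lambda, f = f),
            class = "compartment_tree")
}

#' @export
print.compartment_tree <- function(x, ...) {
  cat("compartment tree:", nrow(x$comps), "compartments,",
      length(x$morphology$sections), "sections\n")
  tb <- table(x$comps$region)
  cat(paste(names(tb), tb, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.neuro_morphology <- function(x, ...) {
  cat("morphology:", length(x$sections), "sections; soma",
      sprintf("%.1f x %.1f um\n", x$soma$L, x$soma$diam))
  invisible(x)
}

#' Write the compartment table as CSV
#'
#' @param tree A `compartment_tree`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compartments <- function(tree, path) {
  stopifnot(inherits(tree, "compartment_tree"))
  write.csv(tree$comps, path, row.names = FALSE)
  invisible(path)
}
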