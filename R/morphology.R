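# Morphologies: a tree of tapered cylindrical sections, a synthetic
# somato-apical trunk generator, and standard 7-column SWC read/write.

#' Construct a morphology from a section table
#'
#' @param sections data.frame with columns `section` (integer id), `parent`
#'   (parent section id, 0 for the root soma), `type` (`soma`, `apical`,
#'   `basal`, `axon`), `length_um`, `diam0` (proximal diameter, um), `diam1`
#'   (distal diameter, um). Sections must be ordered root-first
#'   (`parent < section`).
#' @param id morphology label.
#' @return object of class `neuron_morphology`.
#' @export
morphology <- function(sections, id = "morphology") {
  need <- c("section", "parent", "type", "length_um", "diam0", "diam1")
  stopifnot(all(need %in% names(sections)))
  sections <- sections[order(sections$section), need, drop = FALSE]
  m <- structure(list(sections = sections, id = id),
                 class = "neuron_morphology")
  validate_morphology(m)
  m
}

#' Validate a morphology
#'
#' Checks: exactly one root and it is the soma; the parent links form a
#' connected acyclic tree ordered root-first; all lengths and diameters are
#' strictly positive.
#'
#' @param morph a `neuron_morphology`.
#' @return the morphology, invisibly; errors otherwise.
#' @export
validate_morphology <- function(morph) {
  s <- morph$sections
  roots <- which(s$parent == 0)
  if (length(roots) != 1) stop("morphology must have exactly one root",
                               call. = FALSE)
  if (s$type[roots] != "soma") stop("the root section must be the soma",
                                    call. = FALSE)
  if (any(s$parent >= s$section)) {
    stop("sections must be ordered root-first (parent id < section id)",
         call. = FALSE)
  }
  if (!all(s$parent %in% c(0, s$section))) {
    stop("disconnected morphology: a parent id is missing", call. = FALSE)
  }
  if (any(s$length_um <= 0)) stop("all section lengths must be > 0",
                                  call. = FALSE)
  if (any(s$diam0 <= 0) || any(s$diam1 <= 0)) {
    stop("all diameters must be > 0", call. = FALSE)
  }
  invisible(morph)
}

#' Path distance of each section's proximal end from the soma surface
#'
#' Distance is measured along the tree from the soma/dendrite junction; soma
#' sections sit at distance 0.
#'
#' @param morph a `neuron_morphology`.
#' @return numeric vector, one entry per section (um).
#' @export
section_path_start <- function(morph) {
  s <- morph$sections
  x0 <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    p <- s$parent[i]
    if (p == 0 || s$type[match(p, s$section)] == "soma") {
      x0[i] <- 0
    } else {
      pi_ <- match(p, s$section)
      x0[i] <- x0[pi_] + s$length_um[pi_]
    }
  }
  x0
}

#' Synthetic somato-apical trunk morphology
#'
#' Generates, without any external reconstruction, a soma plus linearly
#' tapered apical trunk emulating the somato-apical trunk of a CA1 pyramidal
#' cell (terminal end ~425 um from the soma). Optional basal equivalent
#' cylinder and axon stub; optional log-normal diameter jitter (off by
#' default; when on, monotone non-increasing taper is enforced).
#'
#' @param trunk_length_um total apical trunk path length (um).
#' @param soma_length_um,soma_diam_um soma cylinder dimensions (um).
#' @param diam_prox_um,diam_dist_um trunk diameters at its proximal and distal
#'   ends (um).
#' @param n_sections number of trunk sections.
#' @param basal optional `list(length_um=, diam_um=)` equivalent cylinder.
#' @param axon optional `list(length_um=, diam_um=)` stub.
#' @param jitter_sd sd of log-normal diameter jitter (0 = off).
#' @param seed RNG seed used only when `jitter_sd > 0`.
#' @return a `neuron_morphology`.
#' @export
make_trunk <- function(trunk_length_um = 425, soma_length_um = 20,
                       soma_diam_um = 20, diam_prox_um = 2.5,
                       diam_dist_um = 1.0, n_sections = 10,
                       basal = NULL, axon = NULL,
                       jitter_sd = 0, seed = 1L) {
  if (trunk_length_um <= 0 || n_sections < 1 || diam_prox_um <= 0 ||
      diam_dist_um <= 0 || diam_dist_um > diam_prox_um ||
      soma_length_um <= 0 || soma_diam_um <= 0) {
    stop("non-physical synthetic trunk specification", call. = FALSE)
  }
  n <- as.integer(n_sections)
  bounds <- seq(0, trunk_length_um, length.out = n + 1)
  diam_at <- function(x) {
    diam_prox_um + (diam_dist_um - diam_prox_um) * x / trunk_length_um
  }
  d0 <- diam_at(bounds[-(n + 1)])
  d1 <- diam_at(bounds[-1])
  if (jitter_sd > 0) {
    rs <- .Random.seed_save()
    on.exit(.Random.seed_restore(rs), add = TRUE)
    set.seed(seed)
    fac <- exp(stats::rnorm(n + 1, 0, jitter_sd))
    dd <- cummin(c(diam_prox_um, diam_at(bounds[-1]) * fac[-1]))
    d0 <- dd[-(n + 1)]
    d1 <- dd[-1]
  }
  sec <- data.frame(
    section = seq_len(n + 1),
    parent = c(0L, seq_len(n)),
    type = c("soma", rep("apical", n)),
    length_um = c(soma_length_um, diff(bounds)),
    diam0 = c(soma_diam_um, d0),
    diam1 = c(soma_diam_um, d1),
    stringsAsFactors = FALSE
  )
  nxt <- n + 2L
  if (!is.null(basal)) {
    sec <- rbind(sec, data.frame(section = nxt, parent = 1L, type = "basal",
                                 length_um = basal$length_um,
                                 diam0 = basal$diam_um, diam1 = basal$diam_um))
    nxt <- nxt + 1L
  }
  if (!is.null(axon)) {
    sec <- rbind(sec, data.frame(section = nxt, parent = 1L, type = "axon",
                                 length_um = axon$length_um,
                                 diam0 = axon$diam_um, diam1 = axon$diam_um))
  }
  morphology(sec, id = "synthetic-trunk")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(rs) {
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
}

swc_type_code <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L)

#' Write a morphology to SWC
#'
#' Standard 7-column SWC (index, type, x, y, z, radius, parent). The soma is
#' written as a single spherical sample of equal surface area; each section is
#' sampled at most every 10 um with linearly interpolated radii. Geometry is
#' synthesized (sections run along fixed axes per type) since the internal
#' representation stores only lengths and diameters.
#'
#' @param morph a `neuron_morphology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  s <- morph$sections
  axis_of <- c(soma = c(0, 1, 0), apical = c(0, 1, 0),
               basal = c(0, -1, 0), axon = c(1, 0, 0))
  rows <- list()
  idx <- 0L
  # soma: sphere of equal surface area: pi*D*L = 4*pi*r^2
  i_soma <- which(s$parent == 0)
  r_soma <- sqrt(s$diam0[i_soma] * s$length_um[i_soma] / 4)
  idx <- idx + 1L
  rows[[idx]] <- c(idx, 1L, 0, 0, 0, r_soma, -1L)
  sec_end_sample <- integer(nrow(s))
  sec_end_xyz <- vector("list", nrow(s))
  sec_end_sample[i_soma] <- 1L
  sec_end_xyz[[i_soma]] <- c(0, 0, 0)
  for (i in seq_len(nrow(s))[-i_soma]) {
    p <- match(s$parent[i], s$section)
    ax <- switch(s$type[i], apical = c(0, 1, 0), basal = c(0, -1, 0),
                 axon = c(1, 0, 0), c(0, 1, 0))
    start <- sec_end_xyz[[p]]
    nseg <- max(1L, ceiling(s$length_um[i] / 10))
    frac <- seq_len(nseg) / nseg
    parent_sample <- sec_end_sample[p]
    if (s$type[match(s$parent[i], s$section)] == "soma") {
      # explicit proximal end point so the first segment's length is encoded
      idx <- idx + 1L
      rows[[idx]] <- c(idx, swc_type_code[[s$type[i]]], start,
                       s$diam0[i] / 2, parent_sample)
      parent_sample <- idx
    }
    for (k in seq_len(nseg)) {
      xyz <- start + ax * s$length_um[i] * frac[k]
      rad <- (s$diam0[i] + (s$diam1[i] - s$diam0[i]) * frac[k]) / 2
      idx <- idx + 1L
      rows[[idx]] <- c(idx, swc_type_code[[s$type[i]]], xyz, rad,
                       parent_sample)
      parent_sample <- idx
    }
    sec_end_sample[i] <- idx
    sec_end_xyz[[i]] <- start + ax * s$length_um[i]
  }
  m <- do.call(rbind, rows)
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                   m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6], m[, 7])
  writeLines(c("# SWC generated by calres", lines), path)
  invisible(path)
}

#' Read a morphology from SWC
#'
#' Standard 7-column SWC; type codes 1 = soma, 2 = axon, 3 = basal dendrite,
#' 4 = apical dendrite. Soma samples are collapsed to a single cylinder of
#' equivalent surface area (length = diameter). Each maximal unbranched
#' chain of same-type samples becomes one tapered section.
#'
#' @param path SWC file.
#' @param id morphology label; default the file name.
#' @return a `neuron_morphology`.
#' @export
read_swc <- function(path, id = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) != 7) stop("SWC must have 7 columns", call. = FALSE)
  colnames(m) <- c("id", "type", "x", "y", "z", "r", "parent")
  ids <- m[, "id"]
  row_of <- function(i) match(i, ids)
  type_name <- c("soma", "axon", "basal", "apical")
  # soma equivalent cylinder
  soma_rows <- which(m[, "type"] == 1)
  if (length(soma_rows) == 0) stop("SWC has no soma samples", call. = FALSE)
  if (length(soma_rows) == 1) {
    area <- 4 * pi * m[soma_rows, "r"]^2
  } else {
    area <- 0
    for (i in soma_rows) {
      p <- m[i, "parent"]
      pr <- row_of(p)
      if (!is.na(pr) && m[pr, "type"] == 1) {
        dl <- sqrt(sum((m[i, c("x", "y", "z")] - m[pr, c("x", "y", "z")])^2))
        area <- area + pi * (m[i, "r"] + m[pr, "r"]) * dl
      }
    }
    if (area == 0) area <- 4 * pi * max(m[soma_rows, "r"])^2
  }
  soma_ld <- sqrt(area / pi)
  children <- split(seq_len(nrow(m)), factor(m[, "parent"], levels = ids))
  nchild <- vapply(children, length, 1L)[as.character(ids)]
  nchild[is.na(nchild)] <- 0L
  is_soma <- m[, "type"] == 1
  sections <- list(data.frame(section = 1L, parent = 0L, type = "soma",
                              length_um = soma_ld, diam0 = soma_ld,
                              diam1 = soma_ld))
  sec_id <- 1L
  sec_of_sample <- integer(nrow(m))
  sec_of_sample[soma_rows] <- 1L
  # section start rows: non-soma samples whose parent is soma, a branch point,
  # or of a different type
  starts <- which(!is_soma & {
    pr <- row_of(m[, "parent"])
    is.na(pr) | is_soma[pr] | nchild[pr] > 1 | m[pr, "type"] != m[, "type"]
  })
  # order starts so parents are processed first
  depth <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    pr <- row_of(m[i, "parent"])
    depth[i] <- if (is.na(pr)) 0L else depth[pr] + 1L
  }
  for (st in starts[order(depth[starts])]) {
    pr <- row_of(m[st, "parent"])
    chain <- st
    cur <- st
    repeat {
      kids <- children[[as.character(ids[cur])]]
      kids <- kids[!is_soma[kids] & m[kids, "type"] == m[cur, "type"]]
      if (length(kids) != 1 || nchild[cur] > 1) break
      cur <- kids
      chain <- c(chain, cur)
    }
    pts <- m[chain, c("x", "y", "z"), drop = FALSE]
    rads <- m[chain, "r"]
    if (!is.na(pr) && !is_soma[pr]) {
      pts <- rbind(m[pr, c("x", "y", "z")], pts)
      rads <- c(m[pr, "r"], rads)
    }
    len <- if (nrow(pts) > 1) {
      sum(sqrt(rowSums(diff(pts)^2)))
    } else 0
    if (len <= 0) next
    sec_id <- sec_id + 1L
    parent_sec <- if (is.na(pr) || is_soma[pr]) 1L else sec_of_sample[pr]
    sections[[sec_id]] <- data.frame(
      section = sec_id, parent = parent_sec,
      type = type_name[m[st, "type"]],
      length_um = len, diam0 = 2 * rads[1], diam1 = 2 * rads[length(rads)])
    sec_of_sample[chain] <- sec_id
  }
  morphology(do.call(rbind, sections), id = id)
}
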