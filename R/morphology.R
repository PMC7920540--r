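#' Neuron morphologies as section tables
#'
#' A morphology is a tibble of cylindrical *sections* (one row per unbranched
#' cable piece) with class `"morphology"`.  Columns:
#'
#' * `id` — integer section id (soma is always id 1),
#' * `region` — `"soma"`, `"ais"` or `"dend"`,
#' * `parent_id` — id of the parent section (`NA` for the soma),
#' * `length_um`, `diam_um` — cylinder dimensions in micrometres,
#' * `branch_order` — 0 for soma/AIS, dendrites counted from the soma,
#' * `path_dist_um` — path distance from the soma surface to the section
#'   midpoint.
#'
#' The soma is modelled as a single compartment of fixed surface area
#' (default 293 um^2); its `length_um`/`diam_um` are the equivalent cylinder
#' with d = L.
#'
#' @param sections tibble of sections as described above.
#' @param soma_area_um2 soma surface area (um^2).
#' @param provenance `"swc"` or `"surrogate"`.
#' @return A `morphology` object (tibble subclass).
#' @export
morphology <- function(sections, soma_area_um2 = 293, provenance = "surrogate") {
  m <- tibble::as_tibble(sections)
  attr(m, "soma_area_um2") <- soma_area_um2
  attr(m, "provenance") <- provenance
  class(m) <- c("morphology", class(tibble::tibble()))
  validate_morphology(m)
  m
}

soma_equiv_dims <- function(area_um2) sqrt(area_um2 / pi)  # d = L cylinder

validate_morphology <- function(m) {
  stopifnot(all(c("id", "region", "parent_id", "length_um", "diam_um",
                  "branch_order", "path_dist_um") %in% names(m)))
  if (sum(m$region == "soma") != 1L)
    stop("morphology must contain exactly one soma section", call. = FALSE)
  non_soma <- m[m$region != "soma", ]
  if (nrow(non_soma) && any(non_soma$length_um <= 0 | non_soma$diam_um <= 0))
    stop("non-soma sections must have positive length and diameter", call. = FALSE)
  if (any(m$id == m$parent_id, na.rm = TRUE))
    stop("section cannot be its own parent", call. = FALSE)
  root <- m$id[is.na(m$parent_id)]
  if (length(root) != 1L || m$region[m$id == root] != "soma")
    stop("parent graph must be a tree rooted at the soma", call. = FALSE)
  # reachability from root guarantees no cycles
  children <- split(m$id, factor(m$parent_id, levels = m$id))
  seen <- logical(nrow(m)); names(seen) <- as.character(m$id)
  stack <- root
  while (length(stack)) {
    s <- stack[[1]]; stack <- stack[-1]
    seen[as.character(s)] <- TRUE
    stack <- c(stack, children[[as.character(s)]])
  }
  if (!all(seen))
    stop("morphology contains sections unreachable from the soma (cycle or orphan)",
         call. = FALSE)
  ord <- m$branch_order
  po <- ord[match(m$parent_id, m$id)]
  if (any(ord < po, na.rm = TRUE))
    stop("branch_order of a child must be >= its parent's", call. = FALSE)
  invisible(m)
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology: %d sections, soma %.0f um^2, provenance %s>\n",
              nrow(x), attr(x, "soma_area_um2"), attr(x, "provenance")))
  NextMethod()
}

#' Total membrane surface area of a morphology
#'
#' @param m a [morphology()].
#' @param regions optional character vector restricting to some regions.
#' @return Area in um^2 (soma counted at its fixed surface area).
#' @export
total_area <- function(m, regions = c("soma", "ais", "dend")) {
  a <- ifelse(m$region == "soma", attr(m, "soma_area_um2"),
              pi * m$diam_um * m$length_um)
  sum(a[m$region %in% regions])
}

#' Configuration for the parametric surrogate morphology
#'
#' The surrogate stands in for a full reconstruction: `n_stems` primary
#' dendrites leave the soma, each branching symmetrically (binary) up to
#' `max_branch_order`, with diameters assigned top-down by the Rall
#' branch-point rule (see [apply_rall_diameters()]).  The axon initial
#' segment is a 70 um x 1.5 um chain on the soma.  With `length_jitter_cv
#' = 0` (the default) the tree is fully deterministic; a positive value adds
#' seeded log-normal jitter to section lengths.
#'
#' @param n_stems number of primary dendrites.
#' @param max_branch_order deepest dendritic branch order.
#' @param section_length_mean dendritic section length (um).
#' @param stem_diameter primary dendrite diameter (um); the default is the
#'   value found by [calibrate_passive()] for the default model.
#' @param rall_exponent exponent of the branch-point rule (3/2).
#' @param ais_length_um,ais_diam_um axon initial segment geometry.
#' @param soma_area_um2 soma surface area.
#' @param length_jitter_cv coefficient of variation of seeded length jitter.
#' @param seed integer seed used only when `length_jitter_cv > 0`.
#' @return A `surrogate_config` list.
#' @export
surrogate_config <- function(n_stems = 5L, max_branch_order = 3L,
                             section_length_mean = 40, stem_diameter = 3.05,
                             rall_exponent = 1.5,
                             ais_length_um = 70, ais_diam_um = 1.5,
                             soma_area_um2 = 293,
                             length_jitter_cv = 0, seed = 1L) {
  stopifnot(n_stems >= 1, max_branch_order >= 0, section_length_mean > 0,
            stem_diameter > 0, rall_exponent > 0)
  structure(list(n_stems = as.integer(n_stems),
                 max_branch_order = as.integer(max_branch_order),
                 section_length_mean = section_length_mean,
                 stem_diameter = stem_diameter,
                 rall_exponent = rall_exponent,
                 ais_length_um = ais_length_um, ais_diam_um = ais_diam_um,
                 soma_area_um2 = soma_area_um2,
                 length_jitter_cv = length_jitter_cv,
                 seed = as.integer(seed)),
            class = "surrogate_config")
}

#' Serialize / restore a surrogate configuration as JSON
#'
#' @param config a [surrogate_config()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
surrogate_config_json <- function(config, path = NULL) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); invisible(js) } else js
}

#' @rdname surrogate_config_json
#' @param json JSON string or file path produced by [surrogate_config_json()].
#' @export
surrogate_config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(surrogate_config, x)
}

#' Build the parametric surrogate morphology
#'
#' @param config a [surrogate_config()].
#' @return A [morphology()] with provenance `"surrogate"`.
#' @export
build_surrogate <- function(config = surrogate_config()) {
  cfg <- config
  dsoma <- soma_equiv_dims(cfg$soma_area_um2)
  rows <- list(tibble::tibble(id = 1L, region = "soma", parent_id = NA_integer_,
                              length_um = dsoma, diam_um = dsoma,
                              branch_order = 0L, path_dist_um = 0))
  nid <- 2L
  # AIS chain (single section; discretization subdivides it)
  rows[[2]] <- tibble::tibble(id = nid, region = "ais", parent_id = 1L,
                              length_um = cfg$ais_length_um,
                              diam_um = cfg$ais_diam_um,
                              branch_order = 0L,
                              path_dist_um = cfg$ais_length_um / 2)
  nid <- nid + 1L
  jitter <- function(n) {
    if (cfg$length_jitter_cv <= 0) return(rep(1, n))
    sdl <- sqrt(log(1 + cfg$length_jitter_cv^2))
    exp(stats::rnorm(n, -sdl^2 / 2, sdl))
  }
  if (cfg$length_jitter_cv > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(cfg$seed)
  }
  # breadth-first growth of the dendritic tree
  frontier <- data.frame(parent = integer(), path0 = numeric())
  for (s in seq_len(cfg$n_stems)) {
    L <- cfg$section_length_mean * jitter(1)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = nid, region = "dend", parent_id = 1L, length_um = L,
      diam_um = cfg$stem_diameter, branch_order = 1L, path_dist_um = L / 2)
    frontier <- rbind(frontier, data.frame(parent = nid, path0 = L))
    nid <- nid + 1L
  }
  if (cfg$max_branch_order >= 2) {
    for (ord in 2:cfg$max_branch_order) {
      nxt <- data.frame(parent = integer(), path0 = numeric())
      for (k in seq_len(nrow(frontier))) {
        for (b in 1:2) {
          L <- cfg$section_length_mean * jitter(1)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            id = nid, region = "dend", parent_id = frontier$parent[k],
            length_um = L, diam_um = cfg$stem_diameter,  # placeholder
            branch_order = ord, path_dist_um = frontier$path0[k] + L / 2)
          nxt <- rbind(nxt, data.frame(parent = nid,
                                       path0 = frontier$path0[k] + L))
          nid <- nid + 1L
        }
      }
      frontier <- nxt
    }
  }
  m <- morphology(dplyr::bind_rows(rows), soma_area_um2 = cfg$soma_area_um2,
                  provenance = "surrogate")
  apply_rall_diameters(m, stem_diameter = cfg$stem_diameter,
                       exponent = cfg$rall_exponent)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Assign dendritic diameters by the Rall branch-point rule
#'
#' Diameters are propagated top-down from the primary dendrites: at every
#' branch point the children satisfy `d_parent^e = sum(d_child^e)` with
#' `e = 3/2`, siblings receiving equal diameters; an unbranched continuation
#' keeps its parent's diameter.  The inverse relation uses exponent 2/3,
#' whence the rule's common name.
#'
#' @param m a [morphology()].
#' @param stem_diameter diameter given to every first-order dendrite (um).
#' @param exponent branch-point exponent (default 3/2).
#' @param min_diam taper clamp (um); children never go below this.
#' @return The morphology with updated dendritic diameters.
#' @export
apply_rall_diameters <- function(m, stem_diameter, exponent = 1.5,
                                 min_diam = 0.3) {
  stopifnot(stem_diameter > 0)
  d <- m$diam_um
  ids <- m$id
  children_of <- split(seq_len(nrow(m)), factor(m$parent_id, levels = ids))
  soma_row <- which(m$region == "soma")
  # breadth-first from the soma through dendrites
  queue <- children_of[[as.character(ids[soma_row])]]
  while (length(queue)) {
    i <- queue[[1]]; queue <- queue[-1]
    if (m$region[i] == "dend") {
      if (identical(m$parent_id[i], ids[soma_row])) {
        d[i] <- stem_diameter
      } else {
        p <- match(m$parent_id[i], ids)
        sibs <- children_of[[as.character(ids[p])]]
        sibs <- sibs[m$region[sibs] == "dend"]
        if (length(sibs) == 1L) {
          d[i] <- d[p]                       # unbranched continuation
        } else {
          d[i] <- max((d[p]^exponent / length(sibs))^(1 / exponent), min_diam)
        }
      }
    }
    queue <- c(queue, children_of[[as.character(ids[i])]])
  }
  m$diam_um <- d
  m
}

#' Classification scheme for the channel-density regions
#'
#' The density table distinguishes the AIS, the soma and three dendritic
#' classes.  The default scheme assigns dendrites by branch order with a
#' path-distance override: first-order sections are "proximal"
#' (`dend_class_2`), higher orders are `dend_class_3`, and any section whose
#' midpoint lies beyond `distal_path_cutoff` is "distal" (`dend_class_1`).
#' The mapping is a plain config object so alternative readings of the
#' region layout can be swapped in.
#'
#' @param distal_path_cutoff path distance (um) beyond which a dendrite is
#'   classed distal.
#' @export
region_scheme <- function(distal_path_cutoff = 150) {
  structure(list(distal_path_cutoff = distal_path_cutoff),
            class = "region_scheme")
}

#' Map every section to a channel-density region label
#'
#' @param m a [morphology()].
#' @param scheme a [region_scheme()].
#' @return Tibble with columns `id`, `label` (one of `ais`, `soma`,
#'   `dend_class_1`, `dend_class_2`, `dend_class_3`).
#' @export
classify_regions <- function(m, scheme = region_scheme()) {
  lab <- character(nrow(m))
  lab[m$region == "soma"] <- "soma"
  lab[m$region == "ais"] <- "ais"
  dd <- m$region == "dend"
  lab[dd & m$branch_order == 1L] <- "dend_class_2"
  lab[dd & m$branch_order >= 2L] <- "dend_class_3"
  lab[dd & m$path_dist_um > scheme$distal_path_cutoff] <- "dend_class_1"
  tibble::tibble(id = m$id, label = lab)
}

#' Discretize a morphology into iso-potential compartments
#'
#' Each section is split into `ceiling(length / max_seg_length)` equal
#' compartments (the soma always stays one compartment of its fixed area).
#' Axial coupling between adjacent compartments is computed from the
#' cytoplasmic resistivity and the half-cylinder resistances
#' `R = 4 ri L / (pi d^2)` on either side of the shared face.
#'
#' @param m a [morphology()].
#' @param max_seg_length maximal compartment length (um).
#' @param ri cytoplasmic (axial) resistivity, ohm cm.
#' @param scheme region scheme passed to [classify_regions()].
#' @return Tibble of compartments: `comp`, `section_id`, `region`, `label`,
#'   `length_um`, `diam_um`, `area_um2`, `parent` (compartment index, 0 for
#'   the root), `g_axial_uS` (coupling to the parent compartment) and
#'   `path_dist_um`.
#' @export
discretize <- function(m, max_seg_length = 20, ri = 60,
                       scheme = region_scheme()) {
  stopifnot(max_seg_length > 0, ri > 0)
  labels <- classify_regions(m, scheme)
  ids <- m$id
  # order sections parent-before-child
  ord <- order(is.na(m$parent_id), decreasing = TRUE)
  pending <- seq_len(nrow(m))[-which(is.na(m$parent_id))]
  done <- which(is.na(m$parent_id))
  while (length(pending)) {
    ready <- pending[match(m$parent_id[pending], ids) %in% done]
    done <- c(done, ready)
    pending <- setdiff(pending, ready)
  }
  sec_order <- done

  comp <- list()
  half_r <- function(L_um, d_um) 4 * ri * (L_um * 1e-4) / (pi * (d_um * 1e-4)^2) / 2 # ohm
  # per-section: first/last compartment index and end half-resistance
  first_comp <- last_comp <- integer(nrow(m))
  end_half <- numeric(nrow(m))
  ncomp <- 0L
  for (i in sec_order) {
    if (m$region[i] == "soma") {
      n <- 1L
      L <- m$length_um[i]; d <- m$diam_um[i]
      area <- attr(m, "soma_area_um2")
    } else {
      n <- as.integer(ceiling(m$length_um[i] / max_seg_length))
      L <- m$length_um[i] / n; d <- m$diam_um[i]
      area <- pi * d * L
    }
    p_sec <- match(m$parent_id[i], ids)
    path0 <- m$path_dist_um[i] - m$length_um[i] / 2
    for (k in seq_len(n)) {
      ncomp <- ncomp + 1L
      if (k == 1L) {
        first_comp[i] <- ncomp
        if (is.na(m$parent_id[i])) {
          parent <- 0L; gax <- 0
        } else {
          parent <- last_comp[p_sec]
          r <- half_r(L, d) + end_half[p_sec]
          gax <- 1e6 / r     # uS
        }
      } else {
        parent <- ncomp - 1L
        gax <- 1e6 / (2 * half_r(L, d))
      }
      comp[[ncomp]] <- tibble::tibble(
        comp = ncomp, section_id = ids[i], region = m$region[i],
        label = labels$label[i], length_um = L, diam_um = d,
        area_um2 = area, parent = parent, g_axial_uS = gax,
        path_dist_um = if (m$region[i] == "soma") 0 else path0 + (k - 0.5) * L)
    }
    last_comp[i] <- ncomp
    end_half[i] <- half_r(L, d)
  }
  out <- dplyr::bind_rows(comp)
  attr(out, "ri_ohm_cm") <- ri
  attr(out, "max_seg_length") <- max_seg_length
  out
}

#' Read an SWC reconstruction
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent; 1-based parent
#' indexing, `-1` for the root).  Type codes 1 = soma, 2 = axon, 3/4 =
#' dendrite.  Per-point segments are merged into unbranched sections, the
#' axon is truncated to its initial 70 um of path length and relabelled
#' `ais`, and the soma is replaced by a single compartment of fixed surface
#' area (default 293 um^2).
#'
#' @param path file path to an SWC file.
#' @param ais_keep_um length of axon retained as the initial segment (um).
#' @param soma_area_um2 standardized soma surface area (um^2).
#' @return A [morphology()] with provenance `"swc"`.
#' @export
load_swc <- function(path, ais_keep_um = 70, soma_area_um2 = 293) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  raw <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(trimws(raw), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad))
    stop(sprintf("malformed SWC row at line %d: expected 7 columns", lineno[bad[1]]),
         call. = FALSE)
  df <- as.data.frame(do.call(rbind, lapply(fields, as.numeric)))
  names(df) <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (anyNA(df))
    stop(sprintf("malformed SWC row at line %d: non-numeric field",
                 lineno[which(rowSums(is.na(df)) > 0)[1]]), call. = FALSE)
  if (any(df$id == df$parent))
    stop("SWC structural error: point is its own parent", call. = FALSE)

  soma_pts <- df$id[df$type == 1]
  if (!length(soma_pts)) stop("SWC structural error: no soma point", call. = FALSE)
  # all soma points must form one connected cluster
  soma_parents <- df$parent[df$type == 1]
  n_root_soma <- sum(soma_parents == -1 | !(soma_parents %in% soma_pts))
  if (n_root_soma != 1)
    stop("SWC structural error: multiple somas", call. = FALSE)

  idx <- match(df$parent, df$id)
  # path distance of each point from the soma (soma points at 0)
  seglen <- sqrt((df$x - df$x[idx])^2 + (df$y - df$y[idx])^2 +
                   (df$z - df$z[idx])^2)
  seglen[is.na(seglen)] <- 0
  path <- numeric(nrow(df))
  ordpts <- order(ifelse(df$parent == -1, 0L, 1L))
  pending <- which(df$parent != -1)
  done <- which(df$parent == -1)
  while (length(pending)) {
    ready <- pending[idx[pending] %in% done]
    if (!length(ready)) stop("SWC structural error: cycle or orphan points", call. = FALSE)
    path[ready] <- ifelse(df$type[idx[ready]] == 1, 0,
                          path[idx[ready]]) + seglen[ready]
    path[ready][df$type[ready] == 1] <- 0
    done <- c(done, ready)
    pending <- setdiff(pending, ready)
  }

  # truncate axon: drop points beyond ais_keep_um; clip the crossing segment
  axon <- df$type == 2
  drop <- axon & path > ais_keep_um
  clip <- axon & path > ais_keep_um & (path - seglen) < ais_keep_um
  seglen[clip] <- ais_keep_um - (path[clip] - seglen[clip])
  drop[clip & seglen > 0] <- FALSE
  df2 <- df[!drop, ]; seglen2 <- seglen[!drop]; path2 <- pmin(path[!drop], ais_keep_um)
  # re-drop any point whose parent vanished (sub-branches of the cut axon)
  repeat {
    orphan <- !(df2$parent %in% c(-1, df2$id)) |
      (df2$parent %in% df$id[drop])
    orphan <- !(df2$parent == -1) & !(df2$parent %in% df2$id)
    if (!any(orphan)) break
    df2 <- df2[!orphan, ]; seglen2 <- seglen2[!orphan]; path2 <- path2[!orphan]
  }

  # merge per-point segments into unbranched sections
  nchild <- table(factor(df2$parent, levels = df2$id))
  is_soma <- df2$type == 1
  region_of <- function(t) c("soma", "ais", "dend", "dend")[t]
  secs <- list(tibble::tibble(id = 1L, region = "soma",
                              parent_id = NA_integer_,
                              length_um = soma_equiv_dims(soma_area_um2),
                              diam_um = soma_equiv_dims(soma_area_um2),
                              branch_order = 0L, path_dist_um = 0))
  nid <- 1L
  pt_sec <- integer(max(df2$id)); pt_sec[df2$id[is_soma]] <- 1L
  # walk non-soma points in parent-first order
  idx2 <- match(df2$parent, df2$id)
  ordv <- order(path2)
  open <- list()  # keyed by point id at section tip: list(sec, len, dsum, n, order, path0)
  for (r in ordv) {
    if (is_soma[r]) next
    pid <- df2$parent[r]
    parent_is_soma <- pid %in% df2$id[is_soma] || pid == -1
    start_new <- parent_is_soma ||
      nchild[[as.character(pid)]] > 1 ||
      df2$type[r] != df2$type[match(pid, df2$id)] ||
      is.null(open[[as.character(pid)]])
    if (start_new) {
      nid <- nid + 1L
      parent_sec <- if (parent_is_soma) 1L else pt_sec[pid]
      p_order <- secs[[parent_sec]]$branch_order
      b_order <- if (region_of(df2$type[r]) == "dend") {
        if (parent_sec == 1L) 1L else {
          if (nchild[[as.character(pid)]] > 1) p_order + 1L else max(p_order, 1L)
        }
      } else 0L
      path0 <- if (parent_is_soma) 0 else path2[match(pid, df2$id)]
      st <- list(sec = nid, len = seglen2[r], dsum = 2 * df2$radius[r] * seglen2[r],
                 order = b_order, path0 = path0, parent_sec = parent_sec,
                 type = df2$type[r])
    } else {
      st <- open[[as.character(pid)]]
      open[[as.character(pid)]] <- NULL
      st$dsum <- st$dsum + 2 * df2$radius[r] * seglen2[r]
      st$len <- st$len + seglen2[r]
    }
    open[[as.character(df2$id[r])]] <- st
    pt_sec[df2$id[r]] <- st$sec
    secs[[st$sec]] <- tibble::tibble(
      id = st$sec, region = region_of(st$type),
      parent_id = st$parent_sec,
      length_um = max(st$len, 1e-6),
      diam_um = max(st$dsum / max(st$len, 1e-9), 1e-3),
      branch_order = st$order,
      path_dist_um = st$path0 + st$len / 2)
  }
  morphology(dplyr::bind_rows(secs), soma_area_um2 = soma_area_um2,
             provenance = "swc")
}

#' Write a morphology back to SWC for inspection
#'
#' Sections are laid out along abstract coordinates (x = path distance);
#' the geometry (lengths, diameters, topology) round-trips, the 3-D
#' embedding does not.
#'
#' @param m a [morphology()].
#' @param path output file path.
#' @export
write_swc <- function(m, path) {
  type_of <- c(soma = 1L, ais = 2L, dend = 3L)
  # one SWC point per section end, plus the soma root
  rows <- data.frame(id = integer(), type = integer(), x = numeric(),
                     y = numeric(), z = numeric(), radius = numeric(),
                     parent = integer())
  soma_i <- which(m$region == "soma")
  rows[1, ] <- c(1, 1, 0, 0, 0, m$diam_um[soma_i] / 2, -1)
  id_map <- stats::setNames(rep(1L, nrow(m)), m$id)
  nid <- 1L
  ord <- order(m$path_dist_um)
  for (i in ord) {
    if (m$region[i] == "soma") next
    nid <- nid + 1L
    p <- id_map[[as.character(m$parent_id[i])]]
    x0 <- rows$x[rows$id == p]
    rows[nid, ] <- c(nid, type_of[[m$region[i]]], x0 + m$length_um[i],
                     0, 0, m$diam_um[i] / 2, p)
    id_map[[as.character(m$id[i])]] <- nid
  }
  writeLines(c("# generated by thalamod",
               apply(rows, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))),
             path)
  invisible(path)
}
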