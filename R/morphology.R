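## Morphology: GENESIS .p and SWC parsing, path distances, region assignment.
## Coordinates in the files are micrometres; everything returned is SI (m).

.morph_finalize <- function(df) {
  rownames(df) <- NULL
  if (sum(is.na(df$parent)) != 1L)
    stop("morphology: exactly one root segment required")
  ## parent graph must be a tree reachable from the root
  idx <- match(df$parent, df$id)
  if (any(is.na(idx) & !is.na(df$parent)))
    stop("morphology: dangling parent reference: ",
         df$parent[which(is.na(idx) & !is.na(df$parent))[1]])
  root <- which(is.na(df$parent))
  ## detect cycles / unreachable nodes by walking up from each node
  n <- nrow(df)
  for (i in seq_len(n)) {
    j <- i; steps <- 0L
    while (!is.na(idx[j])) {
      j <- idx[j]; steps <- steps + 1L
      if (steps > n) stop("morphology: cyclic parent references")
    }
    if (j != root) stop("morphology: segment ", df$id[i],
                        " not connected to the root")
  }
  if (any(df$diameter <= 0))
    stop("morphology: non-positive diameter for segment ",
         df$id[which(df$diameter <= 0)[1]])
  if (any(!df$is_spherical & df$length <= 0))
    stop("morphology: non-positive length for segment ",
         df$id[which(!df$is_spherical & df$length <= 0)[1]])
  ## path distance from soma center to segment midpoint, along the tree;
  ## the root itself is at distance 0 and its distal end is also 0 for a
  ## sphere (distance is measured from the soma surface outward).
  dist_end <- numeric(n)
  pd <- numeric(n)
  ord <- .morph_topo_order(df)
  for (i in ord) {
    if (is.na(idx[i])) {
      dist_end[i] <- if (df$is_spherical[i]) 0 else df$length[i]
      pd[i] <- 0
    } else {
      pd[i] <- dist_end[idx[i]] + df$length[i] / 2
      dist_end[i] <- dist_end[idx[i]] + df$length[i]
    }
  }
  df$path_distance <- pd
  class(df) <- c("neuro_morph", "data.frame")
  df
}

## topological order (parents before children)
.morph_topo_order <- function(df) {
  idx <- match(df$parent, df$id)
  ord <- integer(0)
  placed <- rep(FALSE, nrow(df))
  repeat {
    ready <- which(!placed & (is.na(idx) | placed[idx]))
    if (!length(ready)) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (length(ord) != nrow(df)) stop("morphology: cyclic parent references")
  ord
}

#' Construct a morphology table directly
#'
#' @param id segment labels.
#' @param parent parent labels (`NA` for the single root).
#' @param length segment lengths (m); ignored for the spherical root.
#' @param diameter diameters (m).
#' @param is_spherical logical; only the root may be spherical.
#' @param x,y,z optional distal-end coordinates (m), kept for
#'   re-serialization.
#' @param type optional SWC type codes.
#' @return data frame of class `neuro_morph` with a `path_distance` column
#'   (m from the soma to the segment midpoint, along the tree).
#' @export
morph_segments <- function(id, parent, length, diameter,
                           is_spherical = NULL, x = NA_real_, y = NA_real_,
                           z = NA_real_, type = NA_integer_) {
  if (is.null(is_spherical)) is_spherical <- is.na(parent) & length == 0
  df <- data.frame(id = as.character(id), parent = as.character(parent),
                   length = length, diameter = diameter,
                   is_spherical = is_spherical, x = x, y = y, z = z,
                   type = type, stringsAsFactors = FALSE)
  df <- .morph_finalize(df)
  ## synthesize distal-end coordinates when none are supplied, so the
  ## morphology can be serialized: each segment extends its parent's
  ## endpoint along +x by its length (geometry is not used beyond lengths)
  if (all(is.na(df$x))) {
    idx <- match(df$parent, df$id)
    for (i in .morph_topo_order(df)) {
      if (is.na(idx[i])) {
        df$x[i] <- 0; df$y[i] <- 0; df$z[i] <- 0
      } else {
        df$x[i] <- df$x[idx[i]] + df$length[i]
        df$y[i] <- df$y[idx[i]]
        df$z[i] <- df$z[idx[i]]
      }
    }
  }
  df
}

#' Parse a GENESIS .p morphology file
#'
#' Supports `//` comments, the `*absolute` (default) and `*relative`
#' directives, and 6-column rows `name parent x y z diameter` with
#' coordinates and diameters in micrometres. In absolute mode a root row
#' has zero extent and becomes a spherical soma; in relative mode the
#' coordinates are offsets from the parent's distal end and segment length
#' is their Euclidean norm.
#'
#' @param text the file contents as a single string or character vector of
#'   lines, or a file path (when `is_path = TRUE`).
#' @param is_path interpret `text` as a path.
#' @return a `neuro_morph` data frame (SI units).
#' @export
parse_p_file <- function(text, is_path = FALSE) {
  lines <- if (is_path) readLines(text) else unlist(strsplit(text, "\n"))
  mode <- "absolute"
  rows <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("//.*$", "", lines[ln])
    raw <- trimws(raw)
    if (raw == "") next
    if (startsWith(raw, "*")) {
      if (raw == "*relative") mode <- "relative"
      else if (raw == "*absolute") mode <- "absolute"
      else stop(sprintf("parse_p_file: unknown directive '%s' at line %d",
                        raw, ln))
      next
    }
    tok <- strsplit(raw, "[[:space:]]+")[[1]]
    if (length(tok) != 6L)
      stop(sprintf("parse_p_file: expected 6 columns at line %d", ln))
    xyz <- suppressWarnings(as.numeric(tok[3:5]))
    dia <- suppressWarnings(as.numeric(tok[6]))
    if (any(is.na(c(xyz, dia))))
      stop(sprintf("parse_p_file: non-numeric value at line %d", ln))
    if (dia <= 0)
      stop(sprintf("parse_p_file: non-positive diameter at line %d", ln))
    rows[[length(rows) + 1L]] <-
      list(id = tok[1], parent = tok[2], xyz = xyz, dia = dia, mode = mode,
           line = ln)
  }
  if (!length(rows)) stop("parse_p_file: no segment rows found")
  um <- 1e-6
  ids <- vapply(rows, `[[`, character(1), "id")
  out <- data.frame(id = ids, parent = NA_character_, length = 0,
                    diameter = NA_real_, is_spherical = FALSE,
                    x = NA_real_, y = NA_real_, z = NA_real_,
                    type = NA_integer_, stringsAsFactors = FALSE)
  endpoint <- matrix(NA_real_, nrow(out), 3)
  for (k in seq_along(rows)) {
    r <- rows[[k]]
    is_root <- r$parent %in% c("none", "None", "NONE", "-1")
    out$parent[k] <- if (is_root) NA_character_ else r$parent
    out$diameter[k] <- r$dia * um
    if (is_root) {
      ext <- if (r$mode == "relative") sqrt(sum(r$xyz^2)) * um else 0
      endpoint[k, ] <- if (r$mode == "relative") r$xyz * um else r$xyz * um
      out$length[k] <- ext
      out$is_spherical[k] <- ext == 0
    } else {
      pk <- match(r$parent, ids[seq_len(k - 1L)])
      if (is.na(pk))
        stop(sprintf("parse_p_file: dangling parent '%s' at line %d",
                     r$parent, r$line))
      if (r$mode == "relative") {
        delta <- r$xyz * um
        endpoint[k, ] <- endpoint[pk, ] + delta
      } else {
        endpoint[k, ] <- r$xyz * um
        delta <- endpoint[k, ] - endpoint[pk, ]
      }
      out$length[k] <- sqrt(sum(delta^2))
      if (out$length[k] <= 0)
        stop(sprintf("parse_p_file: zero-length segment at line %d", r$line))
    }
  }
  out$x <- endpoint[, 1]; out$y <- endpoint[, 2]; out$z <- endpoint[, 3]
  .morph_finalize(out)
}

#' Serialize a morphology to GENESIS .p text
#'
#' Writes `*absolute` rows in micrometres; the inverse of [parse_p_file()]
#' up to floating-point formatting.
#'
#' @param morph a `neuro_morph` data frame.
#' @return character scalar with the file contents.
#' @export
write_p_file <- function(morph) {
  stopifnot(inherits(morph, "neuro_morph"))
  um <- 1e6
  rows <- vapply(seq_len(nrow(morph)), function(i) {
    sprintf("%s %s %.12g %.12g %.12g %.12g",
            morph$id[i],
            if (is.na(morph$parent[i])) "none" else morph$parent[i],
            morph$x[i] * um, morph$y[i] * um, morph$z[i] * um,
            morph$diameter[i] * um)
  }, character(1))
  paste(c("// neurofit morphology", "*absolute", rows, ""), collapse = "\n")
}

#' Parse an SWC morphology file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), micrometres.
#' A single root point becomes a spherical soma of diameter 2 x radius;
#' every other point becomes a cylinder from its parent point.
#'
#' @inheritParams parse_p_file
#' @return a `neuro_morph` data frame (SI units).
#' @export
parse_swc <- function(text, is_path = FALSE) {
  lines <- if (is_path) readLines(text) else unlist(strsplit(text, "\n"))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  if (!length(lines)) stop("parse_swc: no records found")
  fields <- lapply(lines, function(l) strsplit(l, "[[:space:]]+")[[1]])
  if (any(lengths(fields) != 7L))
    stop("parse_swc: every record must have 7 columns")
  m <- do.call(rbind, lapply(fields, as.numeric))
  if (any(is.na(m))) stop("parse_swc: non-numeric record")
  um <- 1e-6
  ids <- as.character(as.integer(m[, 1]))
  parents <- as.integer(m[, 7])
  root <- which(parents == -1L)
  if (length(root) != 1L) stop("parse_swc: exactly one root (parent -1) required")
  out <- data.frame(id = ids,
                    parent = ifelse(parents == -1L, NA_character_,
                                    as.character(parents)),
                    length = 0, diameter = 2 * m[, 6] * um,
                    is_spherical = parents == -1L,
                    x = m[, 3] * um, y = m[, 4] * um, z = m[, 5] * um,
                    type = as.integer(m[, 2]), stringsAsFactors = FALSE)
  pk <- match(out$parent, ids)
  for (k in seq_len(nrow(out))) {
    if (is.na(pk[k])) next
    delta <- c(out$x[k] - out$x[pk[k]], out$y[k] - out$y[pk[k]],
               out$z[k] - out$z[pk[k]])
    out$length[k] <- sqrt(sum(delta^2))
  }
  .morph_finalize(out)
}

#' Serialize a morphology to SWC text
#'
#' @param morph a `neuro_morph` data frame.
#' @return character scalar; inverse of [parse_swc()] up to formatting.
#' @export
write_swc <- function(morph) {
  stopifnot(inherits(morph, "neuro_morph"))
  um <- 1e6
  newid <- seq_len(nrow(morph))
  names(newid) <- morph$id
  rows <- vapply(seq_len(nrow(morph)), function(i) {
    sprintf("%d %d %.12g %.12g %.12g %.12g %d",
            newid[[morph$id[i]]],
            if (is.na(morph$type[i])) if (is.na(morph$parent[i])) 1L else 3L
            else morph$type[i],
            morph$x[i] * um, morph$y[i] * um, morph$z[i] * um,
            morph$diameter[i] / 2 * um,
            if (is.na(morph$parent[i])) -1L else newid[[morph$parent[i]]])
  }, character(1))
  paste(c("# neurofit morphology", rows, ""), collapse = "\n")
}

#' Assign neuron regions by path distance
#'
#' Region 0 is the soma (the root segment); region 1 covers segments whose
#' midpoint path distance is at most the first threshold; region 2 is
#' everything beyond. The second threshold is carried in the model
#' specification for forward compatibility but does not enter this rule.
#'
#' @param morph a `neuro_morph` data frame.
#' @param thresholds numeric of length 1 or 2; the first element is the
#'   proximal/distal split (m).
#' @return integer vector of regions (0, 1 or 2), one per segment.
#' @export
assign_regions <- function(morph, thresholds = c(60e-6, 120e-6)) {
  stopifnot(inherits(morph, "neuro_morph"))
  t1 <- thresholds[1]
  ifelse(is.na(morph$parent), 0L,
         ifelse(morph$path_distance <= t1, 1L, 2L))
}

#' Membrane surface area of each segment
#'
#' Sphere: pi d^2; cylinder: pi d L (no spine correction).
#'
#' @param morph a `neuro_morph` data frame.
#' @return numeric vector of areas (m^2).
#' @export
segment_areas <- function(morph) {
  stopifnot(inherits(morph, "neuro_morph"))
  ifelse(morph$is_spherical, pi * morph$diameter^2,
         pi * morph$diameter * morph$length)
}
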