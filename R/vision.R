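# Visual system: rasterize the uncovered silhouette, extract edges, and
# template-match rotated tan edge templates with sum of squared differences.
#
# Rasters are binary matrices indexed [row, col] with row 1 at the BOTTOM
# (y grows with the row index); pixel (r, c) has its centre at
# origin + ((c - 0.5)/res, (r - 0.5)/res).  Edge images and templates use the
# same morphological boundary operator (dilate minus erode, 3x3 cross), so an
# exactly tan-congruent, pixel-aligned hole matches its template with SSD 0.

#' @keywords internal
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' @keywords internal
morph_boundary <- function(mask) {
  # 3x3 cross structuring element
  dil <- mask | shift_mat(mask, 1, 0) | shift_mat(mask, -1, 0) |
    shift_mat(mask, 0, 1) | shift_mat(mask, 0, -1)
  ero <- mask & shift_mat(mask, 1, 0) & shift_mat(mask, -1, 0) &
    shift_mat(mask, 0, 1) & shift_mat(mask, 0, -1)
  dil & !ero
}

#' @keywords internal
rasterize_mask <- function(polys_in, polys_out, origin, H, W, resolution) {
  # sample just off the pixel centre (distinct sub-pixel offsets per axis) so
  # no sample ever lies exactly on a horizontal, vertical or 45-degree edge:
  # every sample is then strictly on one side, and a hole raster partitions
  # cleanly against the rasters of its placed neighbours
  cx <- origin[1] + (seq_len(W) - 0.5 + 0.01) / resolution
  cy <- origin[2] + (seq_len(H) - 0.5 + 0.03) / resolution
  px <- rep(cx, each = H)
  py <- rep(cy, times = W)
  inside <- rep(FALSE, H * W)
  for (p in polys_in) inside <- inside | points_in_poly(px, py, p, tol = 1e-12)
  for (p in polys_out) inside <- inside & !points_in_poly(px, py, p, tol = 1e-12)
  matrix(inside, H, W)
}

#' Rasterize the boundary of the uncovered region
#'
#' Binarizes the uncovered region (silhouette minus placed pieces) and
#' extracts its morphological boundary: the outer silhouette edges plus the
#' exposed edges of placed pieces.
#'
#' @param state A `puzzle_state`.
#' @param resolution Pixels per geometry unit (>= 8).
#' @return Object of class `edge_image`: list with binary `pixels`,
#'   `resolution` and `origin` (geometry coordinates of the raster corner).
#' @export
rasterize_uncovered <- function(state, resolution = 12) {
  if (resolution < 8) stop("resolution must be at least 8 px/unit")
  margin <- 2L
  bb <- poly_bbox(state$puzzle$target)
  origin <- c(bb["xmin"] - margin / resolution, bb["ymin"] - margin / resolution)
  W <- as.integer(ceiling((bb["xmax"] - bb["xmin"]) * resolution - 1e-6)) + 2L * margin
  H <- as.integer(ceiling((bb["ymax"] - bb["ymin"]) * resolution - 1e-6)) + 2L * margin
  placed_polys <- lapply(state$placed, function(p) p$polygon)
  mask <- rasterize_mask(list(state$puzzle$target), placed_polys, origin, H, W, resolution)
  if (uncovered_area(state) <= AREA_TOL) mask[] <- FALSE
  structure(list(pixels = morph_boundary(mask), resolution = resolution,
                 origin = unname(origin)), class = "edge_image")
}

#' Build the bank of tan edge templates
#'
#' One edge template per (kind, rotation) pair, 8 rotations in 45-degree
#' steps, plus mirrored variants of the parallelogram when mirroring is
#' enabled.  Symmetric duplicates (e.g. the square at 0 and 90 degrees) are
#' retained, not deduplicated.
#'
#' @param resolution Pixels per geometry unit; must match the edge image.
#' @param mirroring Include mirrored parallelogram templates.
#' @return Object of class `template_bank`: list of templates, each a list
#'   with `kind`, `rotation`, `mirrored`, `pixels`.
#' @export
build_templates <- function(resolution = 12, mirroring = TRUE) {
  key <- paste0("templates_", resolution, "_", mirroring)
  if (!is.null(.cts_cache[[key]])) return(.cts_cache[[key]])
  out <- list()
  for (kind in tan_kinds()) {
    mirrors <- if (kind == "parallelogram" && mirroring) c(FALSE, TRUE) else FALSE
    for (mir in mirrors) {
      for (rot in seq(0L, 315L, by = 45L)) {
        poly <- transform_tan(kind, rot, c(0, 0), mir)
        bb <- poly_bbox(poly)
        W <- as.integer(ceiling(bb["xmax"] * resolution - 1e-6))
        H <- as.integer(ceiling(bb["ymax"] * resolution - 1e-6))
        mask <- rasterize_mask(list(poly), list(), c(0, 0), H, W, resolution)
        out[[length(out) + 1L]] <- list(kind = kind, rotation = rot, mirrored = mir,
                                        pixels = morph_boundary(mask))
      }
    }
  }
  bank <- structure(out, class = "template_bank")
  .cts_cache[[key]] <- bank
  bank
}

#' @keywords internal
summed_area <- function(m) {
  s <- apply(m, 2, cumsum)
  t(apply(s, 1, cumsum))
}

#' @keywords internal
window_sums <- function(E, th, tw) {
  S <- summed_area(E)
  H <- nrow(E); W <- ncol(E)
  Z <- matrix(0, H + 1L, W + 1L)
  Z[-1, -1] <- S
  r <- seq_len(H - th + 1L); c <- seq_len(W - tw + 1L)
  Z[r + th, c + tw, drop = FALSE] - Z[r, c + tw, drop = FALSE] -
    Z[r + th, c, drop = FALSE] + Z[r, c, drop = FALSE]
}

#' Match one edge template against an edge image
#'
#' Sum-of-squared-differences over every valid window position, followed by
#' non-maximum suppression (radius = half the template's larger dimension) so
#' near-duplicate minima collapse; at most `max_candidates` positions are
#' returned, sorted by ascending SSD with ties broken in (row, column) scan
#' order.
#'
#' @param edges An `edge_image`.
#' @param template One element of a [build_templates()] bank.
#' @param max_candidates Cap on returned positions (default 5).
#' @return data.frame with columns `row`, `col` (window lower-left pixel),
#'   `ssd`; attribute `ssd_max` holds the normalization bound (template set
#'   pixels + maximum set pixels in any window).  Empty when the template is
#'   larger than the image.
#' @export
match_template <- function(edges, template, max_candidates = 5L) {
  E <- edges$pixels * 1
  tp <- template$pixels * 1
  th <- nrow(tp); tw <- ncol(tp)
  H <- nrow(E); W <- ncol(E)
  empty <- data.frame(row = integer(0), col = integer(0), ssd = numeric(0))
  if (th > H || tw > W) {
    attr(empty, "ssd_max") <- sum(tp)
    return(empty)
  }
  S2 <- window_sums(E, th, tw)           # binary: sum of squares = sum
  sumT <- sum(tp)
  CC <- matrix(0, H - th + 1L, W - tw + 1L)
  set <- which(tp > 0, arr.ind = TRUE)
  nr <- nrow(CC); nc <- ncol(CC)
  for (k in seq_len(nrow(set))) {
    i <- set[k, 1]; j <- set[k, 2]
    CC <- CC + E[i:(i + nr - 1L), j:(j + nc - 1L), drop = FALSE]
  }
  SSD <- S2 - 2 * CC + sumT
  ssd_max <- sumT + max(S2)
  ord <- order(SSD, row(SSD), col(SSD))
  radius <- floor(max(th, tw) / 2)
  picked <- matrix(numeric(0), 0, 2)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (idx in ord) {
    r <- row(SSD)[idx]; c <- col(SSD)[idx]
    if (nrow(picked) > 0 &&
        any(pmax(abs(picked[, 1] - r), abs(picked[, 2] - c)) < radius)) next
    picked <- rbind(picked, c(r, c))
    rows <- c(rows, r); cols <- c(cols, c); vals <- c(vals, SSD[idx])
    if (length(rows) >= max_candidates) break
  }
  out <- data.frame(row = rows, col = cols, ssd = vals)
  attr(out, "ssd_max") <- ssd_max
  out
}

#' Similarity score from a raw SSD value
#'
#' Linear rescaling `1 - ssd/ssd_max`, clipped to `[0, 1]`; strictly
#' decreasing in the SSD on `[0, ssd_max]`.
#'
#' @param ssd Raw sum-of-squared-differences (>= 0).
#' @param ssd_max Normalization bound (> 0).
#' @return Similarity in `[0, 1]`.
#' @export
similarity_from_ssd <- function(ssd, ssd_max) {
  if (any(ssd < 0)) stop("invalid score: ssd must be non-negative")
  if (ssd_max <= 0) stop("ssd_max must be positive")
  pmin(1, pmax(0, 1 - ssd / ssd_max))
}

#' @keywords internal
snap_to_grid <- function(state, kind, rotation, mirrored, x, y, resolution) {
  grid <- state$puzzle$grid
  d2 <- (grid$x - x)^2 + (grid$y - y)^2
  radius <- 1.5 / resolution
  near <- which(d2 <= radius^2)
  if (length(near) > 0) {
    near <- near[order(d2[near])]
    for (gi in near) {
      if (is_legal_placement(state, kind, grid$index[gi], rotation, mirrored)) {
        return(list(grid_loc = grid$index[gi], legal = TRUE))
      }
    }
  }
  list(grid_loc = grid$index[which.min(d2)], legal = NA)
}

#' Extract raw candidates for every template
#'
#' Runs [match_template()] for the whole bank on the current uncovered-region
#' edge image, converts pixel locations to grid anchors (snapping prefers the
#' nearest anchor at which the placement is geometrically legal), and merges
#' candidates that snap to the same placement, keeping the lower SSD.
#'
#' @param state A `puzzle_state`.
#' @param resolution Pixels per geometry unit.
#' @param bank Optional pre-built [build_templates()] bank.
#' @param max_candidates Per-template candidate cap (default 5).
#' @param mirroring Include mirrored parallelogram templates.
#' @return data.frame of candidates: `kind`, `grid_loc`, `rotation`,
#'   `mirrored`, `ssd`, `s` (similarity), `legal` (geometric legality, NA if
#'   only snapped by distance).
#' @export
extract_candidates <- function(state, resolution = 12, bank = NULL,
                               max_candidates = 5L, mirroring = TRUE) {
  if (is.null(bank)) bank <- build_templates(resolution, mirroring)
  edges <- rasterize_uncovered(state, resolution)
  res <- list()
  max_per_template <- 0L
  for (tpl in bank) {
    if (length(free_instances(state, tpl$kind)) == 0) next
    m <- match_template(edges, tpl, max_candidates)
    max_per_template <- max(max_per_template, nrow(m))
    if (nrow(m) == 0) next
    ssd_max <- attr(m, "ssd_max")
    for (i in seq_len(nrow(m))) {
      x <- edges$origin[1] + (m$col[i] - 1L) / resolution
      y <- edges$origin[2] + (m$row[i] - 1L) / resolution
      sn <- snap_to_grid(state, tpl$kind, tpl$rotation, tpl$mirrored, x, y, resolution)
      res[[length(res) + 1L]] <- data.frame(
        kind = tpl$kind, grid_loc = sn$grid_loc, rotation = tpl$rotation,
        mirrored = tpl$mirrored, ssd = m$ssd[i],
        s = similarity_from_ssd(m$ssd[i], max(ssd_max, 1)),
        legal = sn$legal, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    return(data.frame(kind = character(0), grid_loc = integer(0),
                      rotation = integer(0), mirrored = logical(0),
                      ssd = numeric(0), s = numeric(0), legal = logical(0)))
  }
  out <- do.call(rbind, res)
  # merge duplicates, keep lowest ssd
  keykeep <- paste(out$kind, out$grid_loc, out$rotation, out$mirrored)
  out <- out[order(keykeep, out$ssd), , drop = FALSE]
  out <- out[!duplicated(paste(out$kind, out$grid_loc, out$rotation, out$mirrored)), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "max_per_template") <- max_per_template
  out
}

#' Filter candidates into action-options
#'
#' Two screens, following the extraction pipeline: a geometric screen (the
#' snapped placement must be legal, i.e. a member of the brute-force
#' [legal_placements()] set) and a frequency screen (the placement must have
#' non-zero phase-conditioned frequency in the training data).  Survivors
#' become action-options carrying similarity `s` and frequency `f`.
#'
#' @param cands Candidate data.frame from [extract_candidates()].
#' @param state A `puzzle_state`.
#' @param freqs A frequency table (see [build_frequency_table()]); may be
#'   NULL when the frequency screen is disabled.
#' @param phase Solution-phase index used for the frequency lookup.
#' @param frequency_screen Apply the frequency screen (default TRUE); when
#'   disabled, geometric survivors pass with `f = 0`.
#' @return data.frame of action-options: `kind`, `grid_loc`, `rotation`,
#'   `mirrored`, `s`, `f`, `phase`, `strength` (NA until scored).
#' @export
filter_candidates <- function(cands, state, freqs = NULL, phase = 1L,
                              frequency_screen = TRUE) {
  if (nrow(cands) > 0) {
    ok_free <- vapply(cands$kind, function(k) length(free_instances(state, k)) > 0,
                      logical(1))
    cands <- cands[ok_free, , drop = FALSE]
  }
  if (nrow(cands) > 0) {
    legal <- cands$legal
    need <- is.na(legal)
    if (any(need)) {
      legal[need] <- vapply(which(need), function(i)
        is_legal_placement(state, cands$kind[i], cands$grid_loc[i],
                           cands$rotation[i], cands$mirrored[i]), logical(1))
    }
    cands <- cands[legal, , drop = FALSE]
  }
  f <- if (nrow(cands) == 0) numeric(0)
       else if (is.null(freqs)) rep(0, nrow(cands))
       else freq_lookup(freqs, cands$kind, cands$grid_loc, cands$rotation, phase)
  if (frequency_screen && nrow(cands) > 0) {
    keep <- f > 0
    cands <- cands[keep, , drop = FALSE]
    f <- f[keep]
  }
  out <- data.frame(kind = cands$kind, grid_loc = cands$grid_loc,
                    rotation = cands$rotation, mirrored = cands$mirrored,
                    s = cands$s, f = f,
                    phase = rep(as.integer(phase), nrow(cands)),
                    strength = rep(NA_real_, nrow(cands)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
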