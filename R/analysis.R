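#' Bin a per-triangle field into linear value bins
#'
#' Divides the value range [min, max] linearly into `n_bins` sub-domains
#' (the last bin right-inclusive) and accumulates triangle areas per bin,
#' the data behind colour-coded curvature maps. A constant field collapses
#' to a single occupied bin with area fraction 1.
#'
#' @param values per-triangle field values.
#' @param areas per-triangle areas (um^2).
#' @param n_bins number of linear bins (>= 1), default 10.
#' @return An object of class `binned_map`: data frame with `bin`, `lo`,
#'   `hi`, `mean_value`, `n_faces`, `area_um2`, `area_fraction`; the
#'   per-triangle bin index is in `attr(, "bin_index")`, the bin edges in
#'   `attr(, "breaks")`.
#' @export
bin_curvature <- function(values, areas, n_bins = 10) {
  stopifnot(length(values) == length(areas), n_bins >= 1)
  if (length(values) == 0) stop("empty field")
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    out <- data.frame(bin = 1L, lo = lo, hi = hi, mean_value = lo,
                      n_faces = length(values), area_um2 = sum(areas),
                      area_fraction = 1)
    attr(out, "bin_index") <- rep(1L, length(values))
    attr(out, "breaks") <- c(lo, hi)
    class(out) <- c("binned_map", class(out))
    return(out)
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  width <- (hi - lo) / n_bins
  idx <- pmin(pmax(floor((values - lo) / width) + 1, 1L), n_bins)
  tot <- sum(areas)
  mean_value <- n_faces <- area <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    sel <- idx == b
    n_faces[b] <- sum(sel)
    area[b] <- sum(areas[sel])
    mean_value[b] <- if (any(sel)) weighted_average_curvature(values[sel], areas[sel]) else NA_real_
  }
  out <- data.frame(bin = seq_len(n_bins), lo = breaks[-(n_bins + 1)],
                    hi = breaks[-1], mean_value = mean_value,
                    n_faces = as.integer(n_faces), area_um2 = area,
                    area_fraction = area / tot)
  attr(out, "bin_index") <- as.integer(idx)
  attr(out, "breaks") <- breaks
  class(out) <- c("binned_map", class(out))
  out
}

#' Binned curvature profile of a (theta, xi) state
#'
#' Meshes the affine-transformed discocyte and bins each of the four
#' curvature types into `n_bins` linear value bins, giving the per-bin mean
#' value and area fraction (the polygonal-graph data of curvature-vs-area
#' analyses).
#'
#' @param geom an [rbc_geometry()].
#' @param theta rotation about x, degrees.
#' @param xi strain factor along z.
#' @param n_bins linear bins per curvature type.
#' @param target_edges mesh resolution.
#' @param mode curvature evaluation mode, see [per_triangle_curvature()].
#' @return Data frame with columns `curvature` (KG/KM/k1/k2), `bin`, `lo`,
#'   `hi`, `mean_value`, `area_um2`, `area_fraction`.
#' @export
curvature_profile <- function(geom, theta = 0, xi = 1, n_bins = 10,
                              target_edges = 12000, mode = "vertex_mean") {
  surf <- deform_surface(implicit_rbc(geom), affine_deformation(theta, xi))
  mesh <- mesh_implicit(surf, target_edges = target_edges)
  fld <- per_triangle_curvature(mesh, surf, mode = mode)
  profile_from_field(fld, n_bins)
}

profile_from_field <- function(fld, n_bins = 10) {
  cols <- c(KG = "KG_um_2", KM = "KM_um_1", k1 = "k1_um_1", k2 = "k2_um_1")
  out <- lapply(names(cols), function(nm) {
    bm <- bin_curvature(fld[[cols[[nm]]]], fld$area_um2, n_bins)
    cbind(curvature = nm, as.data.frame(bm))
  })
  do.call(rbind, out)
}

#' Area, volume and edge statistics over a (theta, xi) grid
#'
#' Re-meshes the transformed implicit surface for every grid cell (the
#' remesh-per-state workflow) and tabulates surface area, volume and mean
#' edge length; optionally the area-weighted average curvatures. Meshing
#' failures are reported per cell and the sweep continues.
#'
#' @param geom an [rbc_geometry()].
#' @param thetas rotation angles, degrees.
#' @param xis strain factors.
#' @param target_edges mesh resolution per cell.
#' @param include_curvature add area-weighted mean of the four curvatures.
#' @return Data frame with one row per (theta, xi).
#' @export
strain_sweep <- function(geom, thetas = c(0, 45, 90),
                         xis = c(1, 1.25, 1.5, 1.75),
                         target_edges = 12000, include_curvature = FALSE) {
  stopifnot(length(thetas) > 0, length(xis) > 0)
  grid <- expand.grid(theta_deg = thetas, xi = xis)
  grid <- grid[order(grid$theta_deg, grid$xi), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    th <- grid$theta_deg[i]; xi <- grid$xi[i]
    res <- tryCatch({
      surf <- deform_surface(implicit_rbc(geom), affine_deformation(th, xi))
      mesh <- mesh_implicit(surf, target_edges = target_edges)
      row <- data.frame(theta_deg = th, xi = xi,
                        n_vertices = nrow(mesh$vertices),
                        n_edges = nrow(mesh_edges(mesh)),
                        n_faces = nrow(mesh$faces),
                        area_um2 = mesh_area(mesh),
                        volume_um3 = mesh_volume(mesh),
                        mean_edge_nm = mean(edge_lengths(mesh)) * 1000,
                        error = NA_character_)
      if (include_curvature) {
        fld <- per_triangle_curvature(mesh, surf)
        row$wavg_KG_um_2 <- weighted_average_curvature(fld$KG_um_2, fld$area_um2)
        row$wavg_KM_um_1 <- weighted_average_curvature(fld$KM_um_1, fld$area_um2)
        row$wavg_k1_um_1 <- weighted_average_curvature(fld$k1_um_1, fld$area_um2)
        row$wavg_k2_um_1 <- weighted_average_curvature(fld$k2_um_1, fld$area_um2)
      }
      row
    }, error = function(e) {
      row <- data.frame(theta_deg = th, xi = xi, n_vertices = NA_integer_,
                        n_edges = NA_integer_, n_faces = NA_integer_,
                        area_um2 = NA_real_, volume_um3 = NA_real_,
                        mean_edge_nm = NA_real_, error = conditionMessage(e))
      if (include_curvature)
        row[c("wavg_KG_um_2", "wavg_KM_um_1", "wavg_k1_um_1", "wavg_k2_um_1")] <- NA_real_
      row
    })
    res
  })
  do.call(rbind, rows)
}

#' Histogram of mesh edge lengths
#'
#' Linear bins over [min, max] edge length, with the summary statistics of
#' interest for the spectrin-network comparison: overall mean, the span and
#' mass of the tallest bin, and the mass of the top-k bins.
#'
#' @param mesh a [trimesh].
#' @param n_bins number of linear bins (20 for the coarse view, 200 for the
#'   fine view).
#' @param top_k how many of the most-populated bins to pool in the
#'   `top_k_fraction` summary.
#' @return List with `histogram` (data frame: bin, lo_nm, hi_nm, count),
#'   `mean_nm`, `modal_bin_span_nm`, `modal_bin_fraction`, `top_k_fraction`.
#' @export
edge_length_histogram <- function(mesh, n_bins = 20, top_k = 2) {
  len_nm <- edge_lengths(mesh) * 1000
  lo <- min(len_nm); hi <- max(len_nm)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  width <- (hi - lo) / n_bins
  idx <- pmin(pmax(floor((len_nm - lo) / width) + 1, 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  modal <- which.max(counts)
  topk <- order(counts, decreasing = TRUE)[seq_len(min(top_k, n_bins))]
  list(histogram = data.frame(bin = seq_len(n_bins),
                              lo_nm = breaks[-(n_bins + 1)],
                              hi_nm = breaks[-1], count = counts),
       mean_nm = mean(len_nm),
       modal_bin_span_nm = c(breaks[modal], breaks[modal + 1]),
       modal_bin_fraction = counts[modal] / length(len_nm),
       top_k_fraction = sum(counts[topk]) / length(len_nm))
}

#' Histogram of triangle areas
#'
#' Linear bins over [min, max] triangle area with per-bin counts, mean area
#' and share of the total surface area.
#'
#' @param mesh a [trimesh].
#' @param n_bins number of linear bins.
#' @return List with `histogram` (bin, lo_nm2, hi_nm2, count, mean_nm2,
#'   area_share) and `mean_area_nm2` (total area / number of triangles).
#' @export
triangle_area_histogram <- function(mesh, n_bins = 10) {
  area_nm2 <- face_areas(mesh) * 1e6
  lo <- min(area_nm2); hi <- max(area_nm2)
  if (hi == lo) {
    hg <- data.frame(bin = 1L, lo_nm2 = lo, hi_nm2 = hi,
                     count = length(area_nm2), mean_nm2 = lo, area_share = 1)
    return(list(histogram = hg, mean_area_nm2 = lo))
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  width <- (hi - lo) / n_bins
  idx <- pmin(pmax(floor((area_nm2 - lo) / width) + 1, 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  meanb <- vapply(seq_len(n_bins), function(b)
    if (counts[b] > 0) mean(area_nm2[idx == b]) else NA_real_, numeric(1))
  share <- vapply(seq_len(n_bins), function(b) sum(area_nm2[idx == b]), numeric(1)) /
    sum(area_nm2)
  list(histogram = data.frame(bin = seq_len(n_bins),
                              lo_nm2 = breaks[-(n_bins + 1)], hi_nm2 = breaks[-1],
                              count = counts, mean_nm2 = meanb, area_share = share),
       mean_area_nm2 = mean(area_nm2))
}

#' Partition triangles by strain-induced area change
#'
#' Meshes the relaxed cell once, pushes the vertices forward through
#' M = S_xi R_theta (triangle identity preserved, volume exactly conserved)
#' and classifies each triangle by the sign of its relative area change
#' (area_after - area_before)/area_before. Relative changes below 1e-12 in
#' magnitude count as unchanged. Connected components of the expanded and
#' diminished face sets (by shared edges) are also counted.
#'
#' @inheritParams curvature_profile
#' @return An object of class `area_change_partition`: list with `per_face`
#'   (face, area_before_um2, area_after_um2, rel_change, class), index sets
#'   `expanded`, `diminished`, `unchanged`, component counts and summary
#'   areas, plus the relaxed and pushed-forward meshes.
#' @export
area_change_partition <- function(geom, theta = 0, xi = 1.75,
                                  target_edges = 12000) {
  def <- affine_deformation(theta, xi)
  relaxed <- mesh_implicit(implicit_rbc(geom), target_edges = target_edges)
  pushed <- push_forward(relaxed, def)
  a0 <- face_areas(relaxed); a1 <- face_areas(pushed)
  rel <- (a1 - a0) / a0
  cls <- ifelse(abs(rel) < 1e-12, "unchanged",
                ifelse(rel > 0, "expanded", "diminished"))
  per_face <- data.frame(face = seq_along(rel), area_before_um2 = a0,
                         area_after_um2 = a1, rel_change = rel, class = cls)
  structure(list(
    per_face = per_face,
    expanded = which(cls == "expanded"),
    diminished = which(cls == "diminished"),
    unchanged = which(cls == "unchanged"),
    n_components_expanded = count_face_components(relaxed, which(cls == "expanded")),
    n_components_diminished = count_face_components(relaxed, which(cls == "diminished")),
    area_before_um2 = sum(a0), area_after_um2 = sum(a1),
    theta = theta, xi = xi,
    relaxed = relaxed, pushed = pushed), class = "area_change_partition")
}

#' @export
print.area_change_partition <- function(x, ...) {
  cat(sprintf("Area-change partition (theta = %g deg, xi = %g):\n", x$theta, x$xi))
  cat(sprintf("  expanded %d faces (%d component(s)), diminished %d faces (%d component(s)), unchanged %d\n",
              length(x$expanded), x$n_components_expanded,
              length(x$diminished), x$n_components_diminished,
              length(x$unchanged)))
  cat(sprintf("  total area %0.2f -> %0.2f um^2\n",
              x$area_before_um2, x$area_after_um2))
  invisible(x)
}

## connected components of a face subset under shared-edge adjacency
count_face_components <- function(mesh, faces_idx) {
  if (length(faces_idx) == 0) return(0L)
  f <- mesh$faces[faces_idx, , drop = FALSE]
  m <- nrow(f)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_len(m), 3)
  ## union-find over faces sharing an edge key
  parent <- seq_len(m)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  sp <- split(fid, key)
  for (grp in sp) {
    if (length(grp) > 1) {
      r <- find(grp[1])
      for (g in grp[-1]) parent[find(g)] <- r
    }
  }
  length(unique(vapply(seq_len(m), find, integer(1))))
}

#' Curvature differences between relaxed and strained states
#'
#' Meshes the relaxed cell, evaluates the four curvatures per triangle, then
#' pushes the same mesh forward through M and evaluates the curvatures of
#' the transformed implicit surface at the pushed-forward triangles, giving
#' per-triangle differences (stretched minus relaxed) with preserved
#' triangle identity.
#'
#' @inheritParams curvature_profile
#' @return Data frame with per-face areas in both states and `dKG_um_2`,
#'   `dKM_um_1`, `dk1_um_1`, `dk2_um_1`.
#' @export
curvature_difference_map <- function(geom, theta = 0, xi = 1.75,
                                     target_edges = 12000,
                                     mode = "vertex_mean") {
  base <- implicit_rbc(geom)
  def <- affine_deformation(theta, xi)
  surf1 <- deform_surface(base, def)
  relaxed <- mesh_implicit(base, target_edges = target_edges)
  pushed <- push_forward(relaxed, def)
  f0 <- per_triangle_curvature(relaxed, base, mode = mode)
  f1 <- per_triangle_curvature(pushed, surf1, mode = mode)
  data.frame(face = f0$face,
             area_before_um2 = f0$area_um2, area_after_um2 = f1$area_um2,
             dKG_um_2 = f1$KG_um_2 - f0$KG_um_2,
             dKM_um_1 = f1$KM_um_1 - f0$KM_um_1,
             dk1_um_1 = f1$k1_um_1 - f0$k1_um_1,
             dk2_um_1 = f1$k2_um_1 - f0$k2_um_1)
}

#' Cytoskeleton tessellation arithmetic
#'
#' Closed-form geometry of a closed triangular tessellation with `n_edges`
#' struts: an equilateral triangle of side a has area a^2 sqrt(3)/4; on a
#' closed single-sheet surface each edge is shared by two triangles and each
#' triangle has three edges, so the triangle count is (2/3) n_edges. From
#' these follow the area of a fully-extended-strut triangle, the implied
#' total tessellation area and its ratio to the real membrane area, the mean
#' triangle area (and the equilateral side length back-computed from the
#' mean rounded to 4 decimal places in um^2, matching the customary rounding
#' of ~0.0016 um^2), and the number of triangles spanned by a membrane patch
#' of given area.
#'
#' @param n_edges number of edges (spectrin tetramers), default 121000.
#' @param extended_strut_nm fully extended strut length, nm (default 200).
#' @param total_area_um2 real membrane area, um^2 (default 128).
#' @param patch_area_um2 optional patch area, um^2 (e.g. 0.79 for a ~1 um
#'   diameter patch-clamp dome).
#' @return A list of class `cytoskeleton_report`.
#' @examples
#' cytoskeleton_report(patch_area_um2 = 0.79)
#' @export
cytoskeleton_report <- function(n_edges = 121000, extended_strut_nm = 200,
                                total_area_um2 = 128, patch_area_um2 = NULL) {
  stopifnot(n_edges > 0, extended_strut_nm > 0, total_area_um2 > 0)
  tri_count <- as.integer(round(2 * n_edges / 3))
  a_um <- extended_strut_nm / 1000
  ext_tri_area_um2 <- a_um^2 * sqrt(3) / 4
  implied_total_um2 <- tri_count * ext_tri_area_um2
  ratio <- implied_total_um2 / total_area_um2
  mean_tri_area_um2 <- total_area_um2 / tri_count
  mean_rounded <- round(mean_tri_area_um2, 4)
  side_nm <- sqrt(4 * mean_rounded / sqrt(3)) * 1000
  out <- list(n_edges = n_edges,
              total_area_um2 = total_area_um2,
              triangle_count = tri_count,
              extended_strut_nm = extended_strut_nm,
              extended_triangle_area_um2 = ext_tri_area_um2,
              implied_total_area_um2 = implied_total_um2,
              area_ratio = ratio,
              mean_triangle_area_um2 = mean_tri_area_um2,
              mean_triangle_area_rounded_um2 = mean_rounded,
              implied_side_nm = side_nm)
  if (!is.null(patch_area_um2)) {
    stopifnot(patch_area_um2 > 0)
    out$patch_area_um2 <- patch_area_um2
    out$triangles_per_patch <- tri_count * patch_area_um2 / total_area_um2
  }
  class(out) <- "cytoskeleton_report"
  out
}

#' @export
print.cytoskeleton_report <- function(x, ...) {
  cat(sprintf("Cytoskeleton tessellation (%d edges -> %d triangles):\n",
              x$n_edges, x$triangle_count))
  cat(sprintf("  fully extended strut %g nm -> triangle area %.4f um^2\n",
              x$extended_strut_nm, x$extended_triangle_area_um2))
  cat(sprintf("  implied tessellation area %.0f um^2 (%.1f x the real %g um^2)\n",
              x$implied_total_area_um2, x$area_ratio, x$total_area_um2))
  cat(sprintf("  mean triangle area %.5f um^2 (rounded %.4f) -> side %.1f nm\n",
              x$mean_triangle_area_um2, x$mean_triangle_area_rounded_um2,
              x$implied_side_nm))
  if (!is.null(x$triangles_per_patch))
    cat(sprintf("  %.0f triangles spanned by a %.2f um^2 patch\n",
                x$triangles_per_patch, x$patch_area_um2))
  invisible(x)
}
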