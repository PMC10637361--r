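#' Treatment record for one patient
#'
#' Holds the therapeutic sonication positions of one patient (world mm, in
#' AC-PC space) together with the computed standard coordinate.
#'
#' @param patient patient identifier.
#' @param points K x 3 matrix of treatment positions, world mm.
#' @param std_coord a [standard_coordinate()] result (or a length-3 point).
#' @return An object of class `tfus_treatment`.
#' @export
treatment_record <- function(patient, points, std_coord) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 1) stop("treatment record needs at least one point",
                             call. = FALSE)
  if (inherits(std_coord, "tfus_std_coord")) std_coord <- std_coord$point
  std_coord <- as.numeric(std_coord)
  stopifnot(length(std_coord) == 3L)
  structure(list(patient = patient, points = points, std_coord = std_coord),
            class = "tfus_treatment")
}

#' Filter sonications by peak temperature
#'
#' Only ablation points that reached a maximum average temperature of at
#' least the threshold (default 55 degrees C, the therapeutic criterion)
#' are retained; the comparison is inclusive.
#'
#' @param points K x 3 matrix of positions.
#' @param temps_c length-K vector of maximum average temperatures, degrees C.
#' @param threshold_c inclusive threshold, default 55.
#' @return the retained rows of `points`.
#' @export
filter_treatment_points <- function(points, temps_c, threshold_c = 55) {
  points <- matrix(as.numeric(points), ncol = 3)
  stopifnot(length(temps_c) == nrow(points))
  keep <- temps_c >= threshold_c
  if (!any(keep))
    stop("no treatment point reached the therapeutic temperature of ",
         threshold_c, " degrees C", call. = FALSE)
  points[keep, , drop = FALSE]
}

#' Mean deviation of treatment points from the standard coordinate
#'
#' `dev(j) = (1/K) sum_i || p(i,j) - stdCoord(j) ||`, the mean Euclidean
#' distance between a patient's K treatment points and the computed
#' standard coordinate.
#'
#' @param r a [treatment_record()].
#' @return deviation in mm.
#' @export
dev_mm <- function(r) {
  stopifnot(inherits(r, "tfus_treatment"))
  mean(sqrt(rowSums(sweep(r$points, 2, r$std_coord)^2)))
}

#' Mean lateral deviation from the 14 mm standard offset
#'
#' `xdev(j) = (1/K) sum_i | |p_x(i,j)| - 14 |`: the per-point lateral (x)
#' coordinate is compared against the defined 14 mm offset of the standard
#' coordinate from the AC-PC line. The magnitude of the lateral component
#' is used so the same formula serves left- (+x) and right-treated (-x)
#' patients.
#'
#' @param r a [treatment_record()] with points in AC-PC space.
#' @return lateral deviation in mm.
#' @export
xdev_mm <- function(r) {
  stopifnot(inherits(r, "tfus_treatment"))
  mean(abs(abs(r$points[, 1]) - LATERAL_OFFSET_MM))
}

#' Conditional cohort mean of a per-patient deviation
#'
#' `devcond = (1/M) sum_{j : cond(dev(j))} dev(j)` over the N-patient
#' cohort, where M patients satisfy the condition.
#'
#' @param records list of [treatment_record()] objects.
#' @param which `"dev"` (Euclidean) or `"xdev"` (lateral).
#' @param cond predicate on the per-patient statistic, e.g.
#'   `function(d) d >= 2`; default keeps every patient.
#' @return list with `mean` (mm), `sd`, `M` (patients satisfying the
#'   condition) and `N`.
#' @export
conditional_mean_dev <- function(records, which = c("dev", "xdev"),
                                 cond = function(d) rep(TRUE, length(d))) {
  which <- match.arg(which)
  f <- if (which == "dev") dev_mm else xdev_mm
  d <- vapply(records, f, 0)
  keep <- cond(d)
  if (length(keep) == 1L) keep <- rep(keep, length(d))
  M <- sum(keep)
  if (M == 0) stop("no patient satisfies the condition", call. = FALSE)
  list(mean = mean(d[keep]), sd = stats::sd(d[keep]), M = M,
       N = length(records))
}

#' Distance from a point to a thresholded bundle
#'
#' Zero when the point lies inside a suprathreshold voxel of the map;
#' otherwise the minimum Euclidean distance from the point to the centres
#' of suprathreshold voxels ("border distance" to the bundle).
#'
#' @param point world-mm position.
#' @param p a thresholded [probability_map()] (or any `tfus_probmap`).
#' @return distance in mm.
#' @export
point_to_bundle_distance <- function(point, p) {
  stopifnot(inherits(p, "tfus_probmap"))
  vol <- p$map
  supra <- which(vol$data > 0, arr.ind = TRUE) - 1
  if (nrow(supra) == 0)
    stop("probability map has no suprathreshold voxels", call. = FALSE)
  point <- as.numeric(point)
  v <- round(world_to_voxel(vol, point))
  d <- dim(vol$data)[1:3]
  if (all(v >= 0) && all(v <= d - 1) &&
      vol$data[v[1] + 1, v[2] + 1, v[3] + 1] > 0)
    return(0)
  centers <- voxel_to_world(vol, supra)
  sqrt(min(rowSums(sweep(centers, 2, point)^2)))
}

#' Centroid of a lesion mask
#'
#' @param mask binary [volume()] with at least one voxel set.
#' @return world-mm centroid of the masked-in voxel centres.
#' @export
lesion_center <- function(mask) {
  stopifnot(is_volume(mask))
  v <- which(mask$data > 0, arr.ind = TRUE) - 1
  if (nrow(v) == 0) stop("lesion mask is empty", call. = FALSE)
  colMeans(voxel_to_world(mask, v))
}

#' Dice overlap of two binary masks
#'
#' `2 |A n B| / (|A| + |B|)` on a common grid.
#'
#' @param a,b binary [volume()] masks on the same grid.
#' @return Dice score in [0, 1].
#' @export
dice <- function(a, b) {
  stopifnot(is_volume(a), is_volume(b))
  if (!all(dim(a$data)[1:3] == dim(b$data)[1:3]))
    stop("masks must share one grid", call. = FALSE)
  A <- a$data > 0; B <- b$data > 0
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0) stop("Dice undefined: both masks are empty", call. = FALSE)
  2 * sum(A & B) / (sa + sb)
}

#' Read a treatment log
#'
#' CSV dialect with columns `patient, x, y, z, temp_c` (positions in world
#' mm, AC-PC space; temperatures in degrees C).
#'
#' @param path CSV path.
#' @param std_coords named list (by patient id) of standard coordinates, or
#'   a single coordinate applied to all patients.
#' @param threshold_c therapeutic temperature threshold (inclusive).
#' @return list of [treatment_record()] objects, one per patient.
#' @export
load_treatment_log <- function(path, std_coords, threshold_c = 55) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "x", "y", "z", "temp_c")
  if (!all(need %in% names(df)))
    stop("treatment log must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- unique(df$patient)
  lapply(stats::setNames(ids, ids), function(id) {
    sub <- df[df$patient == id, ]
    pts <- filter_treatment_points(as.matrix(sub[, c("x", "y", "z")]),
                                   sub$temp_c, threshold_c)
    sc <- if (inherits(std_coords, "tfus_std_coord") ||
              (is.numeric(std_coords) && length(std_coords) == 3))
      std_coords else std_coords[[as.character(id)]]
    treatment_record(id, pts, sc)
  })
}

#' Per-bundle evaluation report
#'
#' For each thresholded bundle map, the distances to (a) the lesion
#' centre, (b) the mean treatment point, and (c) the standard coordinate.
#'
#' @param maps named list of thresholded [probability_map()] objects.
#' @param std_coord standard coordinate (point or `tfus_std_coord`).
#' @param treatment optional [treatment_record()].
#' @param lesion optional lesion mask [volume()].
#' @return data.frame with one row per bundle.
#' @export
evaluation_report <- function(maps, std_coord, treatment = NULL,
                              lesion = NULL) {
  if (inherits(std_coord, "tfus_std_coord")) std_coord <- std_coord$point
  lc <- if (!is.null(lesion)) lesion_center(lesion)
  mt <- if (!is.null(treatment)) colMeans(treatment$points)
  rows <- lapply(names(maps), function(nm) {
    p <- maps[[nm]]
    data.frame(
      bundle = nm,
      dist_to_lesion_center_mm =
        if (is.null(lc)) NA_real_ else point_to_bundle_distance(lc, p),
      dist_to_mean_treatment_mm =
        if (is.null(mt)) NA_real_ else point_to_bundle_distance(mt, p),
      dist_to_std_coord_mm = point_to_bundle_distance(std_coord, p))
  })
  do.call(rbind, rows)
}
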