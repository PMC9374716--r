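#' Cumulative dose-volume histogram
#'
#' Cumulative fractional volume receiving at least each dose level. The
#' curve starts at 1 for dose 0, is monotone non-increasing, and reaches 0
#' above the maximum dose. Statistics never depend on this binning: use
#' [dvhStat()] for D_x values.
#'
#' @param dose dose grid (Gy_w), any shape.
#' @param mask logical mask selecting the organ's voxels (default: all).
#' @param binWidth dose bin width in Gy_w (default 0.1).
#' @param organ organ name used in error messages.
#' @return data.frame of class `dvhCurve` with columns `dose` (bin edges)
#'   and `volume` (fraction of organ volume receiving >= dose).
#' @export
computeDVH <- function(dose, mask = NULL, binWidth = 0.1, organ = "organ") {
  if (binWidth <= 0) stop("binWidth must be > 0")
  d <- if (is.null(mask)) as.numeric(dose) else as.numeric(dose[mask])
  if (!length(d)) stop("empty mask for organ '", organ, "'")
  edges <- seq(0, max(d) + 2 * binWidth, by = binWidth)
  vol <- vapply(edges, function(e) mean(d >= e), numeric(1))
  structure(data.frame(dose = edges, volume = vol),
            class = c("dvhCurve", "data.frame"), organ = organ)
}

#' DVH dose statistic D_x
#'
#' D_x is the largest dose d such that at least x% of the organ's volume
#' receives >= d, evaluated on the raw voxel doses by order statistics
#' (dose to the hottest x% of volume; >=-threshold convention, no
#' interpolation between voxel doses). `x = 100` returns the minimum dose.
#'
#' @param doses voxel doses of one organ (Gy_w).
#' @param x percent of volume, in (0, 100].
#' @return D_x in Gy_w.
#' @examples
#' dvhStat(1:100, 50)  # 51
#' @export
dvhStat <- function(doses, x) {
  if (!length(doses)) stop("empty organ")
  if (any(x <= 0 | x > 100)) stop("x must be in (0, 100]")
  s <- sort(doses, decreasing = TRUE)
  n <- length(s)
  k <- as.integer(ceiling(n * x / 100 - 1e-9))
  s[pmin(pmax(k, 1L), n)]
}

#' Summary DVH statistics for one organ
#'
#' @param doses voxel doses of one organ (Gy_w).
#' @return named numeric: D_min, D_max, D_1, D_50, D_95, D_99 (Gy_w),
#'   satisfying D_min <= D_99 <= D_95 <= D_50 <= D_1 <= D_max.
#' @export
dvhStats <- function(doses) {
  if (!length(doses)) stop("empty organ")
  c(D_min = min(doses), D_max = max(doses),
    D_1 = dvhStat(doses, 1), D_50 = dvhStat(doses, 50),
    D_95 = dvhStat(doses, 95), D_99 = dvhStat(doses, 99))
}

#' Compare two dose plans organ by organ
#'
#' @param gridA,gridB dose grids (Gy_w) on identical meshes.
#' @param organs named list of logical masks, one per organ.
#' @return list: `table` (data.frame: organ, statistic, planA, planB,
#'   difference) and `difference` (voxelwise `gridB - gridA`).
#' @export
comparePlans <- function(gridA, gridB, organs) {
  da <- dim(gridA); db <- dim(gridB)
  if (!identical(da, db))
    stop("mesh mismatch: grid A is ", paste(da, collapse = "x"),
         ", grid B is ", paste(db, collapse = "x"))
  stats <- c("D_min", "D_max", "D_1", "D_50", "D_95", "D_99")
  tabs <- lapply(names(organs), function(org) {
    m <- organs[[org]]
    sa <- dvhStats(gridA[m])
    sb <- dvhStats(gridB[m])
    data.frame(organ = org, statistic = stats, planA = unname(sa[stats]),
               planB = unname(sb[stats]),
               difference = unname(sb[stats] - sa[stats]))
  })
  list(table = do.call(rbind, tabs), difference = gridB - gridA)
}
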