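#' Voxel-wise overlap of extreme deviations within groups
#'
#' For each group, the proportion of its subjects whose deviation map is
#' extreme at each voxel, with the peak proportion and its location.
#' Ties at the peak are all listed, ordered by lowest flat index.
#'
#' @param masks subjects x voxels logical matrix (one tail: e.g. the
#'   negative-extreme masks at a given threshold).
#' @param group factor/character group label per subject.
#' @param vs optional [voxel_space()] used to report peak grid
#'   coordinates (0-based).
#' @return A named list (one entry per group) of class `overlap_map`
#'   elements: `proportion` (per voxel), `n_subjects`, `peak_value`,
#'   `peak_index` (1-based column indices of all tied peaks, lowest
#'   first), `peak_coords` (0-based grid coordinates when `vs` given).
#' @export
overlap_map <- function(masks, group, vs = NULL) {
  stopifnot(is.matrix(masks), nrow(masks) == length(group))
  g <- if (is.factor(group)) group else factor(group)
  if (any(table(g) == 0))
    stop("empty group: ", paste(names(which(table(g) == 0)), collapse = ", "))
  out <- list()
  for (lv in levels(g)) {
    sel <- g == lv
    if (!sum(sel)) stop("empty group: ", lv)
    prop <- colMeans(masks[sel, , drop = FALSE])
    pk <- max(prop)
    idx <- which(prop == pk)
    coords <- if (!is.null(vs)) vs$coords[idx, , drop = FALSE] else NULL
    out[[lv]] <- structure(
      list(group = lv, proportion = prop, n_subjects = sum(sel),
           peak_value = pk, peak_index = idx, peak_coords = coords),
      class = "overlap_map")
  }
  out
}

#' @export
print.overlap_map <- function(x, ...) {
  cat(sprintf("overlap_map[%s]: n=%d, peak %.2f%% at %d voxel(s)\n",
              x$group, x$n_subjects, 100 * x$peak_value, length(x$peak_index)))
  invisible(x)
}

#' Sex-stratified overlap maps
#'
#' Recomputes [overlap_map()] within each stratum (typically sex) of
#' each group and reports the stratum peak values side by side. Empty
#' strata are skipped with a warning.
#'
#' @param masks subjects x voxels logical matrix.
#' @param group group label per subject.
#' @param stratum stratum label per subject (e.g. 0/1 sex codes); must
#'   be non-missing.
#' @param vs optional [voxel_space()].
#' @return A list with `maps` (nested list group -> stratum ->
#'   `overlap_map`) and `peaks` (data.frame of peak values per group and
#'   stratum).
#' @export
stratified_overlap <- function(masks, group, stratum, vs = NULL) {
  if (anyNA(stratum)) stop("stratum must be available for all subjects")
  g <- droplevels(factor(group))
  s <- factor(stratum)
  maps <- list()
  peaks <- data.frame(group = character(0), stratum = character(0),
                      n = integer(0), peak_value = numeric(0))
  for (lv in levels(g)) {
    maps[[lv]] <- list()
    for (sv in levels(s)) {
      sel <- g == lv & s == sv
      if (!sum(sel)) {
        warning(sprintf("stratum %s empty in group %s; skipped", sv, lv))
        next
      }
      om <- overlap_map(masks[sel, , drop = FALSE],
                        rep(lv, sum(sel)), vs = vs)[[lv]]
      maps[[lv]][[sv]] <- om
      peaks <- rbind(peaks, data.frame(group = lv, stratum = sv,
                                       n = om$n_subjects,
                                       peak_value = om$peak_value))
    }
  }
  list(maps = maps, peaks = peaks)
}
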