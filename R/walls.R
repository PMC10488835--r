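# Wall-segment stratification. Chambers are partitioned into anatomical
# walls; ventricles carry septal/lateral/posterior/anterior segments, atria
# additionally a superior segment, and the right atrium has no anterior
# segment (its anterior aspect is dominated by the tricuspid transition and
# is cut out in practice).

#' Allowed wall segments for a chamber
#'
#' @param chamber one of `"RA"`, `"LA"`, `"RV"`, `"LV"`.
#' @return character vector of permitted wall labels for that chamber.
#' @export
wall_scheme <- function(chamber) {
  switch(chamber,
    RA = c("septal", "lateral", "posterior", "superior"),
    LA = c("septal", "lateral", "posterior", "anterior", "superior"),
    RV = ,
    LV = c("septal", "lateral", "posterior", "anterior"),
    abort(sprintf("chamber must be one of %s", paste(CHAMBERS, collapse = ", ")))
  )
}

#' Assign circles to anatomical walls
#'
#' Labels each circle with a wall segment from the per-vertex `wall_label`
#' annotation of the map. Under the default `strict` rule a circle gets
#' label W only if every covered vertex is labeled W — i.e. the circle
#' lies entirely within one wall, so per-wall analyses use the same circles
#' a dedicated single-wall covering would; circles straddling a boundary
#' stay unassigned (`NA`) and participate only in whole-map analyses.
#' Under `majority` a circle takes the label of more than half of its
#' covered vertices.
#'
#' Labels outside the chamber's [wall_scheme()] (or `"unlabeled"`) never
#' produce an assignment. An entirely unlabeled map yields all-`NA`
#' assignments with a warning.
#'
#' @param patches tibble from [cover_map()].
#' @param map the [surface_map()] the patches came from.
#' @param rule `"strict"` (default) or `"majority"`.
#' @return `patches` with the `wall_assignment` column filled.
#' @export
assign_walls <- function(patches, map, rule = c("strict", "majority")) {
  rule <- match.arg(rule)
  if (all(map$wall_label == "unlabeled")) {
    warn("map carries no wall labels; all wall assignments are NA")
    patches$wall_assignment <- NA_character_
    return(patches)
  }
  allowed <- if (!is.null(map$meta$chamber)) wall_scheme(map$meta$chamber)
             else setdiff(WALL_LEVELS, "unlabeled")
  patches$wall_assignment <- vapply(patches$covered, function(ids) {
    labs <- map$wall_label[ids]
    if (length(labs) == 0) return(NA_character_)
    if (rule == "strict") {
      u <- unique(labs)
      if (length(u) == 1 && u %in% allowed) u else NA_character_
    } else {
      tab <- table(labs)
      top <- names(tab)[which.max(tab)]
      if (tab[top] > length(labs) / 2 && top %in% allowed) top
      else NA_character_
    }
  }, character(1))
  patches
}

#' Assign a single patch to a wall
#'
#' Single-patch convenience wrapper around the rule in [assign_walls()].
#'
#' @param patch a `circle_patch` from [clip_ball()].
#' @inheritParams assign_walls
#' @return a wall label or `NA_character_`.
#' @export
assign_wall <- function(patch, map, rule = c("strict", "majority")) {
  rule <- match.arg(rule)
  fake <- tibble(covered = list(patch$covered_vertex_ids),
                 wall_assignment = NA_character_)
  assign_walls(fake, map, rule = rule)$wall_assignment
}
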