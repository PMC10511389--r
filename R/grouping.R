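#' Group strain-field values by deformed tissue region
#'
#' Isolates the strain values lying within each region's deformed contour:
#' a voxel's value joins region `r` iff the voxel centre lies inside `r`'s
#' contour by the even-odd rule. Boundary ties are broken in favour of the
#' smallest region label; the `outer_excluded` region and voxels outside
#' every region are dropped. Strain field and regions must be in the same
#' (deformed, in vivo) coordinate frame and units.
#'
#' @param field a [strain_field()].
#' @param regions a [tissue_region_set()] in the deformed frame.
#' @param case_id,position optional provenance recorded with the result.
#' @return Object of class `region_strains`: named list `samples` of E1
#'   vectors, `counts`, and provenance.
#' @export
group_strains <- function(field, regions, case_id = NA_character_,
                          position = NA_character_) {
  labs <- sort(setdiff(names(regions$regions), "outer_excluded"))
  if (!length(labs)) stop("region set has no strain-carrying regions")
  ctr <- strain_field_centers(field)
  vals <- as.vector(field$values)
  ok <- !is.na(vals)
  assign <- rep(NA_integer_, length(vals))
  for (k in seq_along(labs)) {
    cand <- which(ok & is.na(assign))
    if (!length(cand)) break
    inside <- points_in_polygon(ctr[cand, , drop = FALSE],
                                region_polygon(regions, labs[k]))
    assign[cand[inside]] <- k
  }
  if (all(is.na(assign))) {
    stop("no strain voxels fall inside any region; frame mismatch suspected")
  }
  samples <- stats::setNames(lapply(seq_along(labs), function(k) {
    vals[which(assign == k)]
  }), labs)
  structure(list(samples = samples,
                 counts = vapply(samples, length, integer(1)),
                 case_id = case_id, position = position),
            class = "region_strains")
}

#' @export
print.region_strains <- function(x, ...) {
  cat("<region_strains>\n")
  for (l in names(x$samples)) {
    cat(sprintf("  %s: n=%d, median E1=%.4f\n", l, x$counts[[l]],
                median(x$samples[[l]])))
  }
  invisible(x)
}

#' Long-format data frame of grouped strains
#' @param rs a `region_strains`.
#' @return data.frame with case, position, region_label, E1.
#' @export
region_strains_table <- function(rs) {
  do.call(rbind, lapply(names(rs$samples), function(l) {
    if (!length(rs$samples[[l]])) return(NULL)
    data.frame(case = rs$case_id, position = rs$position,
               region_label = l, E1 = rs$samples[[l]])
  }))
}
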