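# Deterministic LI-RADS category inference over the three major features
# (APHE, washout, enhancing capsule) and lesion size, plus lesion-size
# measurement from a segmented component.

.lr_table <- list(
  # B1 = 0: columns indexed by B2+B3 (0, 1, 2); two size bins
  b0_small = c("LR3", "LR3", "LR4"),   # size < 20 mm
  b0_large = c("LR3", "LR4", "LR4"),   # size >= 20 mm
  # B1 = 1: three size bins
  b1_u10   = c("LR3", "LR4", "LR4"),       # size < 10 mm
  b1_10_19 = c("LR3", "LR4_OR_5", "LR5"),  # 10 <= size < 20 mm
  b1_ge20  = c("LR4", "LR5", "LR5")        # size >= 20 mm
)

#' Infer the LI-RADS category from major features and size
#'
#' Exact lookup of the LR-3/4/5 rule table over the APHE indicator `B1`, the
#' washout/capsule count `B2 + B3`, and the lesion-size bin. Size bins are
#' half-open: "<10" is \[0, 10), "10-19" is \[10, 20), ">=20" is \[20, Inf).
#' The one ambiguous cell (B1 = 1, 10-19 mm, one of washout/capsule) yields
#' `LR4_OR_5`, resolved by `policy`:
#' \describe{
#'   \item{prefer_washout_rule}{LR5 when washout is the present feature,
#'     LR4 when only the capsule is (default; mirrors the ACR v2018
#'     distinction the collapsed table loses).}
#'   \item{report_both}{keep `LR4_OR_5` unresolved.}
#'   \item{force_lr4, force_lr5}{always resolve to that category.}
#' }
#'
#' @param B1,B2,B3 Logical (or 0/1) presence of APHE, washout, capsule.
#' @param size_mm Lesion diameter in mm (> 0).
#' @param policy Ambiguity-resolution policy.
#' @return `list(value, resolved)`, both in
#'   `{"LR3","LR4","LR4_OR_5","LR5"}`; `resolved` never equals `LR4_OR_5`
#'   except under `report_both`.
#' @export
infer_lirads <- function(B1, B2, B3, size_mm,
                         policy = c("prefer_washout_rule", "report_both",
                                    "force_lr4", "force_lr5")) {
  policy <- match.arg(policy)
  stopifnot(length(B1) == 1, length(size_mm) == 1, size_mm > 0,
            B1 %in% c(0, 1), B2 %in% c(0, 1), B3 %in% c(0, 1))
  k <- as.integer(B2) + as.integer(B3) + 1L
  value <- if (!B1) {
    if (size_mm < 20) .lr_table$b0_small[k] else .lr_table$b0_large[k]
  } else {
    if (size_mm < 10) .lr_table$b1_u10[k]
    else if (size_mm < 20) .lr_table$b1_10_19[k]
    else .lr_table$b1_ge20[k]
  }
  resolved <- value
  if (value == "LR4_OR_5") {
    resolved <- switch(policy,
                       prefer_washout_rule = if (B2) "LR5" else "LR4",
                       report_both = "LR4_OR_5",
                       force_lr4 = "LR4",
                       force_lr5 = "LR5")
  }
  list(value = value, resolved = resolved)
}

#' Measure lesion size from a segmented component
#'
#' The size is the maximum in-plane Feret (caliper) diameter over axial
#' slices, in mm, plus one in-plane voxel (so a single-voxel lesion measures
#' one in-plane spacing unit rather than zero).
#'
#' @param component Either a logical/0-1 array (`rows x cols x slices` or a
#'   single slice matrix) or an integer matrix of voxel coordinates with
#'   columns `(y, x, z)`.
#' @param spacing_mm Voxel spacing `c(z, y, x)` in mm.
#' @return Size in mm.
#' @export
measure_lesion_size <- function(component, spacing_mm) {
  d <- dim(component)
  if (!is.null(d) && length(d) == 3) {
    coords <- which(component != 0, arr.ind = TRUE)
  } else if (is.matrix(component) && all(component %in% c(0, 1))) {
    coords <- which(component != 0, arr.ind = TRUE)
    if (nrow(coords) > 0) coords <- cbind(coords, 1L)
  } else if (is.matrix(component) && ncol(component) == 3) {
    coords <- component  # voxel coordinates (y, x, z)
  } else {
    stop("component must be a mask array or an (y, x, z) coordinate matrix")
  }
  if (is.null(dim(coords)) || nrow(coords) == 0)
    stop("empty component: cannot measure size")
  sy <- spacing_mm[2]; sx <- spacing_mm[3]
  feret <- 0
  for (z in unique(coords[, 3])) {
    pts <- coords[coords[, 3] == z, 1:2, drop = FALSE]
    pts <- cbind(pts[, 1] * sy, pts[, 2] * sx)
    if (nrow(pts) > 3) {
      hull <- grDevices::chull(pts)
      pts <- pts[hull, , drop = FALSE]
    }
    if (nrow(pts) >= 2) {
      d2 <- as.matrix(stats::dist(pts))
      feret <- max(feret, max(d2))
    }
  }
  feret + mean(c(sy, sx))
}

#' Score all detected lesions of a study
#'
#' Combines feature calls and measured sizes into LI-RADS categories via the
#' rule engine; one row per lesion, deterministic given its inputs.
#'
#' @param features Data frame with columns `lesion_id, p_aphe, p_washout,
#'   p_capsule, B1, B2, B3, size_mm` (as produced by the characterization
#'   stage plus size measurement).
#' @param policy Ambiguity policy passed to [infer_lirads()].
#' @return The input data frame with `category` (raw rule-table value) and
#'   `resolved` columns appended; zero detected lesions give a zero-row
#'   table.
#' @export
score_study <- function(features, policy = "prefer_washout_rule") {
  need <- c("lesion_id", "B1", "B2", "B3", "size_mm")
  if (!all(need %in% names(features)))
    stop("features must contain columns: ", paste(need, collapse = ", "))
  n <- nrow(features)
  category <- character(n); resolved <- character(n)
  for (i in seq_len(n)) {
    r <- infer_lirads(features$B1[i], features$B2[i], features$B3[i],
                      features$size_mm[i], policy = policy)
    category[i] <- r$value; resolved[i] <- r$resolved
  }
  features$category <- category
  features$resolved <- resolved
  features
}
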