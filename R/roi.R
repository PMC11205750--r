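#' Equal-volume sphere region of interest around a biopsy site
#'
#' Converts a pathology tissue volume into a sphere of equal volume centered
#' on the recorded biopsy coordinate, and enumerates the voxels whose
#' centers lie inside it.  The radius follows the equal-volume formula
#' \eqn{r = (3V / 4\pi)^{1/3}} with \eqn{V} in mm^3; a voxel at 0-based
#' index \eqn{(i,j,k)} has its center at \eqn{(i s_1, j s_2, k s_3)} mm and
#' belongs to the ROI iff its Euclidean distance to the center voxel's
#' center is at most \eqn{r}.  A sphere that would extend past the grid is
#' an error (never silently clipped), reporting the overflow per axis.
#'
#' @param center 0-based voxel index triple of the biopsy location.
#' @param volume_cm3 tissue volume in cm^3 (> 0).
#' @param spacing_mm voxel spacing in mm (length 1 or 3).
#' @param grid_shape grid dimensions in voxels (length 3).
#' @return An object of class `"sphere_roi"` with fields `center`,
#'   `radius_mm`, `volume_cm3`, `spacing_mm`, `voxel_indices` (an n x 3
#'   matrix of 0-based indices) and `n_voxels`.
#' @examples
#' # a 1 mm^3 tissue sample at 1 mm spacing covers just the center voxel
#' sphere_roi(c(16, 16, 16), 0.001, 1, c(32, 32, 32))$n_voxels
#' @export
sphere_roi <- function(center, volume_cm3, spacing_mm, grid_shape) {
  stopifnot(length(center) == 3, length(grid_shape) == 3)
  if (!(volume_cm3 > 0)) stop("'volume_cm3' must be > 0")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3)
  stopifnot(length(spacing_mm) == 3, all(spacing_mm > 0))
  center <- as.numeric(center)
  grid_shape <- as.integer(grid_shape)
  if (any(center < 0 | center > grid_shape - 1L))
    stop("'center' must lie inside the grid")

  radius_mm <- (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  r_vox <- radius_mm / spacing_mm
  lo <- ceiling(center - r_vox)
  hi <- floor(center + r_vox)

  under <- pmax(0 - lo, 0)
  over <- pmax(hi - (grid_shape - 1L), 0)
  if (any(under > 0) || any(over > 0)) {
    ax <- c("i", "j", "k")
    msg <- paste(sprintf("axis %s: %d voxel(s) below 0, %d above %d",
                         ax, under, over, grid_shape - 1L)[under > 0 | over > 0],
                 collapse = "; ")
    stop(sprintf(paste0("sphere of radius %.3f mm around (%s) exceeds the ",
                        "%s grid: %s"),
                 radius_mm, paste(center, collapse = ", "),
                 paste(grid_shape, collapse = "x"), msg))
  }

  g <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                             k = lo[3]:hi[3]))
  d2 <- (g[, 1] - center[1])^2 * spacing_mm[1]^2 +
        (g[, 2] - center[2])^2 * spacing_mm[2]^2 +
        (g[, 3] - center[3])^2 * spacing_mm[3]^2
  keep <- d2 <= radius_mm^2
  idx <- g[keep, , drop = FALSE]
  storage.mode(idx) <- "integer"
  structure(list(center = center, radius_mm = radius_mm,
                 volume_cm3 = volume_cm3, spacing_mm = spacing_mm,
                 voxel_indices = idx, n_voxels = nrow(idx)),
            class = "sphere_roi")
}

#' @export
print.sphere_roi <- function(x, ...) {
  cat(sprintf("Sphere ROI: %g cm^3 -> radius %.3f mm, %d voxels at (%s)\n",
              x$volume_cm3, x$radius_mm, x$n_voxels,
              paste(x$center, collapse = ", ")))
  invisible(x)
}

#' Normalize a volume to its NAWM mean signal
#'
#' Divides every voxel by the scalar mean signal inside the normal-appearing
#' white matter mask, making the volume dimensionless with an in-mask mean
#' of exactly 1.  The operation is scale-invariant and idempotent.
#'
#' @param volume 3-D numeric array.
#' @param nawm_mask logical or 0/1 array of the same dimensions; must be
#'   non-empty.
#' @return The normalized array.
#' @export
nawm_normalize <- function(volume, nawm_mask) {
  if (!identical(dim(volume), dim(nawm_mask)))
    stop("volume and NAWM mask dimensions differ")
  m <- .nawm_mean(volume, nawm_mask)
  volume / m
}

.nawm_mean <- function(volume, nawm_mask) {
  sel <- as.logical(nawm_mask)
  if (!any(sel)) stop("NAWM mask is empty")
  m <- mean(volume[sel])
  if (!is.finite(m) || m <= 0)
    stop(sprintf("NAWM mean signal is %s; input looks corrupt", format(m)))
  m
}

.resolve_contrast <- function(patient, contrast) {
  if (contrast %in% names(patient$volumes)) return(contrast)
  alias <- patient$contrast_alias
  if (!is.null(alias) && contrast %in% names(alias) &&
      alias[[contrast]] %in% names(patient$volumes))
    return(alias[[contrast]])
  stop(sprintf("patient %s lacks contrast %s", patient$patient_id, contrast))
}

#' Build the voxel-wise feature matrix for one gene
#'
#' Concatenates, over patients, one row per biopsy-ROI voxel carrying the
#' NAWM-normalized signal of each selected contrast and the patient's
#' binary mutation status for the target gene.  Multiple biopsies per
#' patient contribute the union of their sphere voxels (overlapping voxels
#' appear once).  Contrast columns follow the cohort's canonical contrast
#' ordering.  A per-patient `contrast_alias` map (e.g. `c("T2W" =
#' "T2W-CE")`) lets a substituted acquisition stand in for a canonical
#' contrast.
#'
#' @param patients an `"mri_cohort"` or a list of patient datasets.
#' @param contrasts contrast subset to extract.
#' @param gene target gene name (must be present in every genotype).
#' @param normalize `"per-contrast"` (default: each contrast divided by its
#'   own NAWM mean) or `"reference"` (every contrast divided by the NAWM
#'   mean of `reference_contrast`, the single-scalar literal variant).
#' @param reference_contrast contrast supplying the scalar for
#'   `normalize = "reference"`.
#' @return A data frame with columns `patient_id`, `i`, `j`, `k`, one
#'   normalized-signal column per contrast, and the response `y`.
#' @export
build_feature_matrix <- function(patients, contrasts, gene,
                                 normalize = c("per-contrast", "reference"),
                                 reference_contrast = "T1W-CE") {
  normalize <- match.arg(normalize)
  if (inherits(patients, "mri_cohort")) patients <- patients$patients
  if (!length(patients)) stop("no patients supplied")
  canonical <- names(patients[[1]]$volumes)
  contrasts <- contrasts[order(match(contrasts, canonical))]

  blocks <- lapply(patients, function(pat) {
    if (!(gene %in% names(pat$genotype)))
      stop(sprintf("gene %s absent from genotype of patient %s",
                   gene, pat$patient_id))
    rois <- lapply(pat$biopsies, function(b)
      sphere_roi(b$center, b$volume_cm3, pat$spacing_mm, pat$shape))
    idx <- unique(do.call(rbind, lapply(rois, `[[`, "voxel_indices")))
    sub <- idx + 1L  # 0-based indices -> R subscripts

    if (normalize == "reference") {
      ref_name <- .resolve_contrast(pat, reference_contrast)
      ref_mean <- .nawm_mean(pat$volumes[[ref_name]], pat$nawm_mask)
    }
    sig <- vapply(contrasts, function(con) {
      vol <- pat$volumes[[.resolve_contrast(pat, con)]]
      m <- if (normalize == "reference") ref_mean
           else .nawm_mean(vol, pat$nawm_mask)
      vol[sub] / m
    }, numeric(nrow(sub)))
    sig <- matrix(sig, nrow = nrow(sub),
                  dimnames = list(NULL, contrasts))
    out <- data.frame(patient_id = pat$patient_id,
                      i = idx[, 1], j = idx[, 2], k = idx[, 3],
                      check.names = FALSE)
    out[contrasts] <- sig
    out$y <- as.numeric(pat$genotype[[gene]])
    out
  })
  res <- do.call(rbind, blocks)
  rownames(res) <- NULL
  res
}
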