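#' Canonical contrast and gene panels
#'
#' The five clinical MR contrasts and five glioma driver genes used as
#' defaults throughout the package, in canonical order.
#'
#' @return Character vector.
#' @export
mri_contrasts <- function() c("T1W", "T1W-CE", "T2W", "T2W-FLAIR", "ADC")

#' @rdname mri_contrasts
#' @export
glioma_genes <- function() c("IDH1", "TP53", "EGFR", "PIK3CA", "NF1")

#' Planted effect-size pattern for the default glioma panel
#'
#' A standardized mean-shift matrix (genes x contrasts) encoding which
#' contrasts carry signal for which mutation in the synthetic cohort.  Each
#' mutated gene shifts the tumor-voxel mean of its associated contrasts by
#' `d` voxel-noise standard deviations: IDH1 and TP53 on T2W-FLAIR and ADC,
#' EGFR on T2W and ADC, PIK3CA on T1W and T1W-CE, NF1 on T1W and ADC.
#'
#' @param d standardized effect size applied to every associated
#'   (gene, contrast) pair (default 1).
#' @param genes,contrasts panel names (defaults: [glioma_genes()],
#'   [mri_contrasts()]).
#' @return Numeric matrix with `genes` rows and `contrasts` columns.
#' @export
glioma_effect_sizes <- function(d = 1, genes = glioma_genes(),
                                contrasts = mri_contrasts()) {
  es <- matrix(0, length(genes), length(contrasts),
               dimnames = list(genes, contrasts))
  pairs <- list(IDH1 = c("T2W-FLAIR", "ADC"),
                TP53 = c("T2W-FLAIR", "ADC"),
                EGFR = c("T2W", "ADC"),
                PIK3CA = c("T1W", "T1W-CE"),
                NF1 = c("T1W", "ADC"))
  for (g in intersect(names(pairs), genes))
    es[g, intersect(pairs[[g]], contrasts)] <- d
  es
}

.expand_named <- function(x, names, what) {
  if (length(x) == 1L && is.null(names(x)))
    return(setNames(rep(as.numeric(x), length(names)), names))
  if (is.null(names(x)) && length(x) == length(names))
    return(setNames(as.numeric(x), names))
  if (!all(names %in% names(x)))
    stop(sprintf("'%s' must name every entry of %s", what,
                 paste(names, collapse = ", ")))
  setNames(as.numeric(x[names]), names)
}

#' Configuration of a synthetic multiparametric MRI cohort
#'
#' Describes a cohort of glioma patients with co-registered contrast
#' volumes, one NAWM region per patient, one or more biopsy spheres, and a
#' Bernoulli genotype per gene.  Voxel signals are homoscedastic Gaussians:
#' outside any biopsy sphere (including the NAWM cuboid) contrast `c` is
#' `Normal(nawm_mean[c], voxel_noise_sd[c])`; inside a sphere the mean is
#' shifted by `sum_g genotype[g] * effect_size[g, c] * voxel_noise_sd[c]`,
#' so a single mutated gene with standardized effect `d` separates tumor
#' from reference signal by exactly `d` noise SDs (binormal AUC
#' `pnorm(d / sqrt(2))`, see [planted_auc()]).  Effects of multiple mutated
#' genes add linearly.
#'
#' @param n_patients number of patients (>= 1).
#' @param contrasts ordered contrast names.
#' @param genes ordered gene names.
#' @param mutation_prevalence per-gene mutation probability in \[0, 1\]
#'   (scalar or named per gene).
#' @param effect_size genes x contrasts matrix of standardized mean shifts
#'   (units of voxel-noise SD); `NULL` for all-zero (null cohort).
#' @param voxel_noise_sd signal SD per contrast (scalar or named), > 0.
#' @param nawm_mean baseline signal per contrast (scalar or named), > 0.
#' @param biopsy_volume_cm3 tissue volume of each biopsy sample (cm^3).
#' @param n_biopsies biopsy samples per patient.
#' @param volume_shape grid dimensions in voxels (length 3).
#' @param voxel_spacing_mm per-axis voxel spacing in mm (length 1 or 3).
#' @param seed master RNG seed; each patient draws from an independent
#'   stream derived from it, so adding patients never perturbs existing
#'   ones.
#' @return An object of class `"cohort_config"`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 10,
                          contrasts = mri_contrasts(),
                          genes = glioma_genes(),
                          mutation_prevalence = 0.5,
                          effect_size = NULL,
                          voxel_noise_sd = 10,
                          nawm_mean = 100,
                          biopsy_volume_cm3 = 4.8,
                          n_biopsies = 1,
                          volume_shape = c(64, 64, 64),
                          voxel_spacing_mm = c(1, 1, 1),
                          seed = 1) {
  stopifnot(n_patients >= 1, length(contrasts) >= 1, length(genes) >= 1,
            n_biopsies >= 1, biopsy_volume_cm3 > 0,
            length(volume_shape) == 3, all(volume_shape >= 2))
  if (anyDuplicated(contrasts)) stop("duplicate contrast names")
  if (anyDuplicated(genes)) stop("duplicate gene names")
  if (length(voxel_spacing_mm) == 1L)
    voxel_spacing_mm <- rep(voxel_spacing_mm, 3)
  stopifnot(length(voxel_spacing_mm) == 3, all(voxel_spacing_mm > 0))

  prevalence <- .expand_named(mutation_prevalence, genes,
                              "mutation_prevalence")
  if (any(prevalence < 0 | prevalence > 1))
    stop("mutation_prevalence must lie in [0, 1]")
  sd_c <- .expand_named(voxel_noise_sd, contrasts, "voxel_noise_sd")
  if (any(sd_c <= 0)) stop("voxel_noise_sd must be > 0")
  mu_c <- .expand_named(nawm_mean, contrasts, "nawm_mean")
  if (any(mu_c <= 0)) stop("nawm_mean must be > 0")

  if (is.null(effect_size)) {
    effect_size <- matrix(0, length(genes), length(contrasts),
                          dimnames = list(genes, contrasts))
  } else {
    effect_size <- as.matrix(effect_size)
    if (is.null(dimnames(effect_size)) &&
        all(dim(effect_size) == c(length(genes), length(contrasts))))
      dimnames(effect_size) <- list(genes, contrasts)
    if (!all(genes %in% rownames(effect_size)) ||
        !all(contrasts %in% colnames(effect_size)))
      stop("effect_size must be a genes x contrasts matrix")
    effect_size <- effect_size[genes, contrasts, drop = FALSE]
  }

  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    contrasts = contrasts, genes = genes,
    mutation_prevalence = prevalence,
    effect_size = effect_size,
    voxel_noise_sd = sd_c, nawm_mean = mu_c,
    biopsy_volume_cm3 = biopsy_volume_cm3,
    n_biopsies = as.integer(n_biopsies),
    volume_shape = as.integer(volume_shape),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    seed = as.integer(seed)
  ), class = "cohort_config")

  # geometry must admit every biopsy sphere; fail here, not mid-generation
  .biopsy_centers(cfg)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic mpMRI cohort config: %d patients, %d contrasts, %d genes\n",
              x$n_patients, length(x$contrasts), length(x$genes)))
  cat(sprintf("  grid %s voxels at %s mm; biopsy %g cm^3 x %d; seed %d\n",
              paste(x$volume_shape, collapse = "x"),
              paste(format(x$voxel_spacing_mm), collapse = "x"),
              x$biopsy_volume_cm3, x$n_biopsies, x$seed))
  nz <- sum(x$effect_size != 0)
  cat(sprintf("  planted effects: %d non-zero (gene, contrast) pairs\n", nz))
  invisible(x)
}

# Deterministic biopsy-sphere placement: first sample at the grid center,
# further samples spaced along axis 1.  Errors (via sphere_roi) if any
# sphere would leave the grid.
.biopsy_centers <- function(config) {
  dims <- config$volume_shape
  sp <- config$voxel_spacing_mm
  r_mm <- (3 * config$biopsy_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  center <- floor((dims - 1) / 2)
  step <- ceiling(2 * r_mm / sp[1]) + 2L
  centers <- vector("list", config$n_biopsies)
  for (b in seq_len(config$n_biopsies)) {
    k <- b %/% 2L
    off <- if (b %% 2L == 0L) k * step else -((b - 1L) %/% 2L) * step
    ctr <- center + c(off, 0L, 0L)
    # validates geometry; the ROI itself is recomputed where needed
    sphere_roi(ctr, config$biopsy_volume_cm3, sp, dims)
    centers[[b]] <- ctr
  }
  centers
}

# NAWM reference region: fixed cuboid in a low-index corner, well away from
# the centrally placed biopsy spheres.
.nawm_mask <- function(dims) {
  lo <- pmax(floor(dims * 0.06), 1L)
  hi <- pmax(floor(dims * 0.22), lo + 1L)
  mask <- array(FALSE, dims)
  mask[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
       (lo[3] + 1):(hi[3] + 1)] <- TRUE
  mask
}

.patient_subseeds <- function(config) {
  set.seed(config$seed)
  sample.int(.Machine$integer.max - 1L, config$n_patients)
}

#' Preview the genotypes a configuration will generate
#'
#' Draws only the Bernoulli genotype matrix of [generate_cohort()] — the
#' genotype is the first draw of each patient's RNG sub-stream, so the
#' result is identical to the genotypes of the full cohort at a fraction
#' of the cost.  Useful for screening configurations for gene balance
#' before generating volumes (mirroring the exclusion of genes with too
#' few mutated or wild-type patients from the analysis).
#'
#' @param config a [cohort_config()].
#' @return Integer patients x genes matrix of 0/1 genotypes.
#' @export
cohort_genotypes <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must be created by cohort_config()")
  subseeds <- .patient_subseeds(config)
  geno <- vapply(seq_len(config$n_patients), function(p) {
    set.seed(subseeds[p])
    rbinom(length(config$genes), 1L, config$mutation_prevalence)
  }, integer(length(config$genes)))
  geno <- t(matrix(geno, nrow = length(config$genes)))
  dimnames(geno) <- list(sprintf("P%02d", seq_len(config$n_patients)),
                         config$genes)
  geno
}

#' Generate a synthetic patient cohort
#'
#' Draws the cohort described by a [cohort_config()]: per patient, a
#' Bernoulli genotype per gene, one Gaussian signal volume per contrast with
#' the configured planted mean shifts inside every biopsy sphere, a fixed
#' cuboid NAWM mask, and the biopsy records.  Each patient consumes an
#' independent RNG sub-stream derived from the master seed, so the same
#' config reproduces the cohort bit-exactly and adding patients leaves
#' existing patients unchanged.
#'
#' @param config a [cohort_config()].
#' @return An object of class `"mri_cohort"`: a list with elements
#'   `patients` (list of per-patient datasets, each holding `patient_id`,
#'   `volumes`, `nawm_mask`, `biopsies`, `genotype`, `shape`, `spacing_mm`)
#'   and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 2,
#'   volume_shape = c(32, 32, 32), biopsy_volume_cm3 = 0.5, seed = 7))
#' names(coh$patients[[1]]$volumes)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must be created by cohort_config()")
  dims <- config$volume_shape
  sp <- config$voxel_spacing_mm
  centers <- .biopsy_centers(config)
  mask <- .nawm_mask(dims)
  rois <- lapply(centers, sphere_roi, volume_cm3 = config$biopsy_volume_cm3,
                 spacing_mm = sp, grid_shape = dims)
  roi_union <- unique(do.call(rbind, lapply(rois, `[[`, "voxel_indices")))
  roi_lin <- 1L + roi_union[, 1] + dims[1] * (roi_union[, 2] +
               dims[2] * roi_union[, 3])

  subseeds <- .patient_subseeds(config)

  patients <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    set.seed(subseeds[p])
    genotype <- setNames(rbinom(length(config$genes), 1L,
                                config$mutation_prevalence),
                         config$genes)
    volumes <- setNames(vector("list", length(config$contrasts)),
                        config$contrasts)
    for (con in config$contrasts) {
      vol <- array(rnorm(prod(dims), mean = config$nawm_mean[con],
                         sd = config$voxel_noise_sd[con]), dims)
      shift <- sum(genotype * config$effect_size[, con]) *
        config$voxel_noise_sd[con]
      if (shift != 0) vol[roi_lin] <- vol[roi_lin] + shift
      volumes[[con]] <- vol
    }
    patients[[p]] <- structure(list(
      patient_id = sprintf("P%02d", p),
      volumes = volumes,
      nawm_mask = mask,
      biopsies = lapply(centers, function(ctr)
        list(center = as.integer(ctr),
             volume_cm3 = config$biopsy_volume_cm3)),
      genotype = genotype,
      shape = dims, spacing_mm = sp
    ), class = "patient_dataset")
  }
  structure(list(patients = patients, config = config),
            class = "mri_cohort")
}

#' @export
print.mri_cohort <- function(x, ...) {
  cat(sprintf("Synthetic mpMRI cohort: %d patients, contrasts %s\n",
              length(x$patients),
              paste(x$config$contrasts, collapse = ", ")))
  geno <- do.call(rbind, lapply(x$patients, `[[`, "genotype"))
  cat("Mutated patients per gene:\n")
  print(colSums(geno))
  invisible(x)
}

#' Closed-form AUC of a planted standardized effect
#'
#' For two homoscedastic Gaussian voxel populations whose means differ by
#' `d` standard deviations, the probability that a random tumor voxel
#' exceeds a random reference voxel (the binormal AUC) is
#' \eqn{\Phi(d/\sqrt{2})}.  This is the oracle against which recovered
#' pooled AUCs are checked.
#'
#' @param d standardized effect size (>= 0; vectorized).
#' @return AUC values in \[0.5, 1).
#' @examples
#' planted_auc(c(0, 0.5, 1, 2))
#' @export
planted_auc <- function(d) {
  if (!is.numeric(d) || anyNA(d) || any(d < 0))
    stop("'d' must be non-negative; direction is a configuration concern")
  pnorm(d / sqrt(2))
}

.config_to_list <- function(config) {
  es <- config$effect_size
  idx <- which(es != 0, arr.ind = TRUE)
  list(
    n_patients = config$n_patients,
    contrasts = config$contrasts,
    genes = config$genes,
    mutation_prevalence = as.list(config$mutation_prevalence),
    effect_size = if (nrow(idx)) data.frame(
      gene = rownames(es)[idx[, 1]],
      contrast = colnames(es)[idx[, 2]],
      d = es[idx]) else data.frame(gene = character(0),
                                   contrast = character(0), d = numeric(0)),
    voxel_noise_sd = as.list(config$voxel_noise_sd),
    nawm_mean = as.list(config$nawm_mean),
    biopsy_volume_cm3 = config$biopsy_volume_cm3,
    n_biopsies = config$n_biopsies,
    volume_shape = config$volume_shape,
    voxel_spacing_mm = config$voxel_spacing_mm,
    seed = config$seed)
}

.config_from_list <- function(x) {
  es <- matrix(0, length(x$genes), length(x$contrasts),
               dimnames = list(x$genes, x$contrasts))
  est <- as.data.frame(x$effect_size)
  if (nrow(est))
    es[cbind(est$gene, est$contrast)] <- est$d
  cohort_config(
    n_patients = x$n_patients, contrasts = unlist(x$contrasts),
    genes = unlist(x$genes),
    mutation_prevalence = unlist(x$mutation_prevalence),
    effect_size = es, voxel_noise_sd = unlist(x$voxel_noise_sd),
    nawm_mean = unlist(x$nawm_mean),
    biopsy_volume_cm3 = x$biopsy_volume_cm3, n_biopsies = x$n_biopsies,
    volume_shape = unlist(x$volume_shape),
    voxel_spacing_mm = unlist(x$voxel_spacing_mm), seed = x$seed)
}

#' Write a cohort to disk as NIfTI + CSV + JSON manifest
#'
#' Writes one NIfTI volume per contrast per patient, one NIfTI NAWM mask per
#' patient, a patient x gene genotype CSV (0/1), a biopsy CSV (patient,
#' sample, i, j, k, volume_cm3; 0-based voxel indices) and a JSON manifest
#' listing every file with its MD5 checksum and the generating config.
#'
#' @param cohort an [generate_cohort()] result.
#' @param directory output directory (created if needed).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, directory) {
  if (!inherits(cohort, "mri_cohort")) stop("'cohort' must be an mri_cohort")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  ref_shape <- cohort$patients[[1]]$shape
  ref_sp <- cohort$patients[[1]]$spacing_mm
  for (pat in cohort$patients) {
    if (!identical(pat$shape, ref_shape) ||
        !identical(pat$spacing_mm, ref_sp))
      stop("shape/spacing mismatch across patients at write time")
    for (con in names(pat$volumes)) {
      if (!identical(dim(pat$volumes[[con]]), as.integer(pat$shape)))
        stop(sprintf("volume %s of %s does not match the declared shape",
                     con, pat$patient_id))
      f <- file.path(directory,
                     sprintf("%s_%s.nii.gz", pat$patient_id, con))
      img <- RNifti::asNifti(pat$volumes[[con]])
      RNifti::pixdim(img) <- pat$spacing_mm
      RNifti::writeNifti(img, f)
      files <- c(files, f)
    }
    f <- file.path(directory, sprintf("%s_NAWM.nii.gz", pat$patient_id))
    img <- RNifti::asNifti(array(as.integer(pat$nawm_mask), pat$shape))
    RNifti::pixdim(img) <- pat$spacing_mm
    RNifti::writeNifti(img, f)
    files <- c(files, f)
  }

  geno <- do.call(rbind, lapply(cohort$patients, `[[`, "genotype"))
  geno_df <- data.frame(patient = vapply(cohort$patients, `[[`, "",
                                         "patient_id"),
                        geno, check.names = FALSE)
  f_geno <- file.path(directory, "genotypes.csv")
  write.csv(geno_df, f_geno, row.names = FALSE)

  biop <- do.call(rbind, lapply(cohort$patients, function(pat) {
    do.call(rbind, lapply(seq_along(pat$biopsies), function(b) {
      bx <- pat$biopsies[[b]]
      data.frame(patient = pat$patient_id, sample = b,
                 i = bx$center[1], j = bx$center[2], k = bx$center[3],
                 volume_cm3 = bx$volume_cm3)
    }))
  }))
  f_biop <- file.path(directory, "biopsies.csv")
  write.csv(biop, f_biop, row.names = FALSE)

  files <- c(files, f_geno, f_biop)
  manifest <- list(
    format = "radiogam-cohort",
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))),
    config = .config_to_list(cohort$config))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory directory containing `manifest.json` and the files it
#'   lists.
#' @return An `"mri_cohort"` object.
#' @export
read_cohort <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", directory)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "radiogam-cohort"))
    stop("not a radiogam cohort directory: ", directory)
  config <- .config_from_list(manifest$config)

  geno <- read.csv(file.path(directory, "genotypes.csv"),
                   check.names = FALSE)
  biop <- read.csv(file.path(directory, "biopsies.csv"))
  patients <- vector("list", nrow(geno))
  for (p in seq_len(nrow(geno))) {
    pid <- geno$patient[p]
    volumes <- setNames(lapply(config$contrasts, function(con) {
      img <- RNifti::readNifti(file.path(directory,
                                         sprintf("%s_%s.nii.gz", pid, con)))
      array(as.numeric(img), dim(img))
    }), config$contrasts)
    msk <- RNifti::readNifti(file.path(directory,
                                       sprintf("%s_NAWM.nii.gz", pid)))
    bx <- biop[biop$patient == pid, , drop = FALSE]
    patients[[p]] <- structure(list(
      patient_id = pid,
      volumes = volumes,
      nawm_mask = array(as.integer(msk) > 0L, dim(msk)),
      biopsies = lapply(seq_len(nrow(bx)), function(b)
        list(center = as.integer(c(bx$i[b], bx$j[b], bx$k[b])),
             volume_cm3 = bx$volume_cm3[b])),
      genotype = setNames(as.integer(geno[p, config$genes]), config$genes),
      shape = config$volume_shape,
      spacing_mm = config$voxel_spacing_mm
    ), class = "patient_dataset")
  }
  structure(list(patients = patients, config = config),
            class = "mri_cohort")
}
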