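## Seeded synthetic CT-lesion cohort generator.
##
## Emulates tumor-centered 128x128 grayscale patches whose texture statistics
## differ by PD-1 class: a shared smooth background, a central "tumor" disk,
## and, for positive patients, an oriented band-pass texture inside the disk
## whose amplitude scales with `effect_size`. Optional survival times follow
## exponential distributions whose hazard ratio is `survival_link`.

TEXTURE_AMP <- 0.10   # texture amplitude per unit effect size
BACKGROUND_AMP <- 0.06
DISK_RADIUS <- 40
DISK_LEVEL <- 0.25
BASE_LEVEL <- 0.35

#' The planted class-discriminative texture template
#'
#' Oriented sinusoidal band-pass pattern masked by the tumor disk; PD-1
#' positive patches carry `effect_size * TEXTURE_AMP` times this template.
#' Exposed so tests and figures can compare recovered class differences
#' against the ground-truth signal.
#'
#' @param size Patch side length (default 128).
#' @return `size x size` matrix in \[-1, 1\].
#' @export
texture_template <- function(size = 128L) {
  cy <- (size + 1) / 2
  r <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  phi <- pi / 5
  pattern <- sin(2 * pi * ((r - cy) * cos(phi) + (cc - cy) * sin(phi)) / 8)
  mask <- disk_mask(size, DISK_RADIUS)
  pattern * mask
}

## soft-edged disk mask centered in the patch
disk_mask <- function(size, radius) {
  cy <- (size + 1) / 2
  r <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  d <- sqrt((r - cy)^2 + (cc - cy)^2)
  1 / (1 + exp((d - radius) / 1.5))
}

## smooth random background: low-resolution gaussian field upsampled
random_background <- function(size, amp) {
  coarse <- matrix(stats::rnorm(64), 8, 8)
  amp * resize_bilinear(coarse, size, size)
}

#' Simulate survival records with a class-linked hazard
#'
#' Exponential event times with baseline median 30 months; the positive
#' group's hazard is `hazard_ratio` times the baseline. Administrative
#' censoring at a uniform 24-60 month follow-up.
#'
#' @param labels Integer vector of group labels (0/1).
#' @param hazard_ratio Hazard ratio of group 1 versus group 0.
#' @return `data.frame(time, event)`; time in months, event 1 = observed.
#' @export
simulate_survival <- function(labels, hazard_ratio = 2.0) {
  stopifnot(all(labels %in% c(0, 1)), hazard_ratio > 0)
  n <- length(labels)
  rate <- log(2) / 30 * hazard_ratio^labels
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 24, 60)
  data.frame(time = pmax(pmin(t_event, t_cens), 1e-3),
             event = as.integer(t_event <= t_cens))
}

#' Generate a synthetic CT-lesion cohort
#'
#' Produces a cohort of labeled 128x128 patches: multiple images per patient,
#' class prevalence near the clinical cohort's (~21% positive), and optional
#' survival times whose hazard ratio between classes is `survival_link`.
#' With `effect_size = 0` the class-conditional image distributions are
#' identical. Fully reproducible given `seed`.
#'
#' @param n_patients Number of patients.
#' @param images_per_patient Integer range `c(lo, hi)` (or a single count) of
#'   images drawn per patient.
#' @param prevalence Fraction of PD-1-positive patients, in (0, 1).
#' @param effect_size Class-separation strength of the planted texture
#'   (0 = no signal; 1 = texture amplitude 0.10 on the \[0,1\] intensity scale).
#' @param noise_sd Per-pixel gaussian noise standard deviation.
#' @param survival_link Hazard ratio of the positive class (1 = no survival
#'   difference); `NULL` disables survival simulation.
#' @param size Patch side length (default 128).
#' @param seed Integer seed.
#' @return Object of class `"rtn_cohort"`: list with `images` (array
#'   `size x size x n_images`) and `meta` (data.frame: `image_id`,
#'   `patient_id`, `label`, and `time`/`event` when survival is simulated).
#' @export
generate_synthetic_cohort <- function(n_patients = 93L,
                                      images_per_patient = c(2L, 4L),
                                      prevalence = 0.213,
                                      effect_size = 1.0,
                                      noise_sd = 0.05,
                                      survival_link = 2.0,
                                      size = 128L,
                                      seed = 1L) {
  if (n_patients < 2) stop("need at least 2 patients")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(survival_link) && survival_link <= 0) stop("survival_link must be > 0")
  set.seed(seed)
  ipp <- rep(range(images_per_patient), length.out = 2)
  labels <- stats::rbinom(n_patients, 1, prevalence)
  n_img_pat <- if (ipp[1] == ipp[2]) rep(ipp[1], n_patients) else
    sample(ipp[1]:ipp[2], n_patients, replace = TRUE)
  template <- texture_template(size)
  disk <- disk_mask(size, DISK_RADIUS)
  n_total <- sum(n_img_pat)
  images <- array(0, dim = c(size, size, n_total))
  meta <- data.frame(image_id = sprintf("img%05d", seq_len(n_total)),
                     patient_id = rep(sprintf("pt%04d", seq_len(n_patients)), n_img_pat),
                     label = rep(labels, n_img_pat),
                     stringsAsFactors = FALSE)
  k <- 0L
  for (p in seq_len(n_patients)) {
    for (j in seq_len(n_img_pat[p])) {
      k <- k + 1L
      img <- BASE_LEVEL + DISK_LEVEL * disk +
        random_background(size, BACKGROUND_AMP) +
        labels[p] * effect_size * TEXTURE_AMP * template +
        matrix(stats::rnorm(size * size, sd = noise_sd), size, size)
      images[, , k] <- pmin(pmax(img, 0), 1)
    }
  }
  if (!is.null(survival_link)) {
    surv <- simulate_survival(labels, survival_link)
    meta$time <- rep(surv$time, n_img_pat)
    meta$event <- rep(surv$event, n_img_pat)
  }
  structure(list(images = images, meta = meta, seed = seed),
            class = "rtn_cohort")
}

#' @export
print.rtn_cohort <- function(x, ...) {
  m <- x$meta
  pat <- !duplicated(m$patient_id)
  cat("Synthetic/loaded CT-lesion cohort\n")
  cat(sprintf("  %d images, %d patients, %.1f%% PD-1-positive (patient level)\n",
              nrow(m), sum(pat), 100 * mean(m$label[pat])))
  cat(sprintf("  patch size %d x %d; survival: %s\n",
              dim(x$images)[1], dim(x$images)[2],
              if (is.null(m$time)) "absent" else "present"))
  invisible(x)
}

#' Write a cohort to disk as PNG images plus a CSV manifest
#'
#' @param cohort An `rtn_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- cohort$meta
  m$path <- file.path(dir, paste0(m$image_id, ".png"))
  for (i in seq_len(nrow(m)))
    png::writePNG(cohort$images[, , i], m$path[i])
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(m, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest CSV
#'
#' The manifest must contain `path`, `patient_id`, `label` and may contain
#' `time`/`event` survival columns. PNG or TIFF (8/16-bit) images are read
#' and converted to single-channel matrices.
#'
#' @param manifest Path to the manifest CSV (paths are resolved relative to
#'   the manifest's directory when not absolute).
#' @param normalize If `TRUE`, min-max stretch each image to \[0, 1\] (use for
#'   raw windowed patches). Default `FALSE`: intensities are mapped by bit
#'   depth only, so writing and re-reading a cohort round-trips.
#' @return An `rtn_cohort`.
#' @export
read_cohort <- function(manifest, normalize = FALSE) {
  m <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("path", "patient_id", "label")
  if (!all(need %in% names(m))) stop("manifest needs columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path, file.path(base, basename(m$path)))
  imgs <- lapply(paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    x <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(p) else png::readPNG(p)
    if (length(dim(x)) == 3) x <- x[, , 1]
    if (normalize) normalize01(x) else x
  })
  size <- nrow(imgs[[1]])
  images <- array(unlist(imgs), dim = c(size, ncol(imgs[[1]]), length(imgs)))
  if (is.null(m$image_id)) m$image_id <- sprintf("img%05d", seq_len(nrow(m)))
  structure(list(images = images, meta = m), class = "rtn_cohort")
}
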