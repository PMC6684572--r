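#' Specification of a synthetic accession cohort
#'
#' Describes one accession/genotype for the synthetic GSA generator:
#' per-LR angles are drawn from a normal distribution truncated to
#' \[0, 180\] degrees, with the replicate structure of the phenotyping
#' experiments (plates of seedlings, tens to hundreds of lateral roots per
#' plate).
#'
#' @param label accession label.
#' @param mean_angle,sd_angle location and spread of the (untruncated)
#'   normal in degrees. The defaults (62, 15) put roughly 60% of angles in
#'   the 51-70 degree reference category.
#' @param n_plates number of plates (default 5).
#' @param seedlings_per_plate seedlings per plate (default 16).
#' @param lrs_per_plate integer range; each plate's LR count is drawn
#'   uniformly from it (default c(30, 120)).
#' @param seed integer seed; one seed fully determines the dataset.
#' @return An object of class `accession_spec`.
#' @export
accession_spec <- function(label, mean_angle = 62, sd_angle = 15,
                           n_plates = 5L, seedlings_per_plate = 16L,
                           lrs_per_plate = c(30L, 120L), seed = 1L) {
  if (!is.character(label) || length(label) != 1)
    stop("label must be a single string")
  if (mean_angle <= 0 || mean_angle >= 180)
    stop("mean_angle must lie in (0, 180)")
  if (sd_angle <= 0) stop("sd_angle must be positive")
  if (n_plates < 1 || seedlings_per_plate < 1 || any(lrs_per_plate < 1))
    stop("all counts must be >= 1")
  if (length(lrs_per_plate) != 2 || lrs_per_plate[1] > lrs_per_plate[2])
    stop("lrs_per_plate must be an increasing integer pair")
  structure(list(label = label, mean_angle = mean_angle,
                 sd_angle = sd_angle, n_plates = as.integer(n_plates),
                 seedlings_per_plate = as.integer(seedlings_per_plate),
                 lrs_per_plate = as.integer(lrs_per_plate),
                 seed = as.integer(seed)),
            class = "accession_spec")
}

# inverse-CDF sampler for the normal truncated to [lo, hi]
rtrunc_normal <- function(n, mean, sd, lo = 0, hi = 180) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-6)
    stop("degenerate truncation: almost no normal mass inside [",
         lo, ", ", hi, "]")
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic per-LR angle dataset for one accession
#'
#' Draws plate-structured GSA records: each plate receives a uniformly
#' drawn LR count from the spec's range, each LR a seedling id and an angle
#' from the truncated normal. The spec's seed fully determines the dataset
#' (the caller's RNG state is left untouched).
#'
#' @param spec an [accession_spec()].
#' @return Data frame with columns `angle_deg`, `plate_id`, `seedling_id`,
#'   `label`.
#' @export
generate_accession_angles <- function(spec) {
  stopifnot(inherits(spec, "accession_spec"))
  with_local_seed(spec$seed, {
    plates <- lapply(seq_len(spec$n_plates), function(p) {
      rng <- spec$lrs_per_plate
      n <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
      data.frame(
        angle_deg = rtrunc_normal(n, spec$mean_angle, spec$sd_angle),
        plate_id = sprintf("%s_P%d", spec$label, p),
        seedling_id = sample.int(spec$seedlings_per_plate, n,
                                 replace = TRUE),
        label = spec$label)
    })
    do.call(rbind, plates)
  })
}

#' Generate a multi-accession panel with allele annotations
#'
#' Concatenates the datasets of several accession specs and annotates each
#' record with its accession's allele, emulating panels of hypo- and
#' hyper-responsive accessions carrying alternative alleles.
#'
#' @param specs list of at least two [accession_spec()] objects with
#'   distinct labels.
#' @param allele_map optional named character vector mapping labels to
#'   allele codes (e.g. `c(Col0 = "T", Acc1 = "G")`).
#' @return Data frame with columns `angle_deg`, `plate_id`, `seedling_id`,
#'   `label` and (when `allele_map` is given) `allele`.
#' @export
generate_panel <- function(specs, allele_map = NULL) {
  if (length(specs) < 2) stop("need at least 2 accession specs")
  labels <- vapply(specs, function(s) s$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate accession labels: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  out <- do.call(rbind, lapply(specs, generate_accession_angles))
  if (!is.null(allele_map)) {
    if (!all(labels %in% names(allele_map)))
      stop("allele_map is missing labels: ",
           paste(setdiff(labels, names(allele_map)), collapse = ", "))
    out$allele <- unname(allele_map[out$label])
  }
  out
}
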