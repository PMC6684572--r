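#' Bending (set-point) angle of a simulated tissue
#'
#' Angle in degrees between the organ's base-to-tip axis — the centroid of
#' the fixed base vertex column to the centroid of the tip-most vertex
#' column — and the gravity vector. 0 deg means the organ points straight
#' down, 90 deg horizontal.
#'
#' @param tissue an `lr_tissue` with at least 2 cell columns.
#' @param gravity unit 2-vector; defaults to the tissue's stored gravity
#'   direction (0, -1).
#' @return Angle in degrees, in \[0, 180\].
#' @export
bending_angle <- function(tissue, gravity = tissue$gravity) {
  stopifnot(inherits(tissue, "lr_tissue"))
  if (tissue$n_cols < 2) stop("need at least 2 cell columns")
  base <- colMeans(tissue$pos[tissue$v_col == tissue$n_cols, , drop = FALSE])
  tip <- colMeans(tissue$pos[tissue$v_col == 0L, , drop = FALSE])
  v <- tip - base
  nv <- sqrt(sum(v * v))
  ng <- sqrt(sum(gravity * gravity))
  if (nv < 1e-12) stop("degenerate geometry: zero-length organ axis")
  ct <- sum(v * gravity) / (nv * ng)
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}

#' Upper/lower flank cell-length fold change
#'
#' Ratio of the mean current axial cell length in the top flank row to that
#' in the bottom flank row, over elongation-zone cells.
#'
#' @param tissue an `lr_tissue`.
#' @return Fold change (top / bottom).
#' @export
flank_fold_change <- function(tissue) {
  stopifnot(inherits(tissue, "lr_tissue"))
  cl <- cell_axial_lengths(tissue)
  ez <- tissue$zone == "elongation"
  top <- ez & tissue$cell_row == tissue$n_rows - 1L
  bot <- ez & tissue$cell_row == 0L
  if (!any(top) || !any(bot))
    stop("empty elongation zone on a flank row")
  mean(cl[top]) / mean(cl[bot])
}

gsa_breaks <- c(0, 30, 50, 70, 90, 110, 180)
gsa_labels <- c("0-30", "31-50", "51-70", "71-90", "91-110", "111-180")

# validate an angle table: angle_deg in [0,180], plate_id present
check_gsa_dataset <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0)
    stop("need a non-empty data frame of angle records")
  if (!all(c("angle_deg", "plate_id") %in% names(data)))
    stop("angle records need 'angle_deg' and 'plate_id' columns")
  bad <- which(!is.finite(data$angle_deg) | data$angle_deg < 0 |
                 data$angle_deg > 180)
  if (length(bad))
    stop("angle outside [0, 180] in record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(data)
}

#' Bin GSA measurements into the six standard angle categories
#'
#' Assigns each angle to one of the categories 0-30, 31-50, 51-70, 71-90,
#' 91-110 and 111-180 degrees using half-open intervals (0,30\], (30,50\],
#' ..., (110,180\] (an angle of exactly 0 goes to the first bin), computes
#' per-plate percentages of incidence, and summarises them as mean and SEM
#' across plates — the plate is the replicate unit, so SEM = sd / sqrt(n
#' plates).
#'
#' @param data data frame with columns `angle_deg` (degrees in \[0, 180\])
#'   and `plate_id`; additional columns (`seedling_id`, `label`) are
#'   allowed.
#' @return An object of class `gsa_distribution`: list with the per-plate
#'   count and percentage tables (plates x 6), `mean` and `sem` percentage
#'   vectors, `n_plates` and `n_records`.
#' @export
bin_gsa <- function(data) {
  check_gsa_dataset(data)
  bin <- cut(data$angle_deg, breaks = gsa_breaks, labels = gsa_labels,
             right = TRUE, include.lowest = TRUE)
  counts <- table(plate = data$plate_id, category = bin)
  counts <- unclass(counts)[, gsa_labels, drop = FALSE]
  pct <- 100 * counts / rowSums(counts)
  structure(list(breaks = gsa_breaks, labels = gsa_labels,
                 counts = counts, per_plate = pct,
                 mean = colMeans(pct),
                 sem = apply(pct, 2, stats::sd) / sqrt(nrow(pct)),
                 n_plates = nrow(pct), n_records = nrow(data)),
            class = "gsa_distribution")
}

#' @export
print.gsa_distribution <- function(x, digits = 1, ...) {
  cat(sprintf("GSA category distribution (%d LRs on %d plates)\n",
              x$n_records, x$n_plates))
  tab <- rbind(`mean %` = round(x$mean, digits),
               `SEM %` = round(x$sem, digits))
  print(tab)
  invisible(x)
}

#' Bar plot of a GSA category distribution
#'
#' @param x a `gsa_distribution`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.gsa_distribution <- function(x, ...) {
  mid <- graphics::barplot(x$mean, names.arg = x$labels,
                           ylim = c(0, max(x$mean + x$sem) * 1.15),
                           xlab = "GSA category (deg)",
                           ylab = "incidence (%)", ...)
  graphics::arrows(mid, x$mean - x$sem, mid, x$mean + x$sem,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test for angle distributions
#'
#' Computes `D = sup_x |ECDF_a(x) - ECDF_b(x)|` exactly over the pooled
#' sample points, and the asymptotic two-sided p-value from the Kolmogorov
#' distribution evaluated at `sqrt(n_eff) * D` with effective sample size
#' `n_eff = n1 * n2 / (n1 + n2)`.
#'
#' @param a,b numeric samples (angles in degrees, or any values).
#' @return An object of classes `ks_angle_test` and `htest` with fields
#'   `statistic` (D), `p.value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(a, b) {
  dn <- paste(deparse1(substitute(a)), "vs", deparse1(substitute(b)))
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1 || length(b) < 1 || anyNA(a) || anyNA(b))
    stop("both samples must be non-empty and free of missing values")
  pooled <- sort(unique(c(a, b)))
  Fa <- vapply(pooled, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(pooled, function(x) mean(b <= x), numeric(1))
  D <- max(abs(Fa - Fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  p <- kolmogorov_sf(sqrt(n_eff) * D)
  structure(list(statistic = c(D = D), p.value = p,
                 n1 = length(a), n2 = length(b),
                 alternative = "two-sided",
                 method = "Two-sample Kolmogorov-Smirnov test (asymptotic)",
                 data.name = dn),
            class = c("ks_angle_test", "htest"))
}

# survival function of the Kolmogorov distribution:
# Q(lambda) = 2 * sum_{k>=1} (-1)^{k-1} exp(-2 k^2 lambda^2)
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Compare the GSA distributions of two groups
#'
#' Pools the angles of each label, runs the two-sample KS test and returns
#' both per-group category distributions — the standard genotype-vs-control
#' comparison of the phenotyping pipeline.
#'
#' @param data data frame with `angle_deg`, `plate_id` and a grouping
#'   column.
#' @param label_a,label_b the two group labels to compare.
#' @param label_col name of the grouping column (default `"label"`).
#' @return An object of class `gsa_comparison`: list with `ks` (the
#'   [ks_two_sample()] result) and `dist_a`, `dist_b` (the
#'   [bin_gsa()] distributions).
#' @export
compare_groups <- function(data, label_a, label_b, label_col = "label") {
  check_gsa_dataset(data)
  if (!label_col %in% names(data))
    stop("no '", label_col, "' column in the dataset")
  lab <- data[[label_col]]
  for (l in c(label_a, label_b))
    if (!any(lab == l)) stop("label not present: ", l)
  da <- data[lab == label_a, , drop = FALSE]
  db <- data[lab == label_b, , drop = FALSE]
  ks <- ks_two_sample(da$angle_deg, db$angle_deg)
  ks$data.name <- paste(label_a, "vs", label_b)
  structure(list(label_a = label_a, label_b = label_b, ks = ks,
                 dist_a = bin_gsa(da), dist_b = bin_gsa(db)),
            class = "gsa_comparison")
}

#' @export
print.gsa_comparison <- function(x, ...) {
  cat(sprintf("GSA comparison: %s (n=%d) vs %s (n=%d)\n", x$label_a,
              x$ks$n1, x$label_b, x$ks$n2))
  cat(sprintf("  KS D = %.4f, p = %.4g\n", x$ks$statistic, x$ks$p.value))
  invisible(x)
}

#' Student's t contrast of mean GSA between two groups
#'
#' Convenience wrapper around [stats::t.test()] (equal-variance Student's
#' t) for contrasting mean angles by allele or genotype.
#'
#' @inheritParams compare_groups
#' @return An `htest` object.
#' @export
gsa_t_test <- function(data, label_a, label_b, label_col = "label") {
  check_gsa_dataset(data)
  lab <- data[[label_col]]
  for (l in c(label_a, label_b))
    if (!any(lab == l)) stop("label not present: ", l)
  stats::t.test(data$angle_deg[lab == label_a],
                data$angle_deg[lab == label_b], var.equal = TRUE)
}

#' Read / write per-LR angle tables
#'
#' Delimited text with header columns `angle_deg`, `plate_id`,
#' `seedling_id`, `label` (comma-separated for `.csv`, tab-separated for
#' `.tsv`/`.txt`).
#'
#' @param path file path.
#' @return `read_gsa_table()` returns the validated data frame.
#' @export
read_gsa_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  check_gsa_dataset(data)
  data
}

#' @rdname read_gsa_table
#' @param data angle data frame to write.
#' @export
write_gsa_table <- function(data, path) {
  check_gsa_dataset(data)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(data, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
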