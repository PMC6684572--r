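# helper: a grid whose base->tip axis is rotated by `phi` degrees below
# the horizontal (tip at minimum x before rotation about the base centroid)
rotated_tissue <- function(phi_deg) {
  tis <- build_lr_grid(4, 2, 10, 10)
  base <- colMeans(tis$pos[tis$v_col == tis$n_cols, ])
  # the base->tip axis points in -x, so lowering the tip by phi_deg
  # corresponds to a mathematically positive rotation of the mesh
  phi <- -phi_deg * pi / 180
  R <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2,
              byrow = TRUE)
  tis$pos <- sweep(sweep(tis$pos, 2, base) %*% t(R), 2, base, `+`)
  tis
}

test_that("bending angle measures the base-to-tip axis against gravity", {
  expect_equal(bending_angle(rotated_tissue(0)), 90)    # horizontal organ
  expect_equal(bending_angle(rotated_tissue(-45)), 45)  # unit-slope diagonal
  expect_equal(bending_angle(rotated_tissue(-90)), 0)   # tip straight down
  expect_equal(bending_angle(rotated_tissue(45)), 135)  # bent upward
})

test_that("bending angle is translation-invariant and reflection-equivariant", {
  tis <- rotated_tissue(-30)
  a0 <- bending_angle(tis)
  tis$pos <- sweep(tis$pos, 2, c(123, -45), `+`)
  expect_equal(bending_angle(tis), a0)
  # reflect about the gravity axis (x -> -x): angle to gravity is preserved
  tis2 <- rotated_tissue(-30)
  tis2$pos[, 1] <- -tis2$pos[, 1]
  expect_equal(bending_angle(tis2), a0)

  degenerate <- rotated_tissue(0)
  degenerate$pos[, ] <- 0
  expect_error(bending_angle(degenerate), "degenerate")
})

test_that("flank fold change compares mean axial lengths of the flank rows", {
  tis <- assign_zones(build_lr_grid(4, 2, 10, 10), 0)
  # stretch the top vertex row: top cells average (10 + 24)/2 = 17 um
  top <- tis$v_row == tis$n_rows
  tis$pos[top, 1] <- tis$pos[top, 1] * 2.4
  expect_equal(flank_fold_change(tis), 17 / 10)
  # with the middle row stretched alike the top cells average 24 um
  mid <- tis$v_row == 1
  tis$pos[mid, 1] <- tis$pos[mid, 1] * 2.4
  expect_equal(flank_fold_change(tis), 24 / 17)
  tis$zone[] <- "tip"
  expect_error(flank_fold_change(tis), "elongation zone")
})

test_that("angle binning matches the six standard categories and conventions", {
  d <- data.frame(angle_deg = c(60, 65, 55, 80, 100), plate_id = "p1")
  dist <- bin_gsa(d)
  expect_equal(unname(dist$mean),
               c(0, 0, 60, 20, 20, 0))
  expect_equal(dist$labels,
               c("0-30", "31-50", "51-70", "71-90", "91-110", "111-180"))

  # boundary convention: half-open on the left, 0 joins the first bin
  b <- bin_gsa(data.frame(angle_deg = c(70, 70.1, 30, 30.5, 0, 180),
                          plate_id = "p"))
  expect_equal(unname(b$counts[1, ]), c(2, 1, 1, 1, 0, 1))

  expect_error(bin_gsa(data.frame(angle_deg = 190, plate_id = "p")),
               "record")
  expect_error(bin_gsa(data.frame(angle_deg = numeric(0),
                                  plate_id = character(0))), "non-empty")
})

test_that("binning conserves counts and percentages; SEM uses plates", {
  set.seed(99)
  d <- data.frame(
    angle_deg = runif(400, 0, 180),
    plate_id = rep(sprintf("p%d", 1:5), length.out = 400))
  dist <- bin_gsa(d)
  expect_equal(sum(dist$counts), 400)
  expect_equal(unname(rowSums(dist$counts)),
               as.vector(table(d$plate_id)[rownames(dist$counts)]))
  expect_equal(unname(rowSums(dist$per_plate)), rep(100, 5),
               tolerance = 1e-9)
  expect_equal(dist$n_plates, 5)

  # five identical plates: zero variance across the replicate unit
  one <- data.frame(angle_deg = rep(c(40, 60, 95), 4), plate_id = "x")
  five <- do.call(rbind, lapply(1:5, function(i)
    transform(one, plate_id = sprintf("x%d", i))))
  expect_equal(unname(bin_gsa(five)$sem), rep(0, 6))
})

test_that("the KS statistic matches hand-derived and brute-force values", {
  expect_equal(unname(ks_two_sample(1:5, 1:5)$statistic), 0)
  expect_equal(ks_two_sample(1:5, 1:5)$p.value, 1)
  expect_equal(unname(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$statistic), 1)
  expect_equal(unname(ks_two_sample(1:4, 3:6)$statistic), 0.5)

  # exhaustive-style check against the O(n^2) oracle on a 4-value alphabet
  set.seed(123)
  for (i in 1:300) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    a <- sample(1:4, n1, replace = TRUE)
    b <- sample(1:4, n2, replace = TRUE)
    expect_identical(unname(ks_two_sample(a, b)$statistic),
                     brute_force_ks_D(a, b))
  }
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("KS statistic and asymptotic p agree with the stats reference", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(60, 60, 20); b <- rnorm(80, 70, 15)
    ours <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(unname(ours$statistic), unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("group comparison pools labels and detects planted shifts", {
  base <- generate_accession_angles(
    accession_spec("ctrl", mean_angle = 60, sd_angle = 12,
                   lrs_per_plate = c(40, 40), seed = 21))
  shifted <- generate_accession_angles(
    accession_spec("shift", mean_angle = 80, sd_angle = 12,
                   lrs_per_plate = c(40, 40), seed = 22))
  d <- rbind(base, shifted)

  same <- compare_groups(rbind(base, transform(base, label = "copy")),
                         "ctrl", "copy")
  expect_equal(unname(same$ks$statistic), 0)

  cmp <- compare_groups(d, "ctrl", "shift")
  expect_gt(unname(cmp$ks$statistic), 0)
  expect_lt(cmp$ks$p.value, 0.05)
  expect_s3_class(cmp$dist_a, "gsa_distribution")
  expect_equal(cmp$ks$n1, nrow(base))
  expect_error(compare_groups(d, "ctrl", "absent"), "not present")

  tt <- gsa_t_test(d, "ctrl", "shift")
  expect_s3_class(tt, "htest")
  expect_lt(tt$p.value, 0.01)
})

test_that("angle tables round-trip through CSV and TSV", {
  d <- generate_accession_angles(accession_spec("acc", seed = 4))
  for (ext in c(".csv", ".tsv")) {
    path <- tempfile(fileext = ext)
    write_gsa_table(d, path)
    back <- read_gsa_table(path)
    expect_equal(back$angle_deg, d$angle_deg)
    expect_identical(back$plate_id, d$plate_id)
    unlink(path)
  }
})
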