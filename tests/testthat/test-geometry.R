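test_that("width inversion round-trips the capsule area relation", {
  set.seed(42)
  w <- runif(200, 0.2, 3)
  l <- w * runif(200, 1, 10)
  w_back <- width_from_area_length(capsule_area(l, w), l)
  expect_equal(w_back, w, tolerance = 1e-9)
  # known roots
  expect_equal(width_from_area_length(pi / 4, 1), 1, tolerance = 1e-12)
  expect_equal(width_from_area_length(3 + pi / 4, 4), 1, tolerance = 1e-12)
})

test_that("inadmissible measurements yield NA widths and are split off", {
  # area beyond any capsule of that length (max is the disk, w = L)
  expect_true(is.na(width_from_area_length(capsule_area(2, 2) * 1.2, 2)))
  expect_true(is.na(width_from_area_length(10, 1)))  # negative discriminant
  cells <- data.frame(cell_id = c("a", "b"), condition = "x", time_h = 0,
                      projected_area_um2 = c(capsule_area(3, 1), 50),
                      length_um = c(3, 1))
  dd <- derive_dimensions(cells)
  expect_equal(nrow(dd$cells), 1)
  expect_equal(dd$rejected$cell_id, "b")
  expect_equal(dd$rejected$reason, "no_admissible_width")
})

test_that("surface and volume match the capsule formulas and sphere limit", {
  sv <- surface_and_volume(4, 1)
  expect_equal(sv$surface_um2, 4 * pi, tolerance = 1e-12)
  expect_equal(sv$volume_um3, 11 * pi / 12, tolerance = 1e-12)
  # sphere limit L = w: V = pi w^3 / 6, A = pi w^2, projected area pi w^2/4
  sph <- surface_and_volume(1, 1)
  expect_equal(sph$volume_um3, pi / 6, tolerance = 1e-14)
  expect_equal(sph$surface_um2, pi, tolerance = 1e-14)
  expect_equal(capsule_area(1, 1), pi / 4, tolerance = 1e-14)
  expect_error(surface_and_volume(1, 1.5), "width exceeds length")
})

test_that("capsule volume agrees with Monte-Carlo voxel integration", {
  # rejection-sample points in the bounding box of an L=3, w=1 capsule
  set.seed(7)
  n <- 4e5
  x <- runif(n, 0, 3); y <- runif(n, -0.5, 0.5); z <- runif(n, -0.5, 0.5)
  ax <- pmin(pmax(x, 0.5), 2.5)           # clamp to the cylinder axis
  inside <- (x - ax)^2 + y^2 + z^2 <= 0.25
  v_mc <- mean(inside) * 3
  v_analytic <- surface_and_volume(3, 1)$volume_um3
  expect_lt(abs(v_mc - v_analytic) / v_analytic, 0.005)
})

test_that("volume is strictly monotone in length and width", {
  w <- seq(0.3, 1.5, by = 0.1)
  v_w <- surface_and_volume(2, w)$volume_um3
  expect_true(all(diff(v_w) > 0))
  l <- seq(1, 8, by = 0.5)
  v_l <- surface_and_volume(l, 0.9)$volume_um3
  expect_true(all(diff(v_l) > 0))
})

test_that("hard filters apply the four strict criteria in order", {
  mk <- function(w, l, a) data.frame(width_um = w, length_um = l,
                                     projected_area_um2 = a)
  expect_equal(nrow(apply_hard_filters(mk(0.5, 2, 1.0))$kept), 1)
  r <- apply_hard_filters(mk(0.5, 4, 1.9))       # aspect = 8
  expect_equal(nrow(r$kept), 0)
  expect_equal(r$rejection_log$criterion, "aspect")
  # boundary values are excluded (strict inequalities)
  expect_equal(nrow(apply_hard_filters(mk(0.35, 2, 1))$kept), 0)
  expect_equal(nrow(apply_hard_filters(mk(0.5, 1.05, 1))$kept), 0)
  expect_equal(nrow(apply_hard_filters(mk(0.36, 2, 0.73))$kept), 0)
  # first-failing criterion in the listed order wins the log
  r2 <- apply_hard_filters(mk(0.3, 0.5, 0.1))    # fails everything
  expect_equal(r2$rejection_log$criterion, "width")
})

test_that("kept set matches brute-force evaluation of the four predicates", {
  cells <- derive_dimensions(random_cells(500, seed = 9))$cells
  res <- apply_hard_filters(cells)
  brute <- with(cells, width_um > 0.35 & length_um > 1.05 & length_um < 10 &
                  length_um / width_um > 1 & length_um / width_um < 7 &
                  projected_area_um2 > 0.73)
  expect_equal(nrow(res$kept), sum(brute))
  expect_setequal(res$kept$cell_id, cells$cell_id[brute])
  # idempotence
  again <- apply_hard_filters(res$kept)
  expect_equal(again$kept, res$kept)
  expect_equal(nrow(again$rejection_log), 0)
})

test_that("log-space sigma filter keeps ties, drops planted outliers", {
  same <- data.frame(volume_um3 = rep(2.5, 50))
  expect_equal(nrow(log_sigma_filter(same)), 50)
  set.seed(3)
  v <- rlnorm(2000, log(1), 0.1)
  v[1] <- exp(log(1) + 5 * 0.1)       # ~5 sigma out in log space
  kept <- log_sigma_filter(data.frame(volume_um3 = v))
  expect_false(v[1] %in% kept$volume_um3)
  # pass-through below 3 records
  expect_equal(nrow(log_sigma_filter(data.frame(volume_um3 = c(1, 100)))), 2)
})

test_that("3-sigma log filter retains about 99.7% of log-normal volumes", {
  set.seed(11)
  v <- data.frame(volume_um3 = rlnorm(1e5, 0, 0.4))
  frac <- nrow(log_sigma_filter(v)) / 1e5
  expect_lt(abs(frac - 0.997), 0.001)
})

test_that("summaries are deterministic and handle degenerate groups", {
  one <- data.frame(condition = "a", time_h = 0, volume_um3 = 2,
                    length_um = 3, width_um = 1, sv_ratio = 1.5)
  s1 <- summarize_cells(one, bootstrap_reps = 100, seed = 5)
  expect_equal(s1$mean_volume_um3, 2)
  expect_equal(s1$sd_volume_um3, 0)
  expect_equal(s1$ci_halfwidth_volume, 0)
  expect_equal(s1$n_cells, 1)
  # two groups with identical data give identical summaries
  cells <- derive_dimensions(random_cells(80, seed = 2))$cells
  two <- rbind(transform(cells, condition = "a"),
               transform(cells, condition = "b"))
  s2 <- summarize_cells(two, bootstrap_reps = 300, seed = 5)
  expect_equal(s2$mean_volume_um3[1], s2$mean_volume_um3[2])
  expect_equal(s2$ci_halfwidth_volume[1], s2$ci_halfwidth_volume[2])
})

test_that("bootstrap interval for the mean volume has near-nominal coverage", {
  set.seed(21)
  hits <- 0L
  reps <- 100L
  true_mean <- exp(0 + 0.35^2 / 2)
  for (r in seq_len(reps)) {
    g <- data.frame(condition = "a", time_h = 0,
                    volume_um3 = rlnorm(500, 0, 0.35),
                    length_um = 1, width_um = 1, sv_ratio = 1)
    s <- summarize_cells(g, bootstrap_reps = 400, seed = r)
    hits <- hits + (abs(s$mean_volume_um3 - true_mean) <= s$ci_halfwidth_volume)
  }
  expect_gte(hits / reps, 0.88)
  expect_lte(hits / reps, 0.99)
})

test_that("grouped filtering applies the sigma filter per time point", {
  set.seed(4)
  a <- derive_dimensions(random_cells(300, seed = 13, time_h = 0))$cells
  b <- derive_dimensions(random_cells(300, seed = 14, time_h = 1))$cells
  res <- filter_cells(rbind(a, b))
  expect_true(all(res$kept$time_h %in% c(0, 1)))
  # equivalent to applying the stages by hand
  hard <- apply_hard_filters(rbind(a, b))$kept
  byhand <- do.call(rbind, lapply(split(hard, hard$time_h), log_sigma_filter))
  expect_equal(nrow(res$kept), nrow(byhand))
})
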