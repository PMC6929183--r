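# batch-means standard error for an autocorrelated Metropolis chain
batch_se <- function(x, nb = 20) {
  m <- tapply(x, ceiling(seq_along(x) / (length(x) / nb)), mean)
  sd(m) / sqrt(nb)
}

test_that("a single window on a flat profile samples around its center", {
  prof <- profile_spec("table", z = c(-5, 5), A = c(0, 0), temperature = 298)
  w <- sample_umbrella_windows(prof, centers = 0.4, bias_k = 50,
                               n_per_window = 4000, seed = 1)
  s <- w[[1]]$samples
  expect_lt(abs(mean(s) - 0.4), 3 * batch_se(s))
  expect_gt(w[[1]]$acceptance, 0.2)
  expect_lt(w[[1]]$acceptance, 0.65)
})

test_that("a harmonic profile with bias gives the Gaussian-product mean", {
  kappa <- 20; kb <- 50; cen <- 0.8
  prof <- profile_spec("harmonic", kappa = kappa, temperature = 298)
  w <- sample_umbrella_windows(prof, centers = cen, bias_k = kb,
                               n_per_window = 6000, seed = 2)
  s <- w[[1]]$samples
  expect_lt(abs(mean(s) - kb * cen / (kappa + kb)), 3 * batch_se(s))
})

test_that("window sampling is seed-deterministic and validates inputs", {
  prof <- profile_spec("harmonic", kappa = 20)
  w1 <- sample_umbrella_windows(prof, c(-0.2, 0.2), 40, 200, seed = 5)
  w2 <- sample_umbrella_windows(prof, c(-0.2, 0.2), 40, 200, seed = 5)
  expect_identical(w1[[1]]$samples, w2[[1]]$samples)
  expect_identical(w1[[2]]$samples, w2[[2]]$samples)
  expect_error(sample_umbrella_windows(prof, c(0.5, -0.5), 40, 200),
               "increasing")
  expect_error(sample_umbrella_windows(prof, 0, -1, 200), "positive")
  expect_error(sample_umbrella_windows(prof, 0, 40, 50), ">= 100")
})

test_that("non-overlapping adjacent windows are flagged", {
  prof <- profile_spec("harmonic", kappa = 0.001)
  expect_warning(
    w <- sample_umbrella_windows(prof, c(-30, 30), bias_k = 2000,
                                 n_per_window = 200, seed = 3),
    "non-overlapping")
  expect_true(attr(w, "overlap_warning"))
})

test_that("umbrella TSV round trips", {
  prof <- profile_spec("harmonic", kappa = 20)
  w <- sample_umbrella_windows(prof, c(-0.3, 0.3), 40, 150, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_umbrella_tsv(w, path)
  back <- read_umbrella_tsv(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$samples, w[[1]]$samples, tolerance = 1e-12)
  expect_equal(back[[2]]$bias_k, 40)
})

test_that("the reaction coordinate is the bond-length difference", {
  spec <- reaction_coordinate_spec(donor = c(1, 2), acceptor = c(2, 3))
  geo <- rbind(c(0, 0, 0), c(0, 0, 1.1), c(0, 0, 2.7))
  expect_equal(reaction_coordinate(geo, spec), -0.5, tolerance = 1e-12)
  geo_sym <- rbind(c(0, 0, 0), c(0, 0, 1.3), c(0, 0, 2.6))
  expect_equal(reaction_coordinate(geo_sym, spec), 0, tolerance = 1e-12)
  geo_prod <- rbind(c(0, 0, 0), c(0, 0, 2), c(0, 0, 3))
  expect_equal(reaction_coordinate(geo_prod, spec), 1, tolerance = 1e-12)
  expect_error(reaction_coordinate(rbind(geo[1, ], geo[1, ], geo[3, ]),
                                   spec), "coincident")
  expect_error(reaction_coordinate_spec(c(1, 2), c(3, 4)), "close the")
  expect_error(reaction_coordinate_spec(c(1, 2), c(2, 1)), "distinct")
})

test_that("single-window WHAM with vanishing bias reduces to histogramming", {
  prof <- profile_spec("harmonic", kappa = 8, temperature = 298)
  w <- sample_umbrella_windows(prof, 0, bias_k = 1e-8, n_per_window = 3000,
                               seed = 4)
  p <- wham(w, th_298, bins = 25)
  breaks <- seq(min(w[[1]]$samples), max(w[[1]]$samples),
                length.out = 26)
  h <- hist(w[[1]]$samples, breaks = breaks, plot = FALSE)
  prob_wham <- exp(-th_298$beta * p$A)
  prob_wham <- prob_wham / sum(prob_wham, na.rm = TRUE)
  prob_hist <- h$counts / sum(h$counts)
  expect_lt(max(abs(prob_wham - prob_hist), na.rm = TRUE), 1e-6)
})

test_that("WHAM is invariant under window relabeling and duplication", {
  prof <- profile_spec("double_well", height = 4, width = 1,
                       temperature = 298)
  centers <- seq(-1.2, 1.2, length.out = 10)
  w <- sample_umbrella_windows(prof, centers, 25, 800, seed = 6)
  p1 <- wham(w, th_298, bins = 40)
  p2 <- wham(rev(w), th_298, bins = 40)
  expect_equal(p2$A, p1$A, tolerance = 1e-6)
  p3 <- wham(c(w, w), th_298, bins = 40)
  expect_equal(p3$A, p1$A, tolerance = 1e-6)
})

test_that("hitting the iteration cap raises a condition carrying the partial result", {
  prof <- profile_spec("double_well", height = 4, width = 1,
                       temperature = 298)
  w <- sample_umbrella_windows(prof, seq(-1.2, 1.2, length.out = 8), 40,
                               300, seed = 8)
  cond <- tryCatch(wham(w, th_298, tol = 1e-12, max_iter = 3),
                   isokie_wham_nonconverged = function(c) c)
  expect_s3_class(cond, "isokie_wham_nonconverged")
  expect_s3_class(cond$profile, "pmf_profile")
  expect_false(cond$profile$converged)
})

test_that("barrier extraction errors on monotone profiles and ignores constant shifts", {
  prof <- profile_spec("harmonic", kappa = 20, temperature = 298)
  w <- sample_umbrella_windows(prof, seq(-1.3, 1.3, length.out = 14), 50,
                               500, seed = 10)
  p <- wham(w, th_298)
  expect_error(barrier_height(p, c(-1.3, -0.6)), "no barrier")

  prof2 <- profile_spec("double_well", height = 4, width = 1,
                        temperature = 298)
  w2 <- sample_umbrella_windows(prof2, seq(-1.3, 1.3, length.out = 14), 50,
                                800, seed = 11)
  p2 <- wham(w2, th_298)
  b <- barrier_height(p2, c(-1.3, -0.6))
  p2_shift <- p2
  p2_shift$A <- p2$A + 3.7
  b_shift <- barrier_height(p2_shift, c(-1.3, -0.6))
  expect_equal(as.numeric(b_shift), as.numeric(b), tolerance = 1e-12)
})

test_that("PMF TSV round trips", {
  prof <- profile_spec("harmonic", kappa = 20, temperature = 298)
  w <- sample_umbrella_windows(prof, seq(-1, 1, length.out = 6), 40, 300,
                               seed = 12)
  p <- wham(w, th_298, bins = 30)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pmf_tsv(p, path)
  back <- read_pmf_tsv(path)
  expect_equal(back$z, p$z, tolerance = 1e-9)
  expect_equal(back$A_kcal_mol, p$A, tolerance = 1e-9)
})
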