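test_that("simulate_lines handles trivial and closed-form cases", {
  cst <- rot1_constants()
  expect_equal(nrow(simulate_lines(cst, NULL, dipole_moment(0, 0, 0),
                                   window = c(2000, 8000))), 0)
  # rigid rotor, narrow window: single a-type line 1_01 <- 0_00 at B+C
  ll <- simulate_lines(cst, NULL, dipole_moment(5.1, 0, 0),
                       window = c(500, 1000), Jmax = 20)
  expect_equal(nrow(ll[ll$Ju == 1, ]), 1)
  expect_equal(ll$frequency[ll$Ju == 1], 304.82621 + 292.43629,
               tolerance = 1e-10)
  expect_error(simulate_lines(cst, NULL, dipole_moment(1, 0, 0),
                              window = c(100, 50)), "window")
  expect_error(simulate_lines(cst, NULL, dipole_moment(1, 0, 0), T = -1,
                              window = c(100, 500)), "temperature")
})

test_that("a-type R-branch in 2-8 GHz spans lower-state J = 3 through 12", {
  ll <- simulate_lines(rot1_constants(), rot1_distortion(),
                       dipole_moment(5.1, 0, 0), window = c(2000, 8000),
                       Jmax = 20)
  rb <- ll[ll$Ju == ll$Jl + 1, ]
  expect_identical(range(rb$Jl), c(3L, 12L))
})

test_that("selection rules match brute-force direction-cosine enumeration", {
  cst <- rot1_constants()
  dst <- rot1_distortion()
  mu <- dipole_moment(1, 1, 1)
  window <- c(100, 25000)
  Jmax <- 5
  got <- simulate_lines(cst, dst, mu, T = 2, window = window, Jmax = Jmax)
  key <- function(d) sprintf("%d.%d.%d-%d.%d.%d.%s", d$Ju, d$Kau, d$Kcu,
                             d$Jl, d$Kal, d$Kcl, d$type)
  # brute force: every ordered state pair across neighbouring J blocks
  blocks <- lapply(0:Jmax, rotjet:::solve_block, cst = cst, dst = dst)
  want <- character(0)
  for (Jl in 0:Jmax) for (Ju in Jl:min(Jl + 1, Jmax)) {
    if (Ju == 0) next
    S <- rotjet:::strength_matrices(blocks[[Ju + 1]], blocks[[Jl + 1]], Ju, Jl)
    su <- blocks[[Ju + 1]]$states; sl <- blocks[[Jl + 1]]$states
    for (ax in c("a", "b", "c")) {
      for (iu in seq_len(nrow(su))) for (il in seq_len(nrow(sl))) {
        nu <- su$energy[iu] - sl$energy[il]
        if (S[[ax]][iu, il] > 1e-10 && nu > 0 &&
            nu >= window[1] && nu <= window[2])
          want <- c(want, sprintf("%d.%d.%d-%d.%d.%d.%s", Ju, su$Ka[iu],
                                  su$Kc[iu], Jl, sl$Ka[il], sl$Kc[il], ax))
      }
    }
  }
  expect_setequal(key(got), want)
  # every returned line obeys the a/b/c parity rules
  expect_identical(transition_type(got), got$type)
})

test_that("symmetric-top a-type R-branch strengths equal Hoenl-London factors", {
  ll <- simulate_lines(rotational_constants(3000, 300, 300), NULL,
                       dipole_moment(1, 0, 0), window = c(1, 1e6), Jmax = 6)
  rb <- ll[ll$Ju == ll$Jl + 1, ]
  hl <- ((rb$Jl + 1)^2 - rb$Kau^2) / (rb$Jl + 1)
  expect_equal(rb$strength, hl, tolerance = 1e-6)
})

test_that("intensities are non-negative and scale with the dipole squared", {
  cst <- rot1_constants()
  ll1 <- simulate_lines(cst, NULL, dipole_moment(2, 0, 1),
                        window = c(2000, 6000), Jmax = 8)
  ll2 <- simulate_lines(cst, NULL, dipole_moment(4, 0, 2),
                        window = c(2000, 6000), Jmax = 8)
  expect_true(all(ll1$intensity >= 0))
  expect_equal(ll2$intensity, 4 * ll1$intensity, tolerance = 1e-12)
})

test_that("consecutive a-type R-branch clusters are spaced by about B+C", {
  ll <- simulate_lines(rot1_constants(), NULL, dipole_moment(5.1, 0, 0),
                       window = c(2000, 8000), Jmax = 20)
  rb <- ll[ll$Ju == ll$Jl + 1 & ll$Kau == 0, ]
  spacing <- diff(rb$frequency[order(rb$Jl)])
  bc <- 304.82621 + 292.43629
  expect_true(all(abs(spacing - bc) / bc < 0.01))
  expect_lt(abs(bc - 600), 5)    # the "about 600 MHz" comb
})

test_that("line lists round-trip through the text format", {
  truth <- rot1_truth()
  ll <- gen_linelist(truth, noise_kHz = 9.1, window = c(2000, 8000),
                     seed = 42, n_strongest = 52)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_linelist(ll, path)
  back <- read_linelist(path)
  expect_equal(nrow(back), 52)
  expect_identical(back[, c("Ju", "Kau", "Kcu", "Jl", "Kal", "Kcl")],
                   ll[, c("Ju", "Kau", "Kcu", "Jl", "Kal", "Kcl")])
  expect_equal(back$frequency, ll$frequency, tolerance = 1e-4)
  # write(read(f)) is the identity on the parsed content
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_linelist(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("line-list parser reports malformed rows by line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "4 0 4 3 0 3 2389.05 9.1"), path)
  one <- read_linelist(path)
  expect_equal(nrow(one), 1)
  expect_identical(one$type, "a")
  expect_equal(one$Jl, 3L)
  writeLines(c("4 0 4 3 0 3"), path)
  expect_error(read_linelist(path), "line 1")
  writeLines(c("4 0 4 3 0 3 2389.05 9.1", "4 x 4 3 0 3 2389.05 9.1"), path)
  expect_error(read_linelist(path), "line 2")
  writeLines(c("4 0 4 3 0 3 -5 9.1"), path)
  expect_error(read_linelist(path), "positive")
  writeLines(character(0), path)
  expect_equal(nrow(read_linelist(path)), 0)
})

test_that("stick spectra place, merge and sum Gaussian profiles", {
  empty <- stick_to_spectrum(rotjet:::empty_linelist(), 0.02, c(4000, 6000), 0.1)
  expect_true(all(empty$intensity == 0))
  one <- data.frame(Ju = 1L, Kau = 0L, Kcu = 1L, Jl = 0L, Kal = 0L,
                    Kcl = 0L, frequency = 5000, uncertainty = NA_real_,
                    strength = 1, intensity = 1, type = "a")
  sp <- stick_to_spectrum(one, 0.02, c(4990, 5010), 0.1)
  expect_lt(abs(sp$frequency[which.max(sp$intensity)] - 5000), 0.02)
  # two equal lines 0.02 MHz apart with fwhm 0.1 merge into one maximum
  two <- rbind(one, one)
  two$frequency <- c(5000, 5000.02)
  sp2 <- stick_to_spectrum(two, 0.005, c(4999, 5001), 0.1)
  peaks <- which(diff(sign(diff(sp2$intensity))) == -2) + 1
  expect_equal(length(peaks), 1)
  expect_true(sp2$frequency[peaks] > 5000 & sp2$frequency[peaks] < 5000.02)
  expect_error(stick_to_spectrum(one, 0.2, c(4990, 5010), 0.1), "grid_step")
})

test_that("JPL catalog records parse to assigned transitions", {
  path <- withr::local_tempfile(fileext = ".cat")
  rec <- sprintf("%13.4f%8.4f%8.4f%2d%10.4f%3d%7d%4d%2d%2d%2d%6s%2d%2d%2d%6s",
                 2389.0500, 0.0091, -5.1234, 3, 0.0797, 9, 123456, 303,
                 4, 0, 4, "", 3, 0, 3, "")
  writeLines(rec, path)
  got <- read_jpl_cat(path)
  expect_equal(got$frequency, 2389.05)
  expect_equal(got$uncertainty, 9.1, tolerance = 1e-9)
  expect_equal(got$Ju, 4L)
  expect_identical(got$type, "a")
})
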