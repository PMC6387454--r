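proto <- study_protocol()
hseqs <- hifi_seqs(proto)
iseqs <- irse_seqs(proto)
me_seq <- proto$mesgre

test_that("HIFI jointly recovers s0, r1 and k from noiseless data", {
  cfg <- fit_config(model = "deichmann")
  for (r1 in c(0.5, 1.0, 2.0, 4.5))
    for (k in c(0.8, 1.0, 1.2)) {
      sig <- hifi_signals(1000, r1, k, hseqs, model = "deichmann")
      fit <- fit_despot1_hifi(sig, hseqs, cfg)
      expect_true(fit$converged)
      expect_equal(fit$params$r1, r1, tolerance = 1e-4)
      expect_equal(fit$params$k, k, tolerance = 1e-4)
      expect_equal(fit$params$s0, 1000, tolerance = 1e-4)
      expect_gt(fit$params$s0, 0)
      expect_gt(fit$params$r1, 0)
      expect_gt(fit$params$k, 0)
    }
})

test_that("each IR-sGRE model is self-consistent under the joint fit", {
  for (m in c("simplified", "deichmann", "brix")) {
    sig <- hifi_signals(800, 1.3, 0.9, hseqs, model = m)
    fit <- fit_despot1_hifi(sig, hseqs, fit_config(model = m))
    expect_equal(fit$params$r1, 1.3, tolerance = 1e-4)
    expect_equal(fit$params$k, 0.9, tolerance = 1e-4)
  }
})

test_that("HIFI input validation catches degenerate and malformed input", {
  expect_error(fit_despot1_hifi(rep(0, 5), hseqs, fit_config()),
               "degenerate")
  expect_error(fit_despot1_hifi(c(1, 2), hseqs[1:2], fit_config()),
               ">= 2 sGRE")
})

test_that("fitting Brix-generated data with the simplified model biases r1
           more at blood-like than tissue-like R1", {
  bias_at <- function(r1_true) {
    sig <- hifi_signals(1000, r1_true, 1, hseqs, model = "brix")
    fit <- fit_despot1_hifi(sig, hseqs, fit_config(model = "simplified"))
    abs(fit$params$r1 - r1_true)
  }
  b_tissue <- bias_at(1.0)
  b_blood <- bias_at(4.5)
  expect_gt(b_blood, b_tissue)
  expect_gt(b_blood, 0.05)
})

test_that("VFA equals truth when k is truly 1, and its two-point closed
           form agrees with the nonlinear refinement", {
  sg <- hseqs[c("sgre_fa12", "sgre_fa5", "sgre_fa3")]
  sig <- hifi_signals(500, 1.1, 1, sg)
  fit <- fit_vfa(sig, sg, fit_config())
  expect_equal(fit$params$r1, 1.1, tolerance = 1e-6)
  expect_equal(fit$params$s0, 500, tolerance = 1e-4)
  # two flip angles: linearised solution is exact, refinement changes nothing
  two <- sg[1:2]
  sig2 <- hifi_signals(500, 0.9, 1, two)
  f_lin <- fit_vfa(sig2, two, fit_config(), refine = FALSE)
  f_nls <- fit_vfa(sig2, two, fit_config(), refine = TRUE)
  expect_equal(f_lin$params$r1, 0.9, tolerance = 1e-8)
  expect_equal(f_nls$params$r1, f_lin$params$r1, tolerance = 1e-8)
  expect_error(fit_vfa(c(1, 2), list(sg[[1]], sg[[1]]), fit_config()),
               "rank-deficient")
})

test_that("VFA is biased under flip-angle error while HIFI is not", {
  sg <- hseqs[c("sgre_fa12", "sgre_fa5", "sgre_fa3")]
  k_true <- 1.15
  sig_sgre <- hifi_signals(1000, 1.0, k_true, sg)
  f_vfa <- fit_vfa(sig_sgre, sg, fit_config())
  expect_gt(abs(f_vfa$params$r1 - 1.0), 0.05)
  sig_all <- hifi_signals(1000, 1.0, k_true, hseqs, model = "deichmann")
  f_hifi <- fit_despot1_hifi(sig_all, hseqs, fit_config(model = "deichmann"))
  expect_lt(abs(f_hifi$params$r1 - 1.0), 1e-3)
})

test_that("R2* fit is exact on noiseless data and ignores harmless
           exclusion settings", {
  me2 <- seq_params("ME-sGRE", tr = 0.5, te = c(0.005, 0.055), flip = 15)
  fit <- fit_r2star(c(90.484, 33.287), me2, fit_config(min_echoes = 2L))
  expect_equal(fit$params$r2star, 20, tolerance = 1e-4)
  expect_equal(fit$params$s_te0, 100, tolerance = 1e-3)
  # constant signal -> zero rate
  fitc <- fit_r2star(rep(42, 8), me_seq, fit_config())
  expect_equal(fitc$params$r2star, 0, tolerance = 1e-8)
  # noiseless full-echo fit unaffected by an exclusion threshold below all
  # data points
  sig <- multiecho_signal(100, 30, me_seq)
  f1 <- fit_r2star(sig, me_seq, fit_config())
  f2 <- fit_r2star(sig, me_seq,
                   fit_config(noise_sigma = 3, noise_floor_factor = 3))
  expect_equal(f1$params$r2star, 30, tolerance = 1e-6)
  expect_equal(f2$params$r2star, 30, tolerance = 1e-6)
  expect_equal(f2$n_points_used, 8L)
  # log-linear fast mode agrees on noiseless data
  f3 <- fit_r2star(sig, me_seq, fit_config(r2star_method = "loglin"))
  expect_equal(f3$params$r2star, 30, tolerance = 1e-8)
})

test_that("R2* noise-floor exclusion shrinks Rician bias", {
  # iron-loaded (post-USPIO venous) decay rate, so the tail echoes
  # actually reach the noise floor within the 4.6-41.5 ms echo train
  r2_true <- 150
  sig0 <- multiecho_signal(100, r2_true, me_seq)
  sigma <- sig0[1] / 30  # SNR 30 at the first echo
  n_vox <- 400
  r2_excl <- r2_all <- numeric(n_vox)
  set.seed(42)
  for (i in seq_len(n_vox)) {
    noisy <- sqrt((sig0 + rnorm(8, 0, sigma))^2 + rnorm(8, 0, sigma)^2)
    r2_excl[i] <- fit_r2star(noisy, me_seq,
      fit_config(noise_sigma = sigma, noise_floor_factor = 3,
                 min_echoes = 3L))$params$r2star
    r2_all[i] <- fit_r2star(noisy, me_seq, fit_config())$params$r2star
  }
  expect_lt(abs(mean(r2_excl) - r2_true), abs(mean(r2_all) - r2_true))
})

test_that("R2* fit flags voxels with too few surviving echoes", {
  # signal entirely below the floor
  fit <- fit_r2star(rep(1, 8), me_seq,
                    fit_config(noise_sigma = 5, noise_floor_factor = 3))
  expect_false(fit$converged)
  expect_true(is.na(fit$params$r2star))
  expect_equal(fit$n_points_used, 0L)
})

test_that("IR-SE fit recovers r1 from signed and magnitude data", {
  sig <- vapply(iseqs, function(sq) irse_signal(200, 0.6, sq), 0)
  f_signed <- fit_irse(sig, iseqs, fit_config())
  expect_equal(f_signed$params$r1, 0.6, tolerance = 1e-6)
  expect_equal(f_signed$params$s0, 200, tolerance = 1e-4)
  # magnitude data: polarity restoration must find the same solution as the
  # signed fit (exhaustive sign search is the implementation's oracle)
  f_mag <- fit_irse(abs(sig), iseqs, fit_config(), magnitude = TRUE)
  expect_equal(f_mag$params$r1, f_signed$params$r1, tolerance = 1e-6)
  # high r1: no zero-crossing within the sampled TI range
  sig_hi <- vapply(iseqs, function(sq) irse_signal(150, 25, sq), 0)
  f_hi <- fit_irse(sig_hi, iseqs, fit_config())
  expect_equal(f_hi$params$r1, 25, tolerance = 1e-4)
})

test_that("fitting is deterministic for fixed inputs and config", {
  sig <- hifi_signals(1000, 2.2, 1.1, hseqs, model = "deichmann") *
    (1 + c(0.01, -0.02, 0.005, -0.01, 0.02))
  f1 <- fit_despot1_hifi(sig, hseqs, fit_config())
  f2 <- fit_despot1_hifi(sig, hseqs, fit_config())
  expect_identical(f1, f2)
})

test_that("fit_volume maps a small noiseless phantom exactly inside the
           mask and leaves sentinels outside", {
  spec <- phantom_spec(grid = c(8L, 8L, 4L),
    compartments = list(list(shape = "box", centre = c(4.5, 4.5, 2.5),
                             size = c(2.5, 2.5, 1.5), r1 = 1.4,
                             r2star = 28, pd = 100)),
    b1_poly = c(1.05, 0, 0, -0.1, -0.1, 0), slab_taper = 0.05,
    noise_sigma = 0)
  maps_true <- build_phantom(spec)
  stacks <- simulate_protocol(maps_true,
    hifi_seqs(study_protocol()), spec, model = "brix")
  mask <- maps_true$label > 0
  maps <- fit_volume(stacks, mask, fit_config(model = "brix"), what = "hifi")
  expect_equal(maps$r1[mask], maps_true$r1[mask], tolerance = 1e-5)
  expect_equal(maps$k[mask], maps_true$k[mask], tolerance = 1e-5)
  expect_true(all(is.na(maps$r1[!mask])))
  # shape mismatch is rejected
  expect_error(fit_volume(stacks, array(TRUE, c(4, 4, 4)), fit_config()),
               "mask")
})

test_that("fit_volume honours per-stack intensity scale factors", {
  spec <- phantom_spec(grid = c(4L, 4L, 2L), compartments = list(),
                       background = list(r1 = 1.2, r2star = 20, pd = 50),
                       b1_poly = c(1, 0, 0, 0, 0, 0), slab_taper = 0,
                       noise_sigma = 0)
  maps_true <- build_phantom(spec)
  stacks <- lapply(seq_along(hseqs), function(i)
    simulate_acquisition(maps_true, hseqs[[i]], spec, model = "deichmann",
                         scale = i))  # different scanner scaling per stack
  mask <- array(TRUE, spec$grid)
  maps <- fit_volume(stacks, mask, fit_config(model = "deichmann"),
                     what = "hifi")
  expect_equal(maps$r1[mask], maps_true$r1[mask], tolerance = 1e-5)
})
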