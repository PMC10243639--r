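test_that("talker generation is deterministic with a consistent tier", {
  alph <- synthetic_alphabet()
  t1 <- generate_talker(10, alph, seed = 5)
  t2 <- generate_talker(10, alph, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1$tier, generate_talker(10, alph, seed = 6)$tier))
  # tier spans exactly the requested duration
  expect_equal(attr(t1$tier, "total_duration_s"), 10)
  expect_equal(sum(t1$tier$end_s - t1$tier$start_s), 10)
  # segment durations within 50-250 ms
  durs <- t1$tier$end_s - t1$tier$start_s
  expect_true(all(durs >= 0.05 - 1e-9 & durs <= 0.3))
  expect_error(generate_talker(5, list(labels = character(0)), 1), "empty")
})

test_that("each rendered segment is dominated by its phoneme's band profile", {
  alph <- synthetic_alphabet()
  tk <- generate_talker(10, alph, seed = 9)
  ok <- vapply(seq_len(nrow(tk$tier)), function(i) {
    rows <- glimpsetrf:::interval_frames(tk$tier$start_s[i], tk$tier$end_s[i],
                                         100, nrow(tk$spec_fine$values))
    seg_peak <- which.max(colMeans(tk$spec_fine$values[rows, , drop = FALSE]))
    prof_peak <- which.max(alph$profiles[, tk$tier$label[i]])
    abs(seg_peak - prof_peak) <= 5
  }, logical(1))
  expect_gt(mean(ok), 0.95)
})

test_that("talker mixing is RMS-matched with sane limits", {
  alph <- synthetic_alphabet()
  a <- generate_talker(5, alph, seed = 1)$spec_fine
  b <- generate_talker(5, alph, seed = 2)$spec_fine
  rms <- function(x) sqrt(mean(x^2))
  m <- mix_talkers(a, b, 0)
  expect_equal(rms(m$b$values), rms(a$values), tolerance = 1e-12)
  expect_equal(m$mixture$values, a$values + m$b$values)
  # silent second talker: mixture equals the first
  silent <- b; silent$values <- b$values * 0
  expect_equal(mix_talkers(a, silent)$mixture$values, a$values)
  # -Inf level: contribution vanishes
  expect_equal(mix_talkers(a, b, -Inf)$mixture$values, a$values)
  # identical talkers (coherent spectrogram-domain sum): doubled values
  expect_equal(mix_talkers(a, a)$mixture$values, 2 * a$values)
  short <- a; short$values <- a$values[1:10, ]
  expect_error(mix_talkers(a, short), "equal durations")
})

test_that("datasets round-trip their generating regressors at theta*", {
  pre <- make_scenario_presets()
  sim <- simulate_dataset(pre$threshold_recovery, seed = 12)
  rebuilt <- build_feature_bank(
    sim$target, sim$nontarget,
    pre$threshold_recovery$theta_star_db, sim$alphabet$fmap,
    include = names(sim$bank$groups))
  expect_equal(rebuilt$groups, sim$bank$groups)
  # dataset reproducibility is bit-for-bit
  sim2 <- simulate_dataset(pre$threshold_recovery, seed = 12)
  expect_identical(sim$responses, sim2$responses)
  expect_identical(sim$target, sim2$target)
})

test_that("near-noiseless simulation lets the TRF recover ground truth", {
  pre <- make_scenario_presets()
  sc <- pre$threshold_recovery
  sc$r_target <- 0.9999
  sc$duration_s <- 120
  sim <- simulate_dataset(sc, seed = 13)
  # a small stabilizing penalty suppresses the numerically unobservable
  # directions without biasing the observable ones
  lam <- setNames(rep(100, length(sim$bank$groups)), names(sim$bank$groups))
  fit <- trf(sim$bank, sim$responses, lambdas = lam,
             lags_ms = c(0, 500), n_folds = 2, cv = FALSE)
  # per electrode, true vs estimated weight tensors correlate > 0.99
  for (e in c(1, 10, 20)) {
    expect_gt(cor(c(sim$truth$weights[, , e]), c(fit$weights[, , e])), 0.99)
  }
})

test_that("subject gains induce within-subject response dependence", {
  pre <- make_scenario_presets()
  sim <- simulate_dataset(pre$threshold_recovery, seed = 14)
  expect_equal(length(unique(sim$truth$gains)), 4)   # one gain per subject
  expect_identical(sim$truth$gains[1], sim$truth$gains[2])
  expect_equal(length(sim$subjects), 40)
  expect_equal(dim(sim$responses), c(6000L, 40L))
})

test_that("waveform rendering survives the audio front end", {
  alph <- synthetic_alphabet()
  tk <- generate_talker(3, alph, seed = 41)
  wav <- render_talker_waveform(tk, alph, fs = 16000, seed = 2)
  expect_equal(length(wav), 3 * 16000)
  expect_lte(max(abs(wav)), 1)
  expect_identical(wav, render_talker_waveform(tk, alph, fs = 16000, seed = 2))
  # the audio-derived spectrogram puts each segment's energy near the
  # phoneme's profile peak
  sp <- compute_band_spectrogram(wav, 16000, n_bands = 100)
  ok <- vapply(seq_len(nrow(tk$tier)), function(i) {
    rows <- glimpsetrf:::interval_frames(tk$tier$start_s[i], tk$tier$end_s[i],
                                         100, nrow(sp$values))
    seg_peak <- which.max(colMeans(sp$values[rows, , drop = FALSE]))
    prof_peak <- which.max(alph$profiles[, tk$tier$label[i]])
    abs(seg_peak - prof_peak) <= 12
  }, logical(1))
  expect_gt(mean(ok), 0.8)
})

test_that("feature-bank shufflers produce valid, reproducible nulls", {
  alph <- synthetic_alphabet()
  tgt <- generate_talker(6, alph, seed = 21)
  ntg <- generate_talker(6, alph, seed = 22)
  bank <- build_feature_bank(tgt, ntg, 0, alph$fmap)
  for (g in c("spectrogram", "glimpsed_phonetic", "masked_phonetic",
              "word_onsets")) {
    sh1 <- bank$shufflers[[g]](1)
    expect_identical(dim(sh1), dim(bank$groups[[g]]))
    expect_identical(sh1, bank$shufflers[[g]](1))
    expect_false(identical(sh1, bank$shufflers[[g]](2)))
  }
  # acoustic shuffle preserves column moments; word-onset shuffle preserves
  # the per-talker impulse count
  sh_sp <- bank$shufflers$spectrogram(3)
  expect_equal(colMeans(sh_sp), colMeans(bank$groups$spectrogram))
  sh_wo <- bank$shufflers$word_onsets(4)
  expect_equal(colSums(sh_wo), colSums(bank$groups$word_onsets),
               ignore_attr = TRUE)
  # phonetic mapping shuffle still reconstructs a binary feature matrix
  shg <- bank$shufflers$glimpsed_phonetic(5)
  shm <- bank$shufflers$masked_phonetic(5)
  sums <- shg + shm
  expect_true(all(abs(sums) < 1e-9 | abs(sums - 1) < 1e-9))
  binary <- bank$groups$glimpsed_phonetic + bank$groups$masked_phonetic
  expect_false(identical(sums, binary))   # articulatory info destroyed
})

test_that("scenario presets are complete and serialize losslessly", {
  pre <- make_scenario_presets(theta_star_db = -8)
  expect_setequal(names(pre), c("hg_like", "stg_like", "null",
                                "threshold_recovery", "flat_threshold"))
  expect_equal(pre$threshold_recovery$theta_star_db, -8)
  expect_equal(pre$stg_like$n_subjects, 7)
  expect_equal(pre$stg_like$electrodes_per_subject, 10)
  expect_equal(pre$stg_like$duration_s, 600)
  expect_equal(pre$stg_like$encoding$glimpsed_phonetic$latency_ms, 190)
  expect_equal(pre$stg_like$encoding$masked_phonetic$latency_ms, 285)
  expect_identical(pre, unserialize(serialize(pre, NULL)))
  expect_error(simulate_dataset(structure(list(), class = "list"), 1))
  # response redraw keeps the stimulus but changes TRFs and noise
  base_sim <- simulate_dataset(pre$null, seed = 1)
  redrawn <- simulate_responses(base_sim, seed = 99)
  expect_identical(redrawn$bank$groups, base_sim$bank$groups)
  expect_false(identical(redrawn$responses, base_sim$responses))
  bad_sc <- pre$null; bad_sc$r_target <- 1.2
  expect_error(simulate_responses(base_sim, seed = 1, scenario = bad_sc),
               "inside")
})
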