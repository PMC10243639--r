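test_that("glimpse ratios match hand counts and boundary rules", {
  tier <- phoneme_tier("P1", 0, 0.02, 1L)
  talker <- spec_from_matrix(matrix(c(2, 4, 1, 1), 2, 2))
  backgr <- spec_from_matrix(matrix(c(1, 1, 2, 2), 2, 2))
  r <- compute_glimpse_ratios(talker, backgr, tier, 0)
  expect_equal(r$ratio_glimpse, 0.5)   # cells: 2>=1, 4>=1, 1<2, 1<2
  expect_equal(r$ratio_mask, 0.5)

  tier4 <- toy_tier()
  # silent background: fully glimpsed at any threshold <= 0
  r <- compute_glimpse_ratios(const_spec(1), const_spec(0), tier4, -3)
  expect_equal(r$ratio_glimpse, rep(1, 4))
  # talker == background at 0 dB: >= comparison makes everything glimpsed
  r <- compute_glimpse_ratios(const_spec(2), const_spec(2), tier4, 0)
  expect_equal(r$ratio_glimpse, rep(1, 4))
  # interval outside the spectrogram errors
  late <- phoneme_tier("P1", 0.5, 0.6, 1L)
  expect_error(compute_glimpse_ratios(const_spec(1), const_spec(1), late, 0),
               "outside")
})

test_that("glimpse ratios are monotone in the threshold with correct limits", {
  set.seed(11)
  tv <- matrix(abs(rnorm(40 * 100)), 40, 100)
  bv <- matrix(abs(rnorm(40 * 100)), 40, 100)
  talker <- spec_from_matrix(tv); backgr <- spec_from_matrix(bv)
  tier <- toy_tier()
  thresholds <- seq(-20, 20, by = 2)
  rg <- sapply(thresholds, function(th) {
    compute_glimpse_ratios(talker, backgr, tier, th)$ratio_glimpse
  })
  for (i in seq_len(nrow(rg))) expect_false(is.unsorted(rev(rg[i, ])))
  # complements sum to 1 at every threshold
  rm_ <- sapply(thresholds, function(th) {
    compute_glimpse_ratios(talker, backgr, tier, th)$ratio_mask
  })
  expect_equal(rg + rm_, matrix(1, nrow(rg), ncol(rg)))
  # limits: talker > 0 everywhere so ratio -> 1 at very low threshold;
  # background > 0 everywhere so ratio -> 0 at very high threshold
  expect_equal(compute_glimpse_ratios(talker, backgr, tier, -200)$ratio_glimpse,
               rep(1, 4))
  expect_equal(compute_glimpse_ratios(talker, backgr, tier, 200)$ratio_glimpse,
               rep(0, 4))
})

test_that("phonetic regressors scale binary features by the glimpse ratio", {
  alph <- synthetic_alphabet()
  tier <- toy_tier()
  full <- compute_glimpse_ratios(const_spec(1), const_spec(0), tier, 0)
  reg <- build_phonetic_regressors(tier, alph$fmap, full, 100)
  binary <- reg$glimpsed + reg$masked
  expect_equal(reg$glimpsed, binary)           # fully glimpsed
  expect_equal(reg$masked, matrix(0, 40, 22,
                                  dimnames = dimnames(reg$masked)))
  expect_equal(sum(reg$glimpsed_onsets), 4)    # one impulse per phoneme

  # conservation at an arbitrary threshold: glimpsed + masked == binary
  set.seed(5)
  talker <- spec_from_matrix(matrix(abs(rnorm(4000)), 40, 100))
  backgr <- spec_from_matrix(matrix(abs(rnorm(4000)), 40, 100))
  part <- compute_glimpse_ratios(talker, backgr, tier, -4)
  reg2 <- build_phonetic_regressors(tier, alph$fmap, part, 100)
  expect_equal(reg2$glimpsed + reg2$masked, binary)
  # column mass: frames of phonemes carrying the feature
  for (f in c(1, 7, 22)) {
    carriers <- tier$label[alph$fmap[tier$label, f] == 1]
    expect_equal(sum(binary[, f]), 10 * length(carriers))
  }
  # unknown label errors by name
  bad <- phoneme_tier("ZZ", 0, 0.1, 1L)
  rr <- compute_glimpse_ratios(const_spec(1), const_spec(0), bad, 0)
  expect_error(build_phonetic_regressors(bad, alph$fmap, rr, 100), "ZZ")
})

test_that("a quarter-glimpsed bilabial plosive gets 0.25 in its feature columns", {
  fmap <- arpabet_features()
  tier <- phoneme_tier("B", 0, 0.1, 1L)
  ratios <- data.frame(label = "B", ratio_glimpse = 0.25, ratio_mask = 0.75,
                       snr_threshold_db = 0)
  reg <- build_phonetic_regressors(tier, fmap, ratios, 100)
  on_feats <- c("voiced", "consonantal", "plosive", "anterior", "obstruent",
                "bilabial")
  expect_equal(unname(reg$glimpsed[1:10, on_feats]),
               matrix(0.25, 10, 6))
  expect_equal(unname(reg$masked[1:10, on_feats]),
               matrix(0.75, 10, 6))
  off <- setdiff(colnames(reg$glimpsed), on_feats)
  expect_true(all(reg$glimpsed[, off] == 0))
  expect_equal(unname(reg$glimpsed_onsets[1, 1]), 0.25)
  expect_equal(unname(reg$masked_onsets[1, 1]), 0.75)
})

test_that("word onsets put exactly one impulse at each word-initial phoneme", {
  tier <- toy_tier()
  w <- word_onset_regressor(tier, 100)
  expect_equal(sum(w), 2)
  expect_equal(which(w[, 1] == 1), c(1L, 21L))
  solo <- phoneme_tier("P1", 0, 0.15, 1L)
  ws <- word_onset_regressor(solo, 100)
  expect_equal(which(ws[, 1] == 1), 1L)
})

test_that("shuffled word onsets keep one impulse per word at phoneme starts", {
  tier <- toy_tier()
  sh <- shuffle_word_onsets(tier, 100, seed = 2)
  expect_equal(sum(sh), 2)
  onset_frames <- round(tier$start_s * 100) + 1
  expect_true(all(which(sh[, 1] == 1) %in% onset_frames))
  # one impulse inside each word's frame range
  expect_equal(sum(sh[1:20, 1]), 1)
  expect_equal(sum(sh[21:40, 1]), 1)
  # monophonemic words force the true onsets
  mono <- phoneme_tier(c("P1", "P2"), c(0, 0.1), c(0.1, 0.2), c(1L, 2L))
  expect_equal(shuffle_word_onsets(mono, 100, seed = 5),
               word_onset_regressor(mono, 100),
               ignore_attr = TRUE)
  expect_identical(shuffle_word_onsets(tier, 100, seed = 2), sh)
})

test_that("feature-mapping shuffles permute vectors consistently", {
  alph <- synthetic_alphabet()
  s1 <- shuffle_feature_mapping(alph$fmap, seed = 1)
  expect_identical(s1, shuffle_feature_mapping(alph$fmap, seed = 1))
  expect_false(identical(unclass(s1),
                         unclass(shuffle_feature_mapping(alph$fmap, seed = 2))))
  # multiset of vectors preserved
  key <- function(m) sort(unname(apply(unclass(m), 1, paste, collapse = "")))
  expect_identical(key(s1), key(alph$fmap))
  expect_identical(rownames(s1), rownames(alph$fmap))
  # total feature mass over a tier changes per column but the duration-
  # weighted multiset of vector sums is preserved on a uniform tier
  tier <- toy_tier()
  full <- compute_glimpse_ratios(const_spec(1), const_spec(0), tier, 0)
  b0 <- build_phonetic_regressors(tier, alph$fmap, full, 100)
  b1 <- build_phonetic_regressors(tier, s1, full, 100)
  expect_equal(sum(b0$glimpsed[1:10, ]), sum(alph$fmap["P1", ]) * 10)
  expect_equal(sum(b1$glimpsed[1:10, ]), sum(s1["P1", ]) * 10)
})

test_that("the ARPABET table matches standard phonology for a spot-check set", {
  fmap <- arpabet_features()
  expect_equal(nrow(fmap), 39)
  expect_identical(colnames(fmap), phonetic_feature_names())
  on_features <- function(p) colnames(fmap)[fmap[p, ] == 1]
  expect_setequal(on_features("B"), c("voiced", "consonantal", "plosive",
                                      "anterior", "obstruent", "bilabial"))
  expect_setequal(on_features("P"), c("unvoiced", "consonantal", "plosive",
                                      "anterior", "obstruent", "bilabial"))
  expect_setequal(on_features("S"), c("unvoiced", "consonantal", "fricative",
                                      "strident", "coronal", "anterior",
                                      "obstruent", "alveolar"))
  expect_setequal(on_features("Z"), c("voiced", "consonantal", "fricative",
                                      "strident", "coronal", "anterior",
                                      "obstruent", "alveolar"))
  expect_setequal(on_features("M"), c("voiced", "sonorant", "consonantal",
                                      "nasal", "anterior", "bilabial"))
  expect_setequal(on_features("NG"), c("voiced", "sonorant", "consonantal",
                                       "nasal", "dorsal", "velar"))
  expect_setequal(on_features("K"), c("unvoiced", "consonantal", "plosive",
                                      "obstruent", "dorsal", "velar"))
  expect_setequal(on_features("IY"), c("voiced", "sonorant", "syllabic",
                                       "front", "high"))
  expect_setequal(on_features("AA"), c("voiced", "sonorant", "syllabic",
                                       "back", "low"))
  expect_setequal(on_features("F"), c("unvoiced", "consonantal", "fricative",
                                      "strident", "anterior", "obstruent",
                                      "labiodental"))
  # every vowel is voiced/sonorant/syllabic; plosives are never sonorant
  vowels <- c("AA","AE","AH","AO","AW","AY","EH","ER","EY","IH","IY",
              "OW","OY","UH","UW")
  expect_true(all(fmap[vowels, c("voiced", "sonorant", "syllabic")] == 1))
  expect_true(all(fmap[fmap[, "plosive"] == 1, "sonorant"] == 0))
})

test_that("alignment readers reproduce a tier from TSV and TextGrid text", {
  tier <- toy_tier()
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(label = tier$label, start_s = tier$start_s,
                         end_s = tier$end_s, word_index = tier$word_index),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- read_alignment_tsv(tsv)
  expect_equal(rt$label, tier$label)
  expect_equal(rt$start_s, tier$start_s)
  expect_equal(rt$word_index, tier$word_index)

  tg <- tempfile(fileext = ".TextGrid")
  writeLines(c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"',
    'xmin = 0', 'xmax = 0.4', 'tiers? <exists>', 'size = 2',
    'item []:', 'item [1]:', 'class = "IntervalTier"', 'name = "phones"',
    'xmin = 0', 'xmax = 0.4', 'intervals: size = 4',
    'intervals [1]:', 'xmin = 0.0', 'xmax = 0.1', 'text = "B"',
    'intervals [2]:', 'xmin = 0.1', 'xmax = 0.2', 'text = "AA"',
    'intervals [3]:', 'xmin = 0.2', 'xmax = 0.3', 'text = "S"',
    'intervals [4]:', 'xmin = 0.3', 'xmax = 0.4', 'text = "IY"',
    'item [2]:', 'class = "IntervalTier"', 'name = "words"',
    'xmin = 0', 'xmax = 0.4', 'intervals: size = 2',
    'intervals [1]:', 'xmin = 0.0', 'xmax = 0.2', 'text = "ba"',
    'intervals [2]:', 'xmin = 0.2', 'xmax = 0.4', 'text = "see"'
  ), tg)
  tgt <- read_textgrid(tg, "phones", word_tier = "words")
  expect_equal(tgt$label, c("B", "AA", "S", "IY"))
  expect_equal(tgt$word_index, c(1L, 1L, 2L, 2L))
  expect_equal(tgt$end_s, c(0.1, 0.2, 0.3, 0.4))
})
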