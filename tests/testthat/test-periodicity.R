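test_that("find_occurrences counts overlapping matches and skips N windows", {
  expect_equal(find_occurrences("AAAA", "WW"), c(0L, 1L, 2L))
  expect_equal(find_occurrences("GGGG", "WW"), integer(0))
  expect_equal(find_occurrences("ATAT", "TA"), 1L)
  expect_equal(find_occurrences("AANAA", "WW"), c(0L, 3L))
  expect_equal(find_occurrences("A", "WW"), integer(0))
  expect_equal(find_occurrences("acgtaa", "WW"), c(3L, 4L))  # case-insensitive
  expect_error(find_occurrences("ACGT", "XX"), "motif")
})

test_that("pairwise distances match the brute-force double-loop oracle", {
  h <- pairwise_distance_hist("AAAA", "WW", d_max = 10)
  expect_equal(unname(h[1:3]), c(2L, 1L, 0L))  # pairs (0,1),(1,2) and (0,2)
  expect_equal(sum(pairwise_distance_hist(c("GG", "CC"), "WW", d_max = 10)), 0L)
  expect_error(pairwise_distance_hist(character(0), "WW"), "empty")

  set.seed(7)
  seqs <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  }, character(1))
  for (motif in c("WW", "TT")) {
    h <- pairwise_distance_hist(seqs, motif, d_max = 150)
    oracle <- brute_pair_hist(seqs, promarch:::dinuc_members(motif), 150)
    expect_equal(unname(h), oracle)
    # conservation: n_pairs equals total brute-force count
    expect_equal(sum(h), sum(oracle))
  }
})

test_that("distribution normalization detrends decay and flags empty input", {
  flat <- normalize_distribution(rep(5, 60))
  expect_lt(max(abs(flat)), 1e-12)

  zero <- normalize_distribution(rep(0, 60))
  expect_true(all(zero == 0))
  expect_true(attr(zero, "flagged"))

  # pure 10-bp comb keeps its period through the pipeline
  comb <- rep(0, 200)
  comb[seq(10, 200, by = 10)] <- 100
  nd <- normalize_distribution(comb)
  psd <- power_spectral_density(nd)
  periods <- 2:50
  expect_equal(periods[which.max(vapply(periods, function(p) psd_at(psd, p),
                                        numeric(1)))], 10)

  expect_error(normalize_distribution(1:5), "length")
})

test_that("FFT power spectrum equals the naive DFT oracle", {
  expect_true(all(power_spectral_density(rep(0, 30))$psd == 0))

  set.seed(11)
  for (L in c(10, 17, 32, 50, 64)) {
    x <- rnorm(L)
    got <- power_spectral_density(x, pad_to = L)
    expect_equal(got$psd, naive_dft_psd(x), tolerance = 1e-9)
    # default padding path, checked against the oracle on the padded vector
    pad <- power_spectral_density(x)
    L_pad <- 2 * (nrow(pad) - 1)
    expect_equal(pad$psd, naive_dft_psd(c(x, numeric(L_pad - L))),
                 tolerance = 1e-9)
  }

  # cosine at 10-bp period peaks exactly on the 0.1 bp^-1 grid point
  x <- cos(2 * pi * (1:200) / 10)
  psd <- power_spectral_density(x, pad_to = 200)
  expect_equal(psd$freq[which.max(psd$psd)], 0.1)
})

test_that("planted 10-bp WW periodicity is recovered and dies under shuffling", {
  g <- gen_periodic_sequences(100, 350, period = 10, seed = 21)
  res <- get_periodicity(g$sequences, "WW")
  score10 <- res$psd_at_period
  for (p in c(7, 8, 9, 11, 12)) expect_gt(score10, psd_at(res, p))

  g8 <- gen_periodic_sequences(100, 350, period = 8, seed = 22)
  res8 <- get_periodicity(g8$sequences, "WW")
  periods <- 5:15
  expect_equal(periods[which.max(vapply(periods, function(p) psd_at(res8, p),
                                        numeric(1)))], 8)

  shuffled <- shuffle_sequences(g$sequences, seed = 23)
  res_sh <- get_periodicity(shuffled, "WW")
  expect_gt(score10 / res_sh$psd_at_period, 5)
})

test_that("periodicity score grows with the planted fraction and is RC-symmetric", {
  scores <- vapply(c(0, 0.25, 0.5, 1), function(f) {
    g <- gen_periodic_sequences(60, 300, planted_fraction = f, seed = 31)
    get_periodicity(g$sequences, "WW")$psd_at_period
  }, numeric(1))
  expect_true(all(diff(scores) > 0))

  # WW is reverse-complement closed: identical spectra on both strands
  g <- gen_periodic_sequences(20, 250, seed = 32)
  rc <- Biostrings::reverseComplement(g$sequences)
  fwd <- get_periodicity(g$sequences, "WW")
  rev <- get_periodicity(rc, "WW")
  expect_identical(fwd$hist, rev$hist)
  expect_equal(fwd$psd_at_period, rev$psd_at_period)
})

test_that("uniform sequences score within the mononucleotide shuffle null", {
  set.seed(41)
  seqs <- vapply(1:15, function(i) {
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  }, character(1))
  obs <- get_periodicity(seqs, "WW", d_max = 140)$psd_at_period
  null <- vapply(1:200, function(i) {
    get_periodicity(shuffle_sequences(seqs, seed = 1000 + i), "WW",
                    d_max = 140)$psd_at_period
  }, numeric(1))
  expect_lt(abs(obs - mean(null)), 3 * sd(null))
})

test_that("periodicity tracks localize planted cassettes", {
  base <- gen_periodic_sequences(1, 1000, planted_fraction = 0, seed = 51)
  ch <- as.character(base$sequences[[1]])
  cassette <- as.character(
    gen_periodic_sequences(1, 300, jitter = 0, seed = 52)$sequences[[1]])
  substr(ch, 401, 700) <- cassette  # 0-based [400, 700)
  genome <- Biostrings::DNAStringSet(c(chrT = ch))

  region <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 1000))
  tr <- periodicity_track(genome, region, window = 100, step = 2)
  expect_equal(length(tr), 451L)  # (1000-100)/2 + 1
  peak0 <- IRanges::start(tr)[which.max(tr$score)] - 1L
  expect_gte(peak0, 400L)
  expect_lt(peak0, 700L)

  # all-G chromosome scores zero everywhere
  gonly <- Biostrings::DNAStringSet(c(chrG = paste(rep("G", 300), collapse = "")))
  trg <- periodicity_track(gonly, GenomicRanges::GRanges("chrG", IRanges::IRanges(1, 300)))
  expect_true(all(trg$score == 0))

  # 200-bp region, window 100, step 2 -> 51 scored positions
  tr51 <- periodicity_track(genome, GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 200)))
  expect_equal(length(tr51), 51L)

  expect_warning(
    periodicity_track(genome, GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 50))),
    "narrower than window")

  # N-containing windows are flagged and score zero
  chn <- ch
  substr(chn, 1, 200) <- paste(rep("N", 200), collapse = "")
  gn <- Biostrings::DNAStringSet(c(chrT = chn))
  trn <- periodicity_track(gn, GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 300)))
  expect_true(all(trn$score[trn$flagged] == 0))
  expect_gt(sum(trn$flagged), 0)
})
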