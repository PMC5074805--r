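# Profile construction, window scanning, Gumbel calibration, FDR and
# singleton extraction.

test_that("build_profile matches hand-computed smoothed log-odds", {
  set.seed(11)
  msa <- vapply(1:10, function(i) {
    paste(sample(aa_alphabet(), 34, replace = TRUE), collapse = "")
  }, character(1))
  bg <- setNames(rep(1 / 20, 20), aa_alphabet())
  prof <- build_profile(msa, pseudocount_weight = 1, background = bg)
  m <- matrix(unlist(strsplit(msa, "")), nrow = 10, byrow = TRUE)
  for (p in c(1L, 7L, 34L)) {
    expect_equal(prof$log_odds[p, ],
                 brute_column_log_odds(m[, p], 10L, 1, bg),
                 tolerance = 1e-12)
  }
  # log-odds consistency: sum_a bg(a) 2^S(p,a) = 1 at every position
  expect_equal(
    as.numeric(2^prof$log_odds %*% bg), rep(1, 34), tolerance = 1e-9)
})

test_that("single-row and replicated-row profiles behave as frequencies", {
  unit <- rps20hhta_unit()
  p1 <- build_profile(unit, pseudocount_weight = 0)
  # observed residue is the only finite-positive score per column
  expect_identical(profile_consensus(p1), unit)
  chars <- strsplit(unit, "")[[1]]
  for (p in c(1L, 10L, 34L)) {
    expect_gt(p1$log_odds[p, chars[p]], 0)
    expect_true(all(is.infinite(p1$log_odds[p, setdiff(aa_alphabet(),
                                                       chars[p])])))
  }
  p3 <- build_profile(rep(unit, 3L), pseudocount_weight = 0)
  expect_equal(p1$log_odds, p3$log_odds)
})

test_that("build_profile rejects malformed input", {
  expect_error(build_profile(c("ACDE", "ACD")), class = "tpr_shape_error")
  expect_error(build_profile("AC-E"), class = "tpr_shape_error")
  bad_bg <- aa_background(); bad_bg["W"] <- 0
  expect_error(build_profile("ACDE", background = bad_bg / sum(bad_bg)),
               class = "tpr_calibration_error")
  expect_error(build_profile("ACDE", pseudocount_weight = -1),
               class = "tpr_value_error")
})

test_that("window scores equal brute-force per-position sums", {
  set.seed(21)
  msa <- make_unit_msa(rps20hhta_unit(), n_rows = 20, seed = 3)
  prof <- build_profile(msa)
  seqs <- make_null_db(20, length_pool = 60:120, seed = 4)
  for (s in seqs[1:5]) {
    sc <- window_scores(prof, s)
    for (st in sample(seq_along(sc), 10)) {
      expect_equal(sc[st], brute_window_score(prof, s, st),
                   tolerance = 1e-10)
    }
  }
})

test_that("unknown residues score as background with a warning", {
  prof <- build_profile(make_unit_msa(rps20hhta_unit(), 20, seed = 5))
  base <- window_scores(prof, strrep("A", 34))
  seq_x <- paste0("X", strrep("A", 33))
  expect_warning(sx <- window_scores(prof, seq_x), "non-standard")
  expect_equal(sx, base - unname(prof$log_odds[1, "A"]))
})

test_that("Gumbel calibration is reproducible, monotone and self-consistent", {
  prof <- build_profile(make_unit_msa(rps20hhta_unit(), 40, seed = 6))
  cal1 <- calibrate_null(prof, n_sequences = 1000, length_pool = 80:200,
                         seed = 42)
  cal2 <- calibrate_null(prof, n_sequences = 1000, length_pool = 80:200,
                         seed = 42)
  expect_identical(cal1$mu0, cal2$mu0)
  expect_identical(cal1$beta, cal2$beta)
  expect_gt(cal1$beta, 0)
  # p-values decrease monotonically with score
  s <- seq(-20, 60, length.out = 50)
  p <- p_value_from_score(cal1, s, 150)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 1))
  # degenerate: identical maxima cannot be calibrated
  expect_error(
    tprhairpin:::fit_gumbel_calibration(rep(5, 500), rep(100L, 500), 34L,
                                        500L),
    class = "tpr_calibration_error")
})

test_that("fitted quantiles match empirical exceedance on fresh nulls", {
  prof <- build_profile(make_unit_msa(rps20hhta_unit(), 40, seed = 6))
  cal <- calibrate_null(prof, n_sequences = 10000, length_pool = 120L,
                        seed = 7)
  thr <- tprhairpin:::score_threshold(cal, 1e-3, 120L)
  set.seed(8)
  n <- 10000L
  lens <- rep(120L, n)
  codes <- sample.int(20L, sum(lens), replace = TRUE,
                      prob = aa_background())
  starts <- c(0L, cumsum(lens)[-n])
  maxima <- tprhairpin:::cpp_db_max_scores(codes, starts, lens,
                                           prof$log_odds)
  exceed <- mean(maxima > thr)
  # binomial 3-sigma band around 1e-3
  expect_lt(abs(exceed - 1e-3), 3 * sqrt(1e-3 * (1 - 1e-3) / n) + 1e-3)
})

test_that("scanning finds planted repeats and respects the length floor", {
  m0 <- published_constructs()$M0
  reps <- decompose_construct(m0)$repeats
  prof <- build_profile(reps, pseudocount_weight = 1)
  cal <- calibrate_null(prof, n_sequences = 500, length_pool = 80:200,
                        seed = 9)
  hits <- scan_sequence(prof, m0$sequence, cal, p_cutoff = 1e-4,
                        seq_id = "M0")
  expect_identical(hits$start, c(3L, 37L, 71L))
  expect_identical(hits$window, reps)
  expect_true(all(hits$p_value <= 1e-4))
  # sequences shorter than a unit yield no hits
  expect_identical(nrow(scan_sequence(prof, strrep("A", 33), cal)), 0L)
  expect_error(scan_sequence(prof, m0$sequence, cal, p_cutoff = 0),
               class = "tpr_value_error")
})

test_that("null scan hit rate is bounded by the per-window expectation", {
  prof <- build_profile(make_unit_msa(rps20hhta_unit(), 40, seed = 6))
  cal <- calibrate_null(prof, n_sequences = 2000, length_pool = 200L,
                        seed = 10)
  db <- make_null_db(1000, length_pool = 200L, seed = 11)
  hits <- scan_db(prof, db, cal, p_cutoff = 1e-4)
  # naive per-window bound: 1000 sequences x 167 windows x 1e-4 = 16.7;
  # max-calibrated p-values make the observed count far smaller
  expect_lte(nrow(hits), stats::qbinom(0.999, 1000L * 167L, 1e-4))
})

test_that("estimate_fdr matches an independent string-based recount", {
  prof <- build_profile(make_unit_msa(rps20hhta_unit(), 40, seed = 6))
  cal <- calibrate_null(prof, n_sequences = 2000, length_pool = 80:150,
                        seed = 12)
  db <- make_null_db(400, length_pool = 80:150, seed = 13)
  planted <- plant_hairpins(db, rep(profile_consensus(prof), 10), seed = 14)
  fdr <- estimate_fdr(prof, cal, planted$db, n_repetitions = 5,
                      p_cutoff = 1e-4, seed = 99)
  expect_identical(fdr$n_repetitions, 5L)
  expect_equal(fdr$fdr_mean, mean(fdr$simulated_hit_counts) /
                 fdr$real_hit_count)
  # recount each repetition through the string-based scan_db path
  lens <- nchar(planted$db)
  lens <- lens[lens >= 34L]
  for (r in 1:5) {
    set.seed(derive_seed(99, r))
    codes <- sample.int(20L, sum(lens), replace = TRUE,
                        prob = aa_background())
    ends <- cumsum(lens)
    seqs <- vapply(seq_along(lens), function(i) {
      paste(aa_alphabet()[codes[(c(1L, head(ends, -1L) + 1L)[i]):ends[i]]],
            collapse = "")
    }, character(1))
    names(seqs) <- sprintf("sim%04d", seq_along(seqs))
    expect_identical(nrow(scan_db(prof, seqs, cal, 1e-4)),
                     fdr$simulated_hit_counts[r])
  }
})

test_that("estimate_fdr handles degenerate hit counts", {
  prof <- build_profile(make_unit_msa(rps20hhta_unit(), 40, seed = 6))
  cal <- calibrate_null(prof, n_sequences = 500, length_pool = 60:100,
                        seed = 15)
  # no real hits -> undefined ratio
  db0 <- make_null_db(20, length_pool = 60:100, seed = 16)
  expect_error(
    estimate_fdr(prof, cal, db0, n_repetitions = 2, p_cutoff = 1e-12,
                 seed = 1),
    class = "tpr_value_error")
  # hits present but simulated counts all zero -> FDR exactly 0
  host <- setNames(profile_consensus(prof), "planted")
  fdr <- estimate_fdr(prof, cal, host, n_repetitions = 3, p_cutoff = 1e-6,
                      seed = 2)
  expect_identical(fdr$simulated_hit_counts, c(0L, 0L, 0L))
  expect_identical(fdr$fdr_mean, 0)
  expect_identical(fdr$fdr_sd, 0)
})

test_that("singleton extraction applies the inter-unit gap rule", {
  mk <- function(seq_id, start) {
    data.frame(seq_id = seq_id, start = start, end = start + 33L,
               window = strrep("A", 34), score = 10, p_value = 1e-5,
               stringsAsFactors = FALSE)
  }
  # gap of 5 (< 10): neither is a singleton
  h <- rbind(mk("s1", 1L), mk("s1", 40L))
  h$window <- c("AAAA", "CCCC")  # distinct windows
  expect_identical(nrow(extract_singletons(h)), 0L)
  # gap of 15 (>= 10): both are singletons
  h2 <- rbind(mk("s1", 1L), mk("s1", 50L))
  h2$window <- c("AAAA", "CCCC")
  expect_identical(extract_singletons(h2)$start, c(1L, 50L))
  # lone hit is a singleton; empty input passes through
  expect_identical(nrow(extract_singletons(mk("s2", 5L))), 1L)
  expect_identical(nrow(extract_singletons(h[0, ])), 0L)
})

test_that("singleton extraction is idempotent, order-invariant and dedups", {
  set.seed(31)
  hits <- do.call(rbind, lapply(1:8, function(i) {
    starts <- sort(sample.int(400L, sample(1:4, 1)))
    data.frame(seq_id = sprintf("s%02d", i), start = starts,
               end = starts + 33L,
               window = replicate(length(starts),
                                  paste(sample(aa_alphabet(), 34,
                                               replace = TRUE),
                                        collapse = "")),
               score = runif(length(starts), 5, 50),
               p_value = runif(length(starts), 1e-8, 1e-4),
               stringsAsFactors = FALSE)
  }))
  once <- extract_singletons(hits)
  twice <- extract_singletons(once)
  expect_identical(once, twice)
  shuffled <- hits[sample.int(nrow(hits)), ]
  expect_identical(extract_singletons(shuffled), once)
  # identical windows across the database are reported once
  dup <- rbind(hits[1, ], transform(hits[1, ], seq_id = "zz"))
  expect_identical(nrow(extract_singletons(dup)), 1L)
})
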