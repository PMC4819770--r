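random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

test_that("window scanning computes GC exactly and skips ambiguity", {
  cand <- scan_candidates("GGCCAATT", oligo_len = 8, gc_target = 0.5,
                          gc_tol = 0)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$gc_fraction, 0.5)
  expect_equal(cand$start, 0L)
  # an all-A target has no candidates near 55% GC
  expect_equal(nrow(scan_candidates(strrep("A", 200))), 0)
  # N-containing windows are skipped
  withN <- scan_candidates("GGCCNATT", oligo_len = 4, gc_target = 0.5,
                           gc_tol = 0.5)
  expect_false(any(vapply(seq_len(nrow(withN)),
                          function(i) grepl("N", withN$sequence[i]),
                          logical(1))))
  expect_error(scan_candidates("ACGT", oligo_len = 50),
               class = "nanosep_domain_error")
})

test_that("window scanning matches a brute-force oracle on a 1-kb target", {
  target <- random_dna(1000, seed = 42)
  cand <- scan_candidates(target, 50, 0.55, 0.05)
  # independent oracle: naive loop over all windows
  oracle <- c()
  for (i in 1:(1000 - 50 + 1)) {
    w <- substr(target, i, i + 49)
    gc <- sum(strsplit(w, "")[[1]] %in% c("G", "C")) / 50
    if (abs(gc - 0.55) <= 0.05 + 1e-12) oracle <- c(oracle, i - 1L)
  }
  expect_identical(cand$start, as.integer(oracle))
})

test_that("modified-base placement respects the >8-base spacing rule", {
  mk <- function(tpos, len = 50) {
    s <- rep("A", len); s[tpos + 1] <- "T"
    tibble::tibble(sequence = paste(s, collapse = ""))
  }
  ok <- assign_modified_bases(mk(c(5, 14, 23, 32, 41)), n_mods = 5)
  expect_true(is.na(ok$mod_flag))
  expect_equal(sort(ok$modified_T_positions[[1]]), c(5, 14, 23, 32, 41))
  # a 7-base gap violates the rule
  bad <- assign_modified_bases(mk(c(5, 12)), n_mods = 2)
  expect_equal(bad$mod_flag, "mods_too_close")
  # too few T's is flagged, not an error
  few <- assign_modified_bases(mk(c(10, 30)), n_mods = 5)
  expect_equal(few$mod_flag, "too_few_T")
})

test_that("spacing maximization matches the exhaustive-subset oracle", {
  for (seed in 1:6) {
    withr::with_seed(seed, {
      tpos <- sort(sample(0:49, sample(8:14, 1)))
    })
    got <- nanosep:::max_min_spacing_subset(tpos, 5)
    best <- max(apply(utils::combn(tpos, 5), 2, function(s) min(diff(s))))
    expect_equal(min(diff(got)), best)
    expect_true(all(got %in% tpos))
  }
})

test_that("the 20-mer uniqueness screen agrees with naive substring search", {
  bg <- random_dna(10000, seed = 7)
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  naive_screen <- function(cand, k = 20) {
    hits <- c()
    for (i in 1:(nchar(cand) - k + 1)) {
      km <- substr(cand, i, i + k - 1)
      if (grepl(km, bg, fixed = TRUE) || grepl(km, revcomp(bg), fixed = TRUE)) {
        hits <- c(hits, km)
      }
    }
    unique(hits)
  }
  # a candidate deliberately sharing a 20-mer with the background
  shared <- substr(bg, 501, 520)
  cand_bad <- paste0(random_dna(15, seed = 8), shared, random_dna(15, seed = 9))
  res <- uniqueness_screen(cand_bad, bg)
  expect_false(res$passed)
  expect_true(shared %in% res$offending_kmers)
  expect_setequal(res$offending_kmers, naive_screen(cand_bad))
  # a candidate hitting only the reverse strand still fails
  cand_rc <- paste0(random_dna(15, seed = 10), revcomp(shared),
                    random_dna(15, seed = 11))
  expect_false(uniqueness_screen(cand_rc, bg)$passed)
  # random candidates agree with the oracle either way
  for (seed in 20:23) {
    cand <- random_dna(50, seed)
    res <- uniqueness_screen(cand, bg)
    expect_equal(res$passed, length(naive_screen(cand)) == 0)
  }
  # empty background always passes
  expect_true(uniqueness_screen(random_dna(50, 1), character(0))$passed)
  expect_error(uniqueness_screen("ACGT", bg, k = 20),
               class = "nanosep_domain_error")
})

test_that("probe-set assembly minimizes span and enforces the 600-nt limit", {
  mk <- function(starts, len = 50) {
    tibble::tibble(start = as.integer(starts),
                   sequence = vapply(starts, function(i) random_dna(len, i),
                                     character(1)))
  }
  # five probes packed inside 380 nt: accepted without warning
  ok <- mk(c(0, 80, 160, 240, 330))
  expect_silent(set <- assemble_probe_set(ok))
  expect_equal(set$span_nt, 380)
  expect_true(set$within_ideal)
  # best achievable span 650 nt: rejected
  expect_error(assemble_probe_set(mk(c(0, 150, 300, 450, 600))),
               class = "nanosep_infeasible")
  expect_error(assemble_probe_set(mk(c(0, 100))),
               class = "nanosep_infeasible")
})

test_that("assembly over scattered candidates matches exhaustive search", {
  withr::with_seed(33, starts <- sort(sample(0:1200, 12)))
  cand <- tibble::tibble(
    start = as.integer(starts),
    sequence = vapply(starts, function(i) random_dna(50, i + 1), character(1)))
  set <- tryCatch(suppressWarnings(assemble_probe_set(cand, max_span = 1300)),
                  nanosep_infeasible = function(e) NULL)
  # oracle: all 5-subsets, keep non-overlapping ones, minimize span
  combos <- utils::combn(12, 5)
  best <- Inf
  for (j in seq_len(ncol(combos))) {
    s <- starts[combos[, j]]
    if (all(diff(s) >= 50)) best <- min(best, max(s) + 50 - min(s))
  }
  if (is.finite(best)) {
    expect_equal(set$span_nt, best)
  } else {
    expect_null(set)
  }
  # determinism
  set2 <- suppressWarnings(assemble_probe_set(cand, max_span = 1300))
  expect_identical(set$probes$start, set2$probes$start)
})

test_that("the full screen runs end to end on FASTA-style input", {
  target <- random_dna(1500, seed = 101)
  bg <- random_dna(5000, seed = 102)
  res <- design_probes(target, bg, max_span = 1500, ideal_span = 1500)
  expect_true(all(c("gc_fraction", "mod_flag", "unique_ok") %in%
                    names(res$candidates)))
  if (!is.null(res$probe_set)) {
    expect_s3_class(res$probe_set, "probe_set")
    expect_lte(res$probe_set$span_nt, 1500)
    expect_equal(nrow(res$probe_set$probes), 5)
  }
})
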