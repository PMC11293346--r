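# shared amplicon fixture: a 285-bp locus amplicon with the cut at 140
amp_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ex <- toy_experiment()
      cut <- cut_position(ex$locus)
      cache <<- list(ex = ex, cut = cut,
                     reference = substr(ex$locus$sequence, cut - 140 + 1,
                                        cut + 145),
                     ref_cut = 140L)
    }
    cache
  }
})

test_that("indel calling counts only window-overlapping indels, never substitutions", {
  fx <- amp_fixture()
  ref <- fx$reference; cut <- fx$ref_cut
  ch <- strsplit(ref, "")[[1]]
  sub_far <- ch; sub_far[cut - 30] <- setdiff(c("A", "C", "G", "T"),
                                              ch[cut - 30])[1]
  sub_near <- ch; sub_near[cut + 2] <- setdiff(c("A", "C", "G", "T"),
                                               ch[cut + 2])[1]
  reads <- data.frame(
    read_id = c("identical", "del_at_cut", "sub_far", "sub_near",
                "ins_at_cut", "del_outside"),
    sequence = c(
      ref,
      paste0(substr(ref, 1, cut), substr(ref, cut + 2, 285)),   # 1-nt del
      paste(sub_far, collapse = ""),
      paste(sub_near, collapse = ""),
      paste0(substr(ref, 1, cut), "ACGTA", substr(ref, cut + 1, 285)),
      paste0(substr(ref, 1, 80), substr(ref, 84, 285))),        # del at 80
    stringsAsFactors = FALSE)
  res <- call_amplicon_indels(reads, ref, cut)
  got <- setNames(res$calls$modified, res$calls$read_id)
  expect_false(got[["identical"]])
  expect_true(got[["del_at_cut"]])
  expect_false(got[["sub_far"]])
  expect_false(got[["sub_near"]])   # substitutions alone never count
  expect_true(got[["ins_at_cut"]])
  expect_false(got[["del_outside"]])
  expect_equal(res$modified_fraction, 2 / 6)
  # substitution-counting mode flips the near-cut substitution only
  res2 <- call_amplicon_indels(reads, ref, cut, count_substitutions = TRUE)
  got2 <- setNames(res2$calls$modified, res2$calls$read_id)
  expect_true(got2[["sub_near"]])
  expect_false(got2[["sub_far"]])
  expect_error(call_amplicon_indels(reads, ref, 500L), "outside")
})

test_that("planted modified fractions are recovered exactly without noise", {
  fx <- amp_fixture(); ex <- fx$ex
  nv <- make_nuclease_vector()
  mix <- mixture_amplicon(indel_fraction = 0.29, capture_fraction = 0.01)
  sim <- simulate_alleles(600, mix, ex$locus, ex$donor,
                          params = allele_params(nuclease_vector = nv),
                          seed = 17)
  rd <- simulate_reads(sim, error_free_profile("short"), n_reads = 500,
                       seed = 17, side = "5p")
  res <- call_amplicon_indels(rd$reads, fx$reference, fx$ref_cut)
  planted <- mean(rd$truth$class != "unedited")
  expect_identical(res$n_excluded, 0L)
  expect_equal(res$modified_fraction, planted)
  # shrinking the window can only decrease the modified fraction
  fr <- vapply(c(17L, 8L, 2L, 0L), function(w)
    call_amplicon_indels(rd$reads, fx$reference, fx$ref_cut,
                         window = w)$modified_fraction, 0)
  expect_true(all(diff(fr) <= 0))
  # substitution-only noise does not change the calls
  prof <- error_profile("short", sub = 0.003, ins = 0, del = 0)
  rdn <- simulate_reads(sim, prof, n_reads = 500, seed = 17, side = "5p")
  resn <- call_amplicon_indels(rdn$reads, fx$reference, fx$ref_cut)
  expect_equal(resn$modified_fraction, planted)
})

test_that("captured insertions are traced back to their vector of origin", {
  fx <- amp_fixture(); ex <- fx$ex
  nv <- make_nuclease_vector()
  vecs <- vector_ref_set(ex$donor, nv)
  set.seed(18)
  n_half <- 40L
  frag_from <- function(src, lo, hi) {
    len <- sample(12:60, 1)
    s <- sample(lo:(hi - len), 1)
    f <- substr(src, s + 1, s + len)
    if (runif(1) < 0.5) oracle_revcomp(f) else f
  }
  # fragments spanning the left ITR / inverted-site boundary carry
  # donor-specific context: attributed to the donor ITR
  donor_itr_frags <- vapply(seq_len(n_half), function(i) {
    len <- sample(30:60, 1)
    s <- sample((145 - len + 12):(145 - 12), 1)  # >= 12 bases each side
    f <- substr(ex$donor$full_sequence, s + 1, s + len)
    if (runif(1) < 0.5) oracle_revcomp(f) else f
  }, "")
  iv <- nv$itr_intervals
  cas9_int_frags <- vapply(seq_len(n_half), function(i)
    frag_from(nv$sequence, iv$end[1], iv$start[2]), "")
  labels <- classify_insertion_origins(c(donor_itr_frags, cas9_int_frags),
                                       vecs)
  expect_identical(labels[seq_len(n_half)], rep("donor_itr", n_half))
  expect_identical(labels[n_half + seq_len(n_half)],
                   rep("nuclease_internal", n_half))
  # the two vectors share identical ITRs, so a fragment from inside the
  # repeat alone ties between them and is never guessed
  pure <- substr(ex$donor$full_sequence, 41, 80)
  expect_identical(classify_insertion_origins(pure, vecs), "unknown")
  # too-short or alien sequence is unknown
  expect_identical(classify_insertion_origins("ACGTACGTA", vecs), "unknown")
  expect_error(classify_insertion_origins("ACGT", "notavectorset"))
})

test_that("window insertion extraction feeds the origin analysis end to end", {
  fx <- amp_fixture(); ex <- fx$ex
  nv <- make_nuclease_vector()
  mix <- outcome_mixture(unedited = 0.8, itr_fragment_capture = 0.1,
                         cas9_fragment_capture = 0.1)
  # fragments of 12-40 bases are always fully contained in a 200-nt read
  # that covers the junction with 50 bases on each side, so every capture
  # read yields one countable insertion
  params <- allele_params(nuclease_vector = nv, frag_min = 12L,
                          frag_max = 40L)
  sim <- simulate_alleles(200, mix, ex$locus, ex$donor, params, seed = 19)
  rd <- simulate_reads(sim, error_free_profile("short"), n_reads = 200,
                       seed = 19, side = "5p")
  ins <- extract_window_insertions(rd$reads, fx$reference, fx$ref_cut,
                                   min_len = 10L)
  planted <- sum(rd$truth$class %in%
                   c("itr_fragment_capture", "cas9_fragment_capture") &
                   rd$truth$junction_3p - rd$truth$junction_5p > 10)
  expect_identical(nrow(ins), planted)
  vecs <- vector_ref_set(ex$donor, nv)
  labels <- classify_insertion_origins(ins, vecs)
  truth_class <- rd$truth$class[match(ins$read_id, rd$truth$read_id)]
  # nuclease-internal fragments are unambiguous
  expect_true(all(labels[truth_class == "cas9_fragment_capture"] ==
                    "nuclease_internal"))
  # donor ITR fragments land on an ITR; pure-repeat fragments tie between
  # the two vectors and are reported unknown rather than guessed
  donor_lab <- labels[truth_class == "itr_fragment_capture"]
  expect_true(all(donor_lab %in% c("donor_itr", "unknown")))
})

test_that("two-stage short-read ITR frequency recovers planted content", {
  fx <- amp_fixture(); ex <- fx$ex
  hiti_ref <- ex$refs$sequence[ex$refs$label == "hiti_forward_5p"]
  # 100 error-free reads, 10 carrying a 20-nt ITR fragment at the junction
  set.seed(20)
  cut_in_ref <- 250L
  clean <- vapply(1:90, function(i) {
    s <- sample(0:100, 1)
    substr(hiti_ref, s + 1, s + 400)
  }, "")
  itr20 <- substr(ex$itr$sequence, 41, 60)
  planted <- vapply(1:10, function(i) {
    paste0(substr(hiti_ref, cut_in_ref - 180 + 1, cut_in_ref), itr20,
           substr(hiti_ref, cut_in_ref + 1, cut_in_ref + 180))
  }, "")
  reads <- data.frame(read_id = sprintf("r%03d", 1:100),
                      sequence = c(clean, planted),
                      stringsAsFactors = FALSE)
  q <- quantify_itr_short_reads(reads, hiti_ref, ex$itr)
  expect_identical(q$n_mapped, 100L)
  expect_equal(q$frequency, 0.10)
  # no planted ITR: frequency 0
  q0 <- quantify_itr_short_reads(reads[1:90, ], hiti_ref, ex$itr)
  expect_equal(q0$frequency, 0)
  # order invariance
  qs <- quantify_itr_short_reads(reads[sample(100), ], hiti_ref, ex$itr)
  expect_equal(qs$frequency, 0.10)
  # zero mapped reads: undefined frequency, reported as such
  junk <- data.frame(read_id = "x", sequence = random_dna(150))
  qna <- quantify_itr_short_reads(junk, hiti_ref, ex$itr)
  expect_true(is.na(qna$frequency))
  expect_identical(qna$n_unmapped, 1L)
})
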