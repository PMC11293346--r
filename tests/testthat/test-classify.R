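test_that("windowed insertion counting respects window and length bounds", {
  set.seed(12)
  ref <- random_dna(800)
  jc <- 400L
  plant <- function(pos, len) {
    read <- paste0(substr(ref, 1, pos), random_dna(len),
                   substr(ref, pos + 1, 800))
    align_semiglobal(read, ref)
  }
  # 15-nt insertion anchored 150 bp from the junction: counted
  a <- plant(jc - 150L, 15L)
  expect_identical(nrow(count_window_insertions(a, jc, 800L)), 1L)
  # anchored 250 bp away: outside the 200 bp window
  a <- plant(jc - 250L, 15L)
  expect_identical(nrow(count_window_insertions(a, jc, 800L)), 0L)
  # 9-nt insertion at the junction: below the >9 bp length floor
  a <- plant(jc, 9L)
  expect_identical(nrow(count_window_insertions(a, jc, 800L)), 0L)
  # but counted when the floor is lowered
  expect_identical(nrow(count_window_insertions(a, jc, 800L, min_len = 5L)),
                   1L)
  expect_error(count_window_insertions(a, 900L, 800L), "outside")
})

test_that("ITR content detection honours the >9 bp boundary", {
  itr <- aav2_itr()
  # 20-nt exact ITR substring: flagged, >= 20 bases matched
  seg <- substr(itr$sequence, 31, 50)
  hit <- detect_itr_content(seg, itr)
  expect_true(hit$flag)
  expect_true(hit$matched_bases >= 20L)
  # reverse complement is found too
  hit_rc <- detect_itr_content(oracle_revcomp(seg), itr)
  expect_true(hit_rc$flag)
  # 9 exact ITR bases: below the floor
  hit9 <- detect_itr_content(substr(itr$sequence, 31, 39), itr)
  expect_false(hit9$flag)
  expect_true(hit9$matched_bases <= 9L)
  # empty segment: no content
  expect_false(detect_itr_content("", itr)$flag)
})

test_that("ITR flags agree with an exhaustive score bound on random segments", {
  # any alignment covering >= 10 ITR bases at >= 90% identity scores at
  # least 12 under match +2 / mismatch -4 / gaps 4+2 (worst case 9 matches,
  # 1 mismatch), so a Biostrings local score < 12 proves the flag must be
  # off, while a planted exact >= 10-mer forces it on
  set.seed(9)
  toy_itr <- itr_element(random_dna(40), "toy")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  bio_local <- function(a, b)
    max(vapply(c(b, oracle_revcomp(b)), function(s)
      as.integer(Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a), Biostrings::DNAString(s), type = "local",
        substitutionMatrix = mat, gapOpening = 4, gapExtension = 2,
        scoreOnly = TRUE)), 0L))
  n_on <- 0L; n_off <- 0L
  for (i in 1:30) {
    if (i %% 3 == 0) {
      k <- sample(10:25, 1); s0 <- sample(1:(40 - k + 1), 1)
      seg <- paste0(random_dna(15), substr(toy_itr$sequence, s0, s0 + k - 1),
                    random_dna(35 - k))
      expect_true(detect_itr_content(seg, toy_itr)$flag)
      n_on <- n_on + 1L
    } else {
      seg <- random_dna(50)
      if (bio_local(seg, toy_itr$sequence) < 12L) {
        expect_false(detect_itr_content(seg, toy_itr)$flag)
        n_off <- n_off + 1L
      }
    }
  }
  expect_true(n_on >= 8L && n_off >= 10L)
})

test_that("error-free reads of every planted class get the expected call", {
  ex <- toy_experiment()
  nv <- make_nuclease_vector()
  params <- allele_params(nuclease_vector = nv)
  cases <- list(
    c("unedited", "unedited"),
    c("hiti_forward", "hiti_clean"),
    c("hiti_reverse", "reverse_orientation"),
    c("itr_retained_forward", "itr_containing"),
    c("itr_retained_reverse", "itr_containing"),
    c("itr_fragment_capture", "itr_containing"),
    c("nhej_indel", "nhej_indel"))
  for (side in c("5p", "3p")) {
    for (cs in cases) {
      a <- simulate_allele(cs[1], ex$locus, ex$donor, params, rng_seed = 42)
      j <- if (side == "5p") a$junction_5p else a$junction_3p
      read <- substr(a$sequence, j - 300 + 1, j + 300)
      cl <- classify_read(read, ex$refs, ex$itr, side = side,
                          thresholds = strict_thresholds())
      expect_identical(cl$class, cs[2],
                       info = paste(cs[1], side))
      if (cs[2] == "itr_containing")
        expect_true(cl$itr_bases >= 10L, info = paste(cs[1], side))
      else
        expect_identical(cl$itr_bases, 0L, info = paste(cs[1], side))
      # orientation symmetry: the reverse complement gets the same class
      cl_rc <- classify_read(oracle_revcomp(read), ex$refs, ex$itr,
                             side = side, thresholds = strict_thresholds())
      expect_identical(cl_rc$class, cl$class, info = paste(cs[1], side))
    }
  }
  expect_error(classify_read("ACGT", ex$refs[0, ], ex$itr), "empty")
})

test_that("junk reads fall back to unassigned rather than forced calls", {
  ex <- toy_experiment()
  set.seed(14)
  cl <- classify_read(random_dna(500), ex$refs, ex$itr, side = "5p")
  expect_identical(cl$class, "unassigned")
  # a read that misses the junction window entirely is unassigned
  far <- substr(ex$locus$sequence, 1, 260)  # locus start, far from the cut
  cl2 <- classify_read(far, ex$refs, ex$itr, side = "5p")
  expect_identical(cl2$class, "unassigned")
})

test_that("raising ITR thresholds never increases the itr_containing count", {
  ex <- toy_experiment()
  mix <- outcome_mixture(hiti_forward = 0.7, itr_retained_forward = 0.2,
                         itr_fragment_capture = 0.1)
  sim <- simulate_alleles(60, mix, ex$locus, ex$donor, seed = 15)
  rd <- simulate_reads(sim, error_profile("long"), n_reads = 60, seed = 15,
                       side = "5p", flank_up = 280, flank_down = 280)
  count_itr <- function(min_bases, min_insertion) {
    th <- classify_thresholds(itr_min_bases = min_bases,
                              min_insertion = min_insertion)
    cl <- classify_reads(rd$reads, ex$refs, ex$itr, side = "5p",
                         thresholds = th)
    sum(cl$class == "itr_containing")
  }
  by_bases <- vapply(c(10L, 20L, 40L, 80L, 160L),
                     function(b) count_itr(b, 10L), 0L)
  expect_true(all(diff(by_bases) <= 0))
  by_len <- vapply(c(10L, 20L, 40L, 80L, 160L),
                   function(l) count_itr(10L, l), 0L)
  expect_true(all(diff(by_len) <= 0))
})

test_that("per-side summaries report both denominators and sum to one", {
  cl <- data.frame(
    read_id = sprintf("r%02d", 1:10), side = "5p",
    class = c(rep("hiti_clean", 6), rep("itr_containing", 2),
              "nhej_indel", "unassigned"),
    stringsAsFactors = FALSE)
  s <- summarize_junctions(cl)
  cls <- s[s$class != "unassigned", ]
  expect_equal(sum(cls$fraction), 1, tolerance = 1e-12)
  expect_equal(cls$fraction[cls$class == "itr_containing"], 2 / 9)
  expect_equal(s$fraction_incl_unassigned[s$class == "itr_containing"],
               0.2)
  expect_true(is.na(s$fraction[s$class == "unassigned"]))
  # single-class input gives fraction 1
  s1 <- summarize_junctions(data.frame(read_id = "a", side = "3p",
                                       class = "hiti_clean"))
  expect_equal(s1$fraction, 1)
  # all-unassigned input does not divide by zero
  s2 <- summarize_junctions(data.frame(read_id = c("a", "b"), side = "5p",
                                       class = "unassigned"))
  expect_true(all(is.na(s2$fraction)))
  expect_error(summarize_junctions(cl[0, ]), "no classifications")
})

test_that("a planted 3% retained fraction is recovered exactly without noise", {
  ex <- toy_experiment()
  # plant exactly 3% at the allele level to mirror the 3' junction
  classes <- c(rep("itr_retained_forward", 3), rep("hiti_forward", 97))
  sims <- lapply(seq_along(classes), function(i)
    simulate_allele(classes[i], ex$locus, ex$donor, rng_seed = i))
  sim <- list(sequences = vapply(sims, `[[`, "", "sequence"),
              truth = data.frame(
                allele_id = sprintf("a%03d", seq_along(sims)),
                class = classes,
                junction_5p = vapply(sims, `[[`, 0, "junction_5p"),
                junction_3p = vapply(sims, `[[`, 0, "junction_3p"),
                itr_bases = vapply(sims, `[[`, 0L, "itr_bases")))
  reads <- data.frame(
    read_id = sim$truth$allele_id,
    sequence = vapply(seq_along(sims), function(i)
      substr(sim$sequences[i], sim$truth$junction_3p[i] - 300 + 1,
             sim$truth$junction_3p[i] + 300), ""),
    stringsAsFactors = FALSE)
  cl <- classify_reads(reads, ex$refs, ex$itr, side = "3p",
                       thresholds = strict_thresholds())
  s <- summarize_junctions(cl)
  expect_equal(s$fraction[s$class == "itr_containing"], 0.03)
  expect_equal(s$fraction[s$class == "hiti_clean"], 0.97)
})
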