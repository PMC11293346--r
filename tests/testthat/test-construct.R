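test_that("guide validation and cut position follow the blunt-cut convention", {
  expect_silent(guide_site("GTATTTAATAGGCAGCAGTG", "AGG"))
  expect_error(guide_site("GTATTTAATAGGCAGCAGT", "AGG"), "20 nt")
  expect_error(guide_site("GTATTTAATAGGCAGCAGTG", "ATT"), "NGG")
  expect_error(guide_site("GTATTTAATAGGCAGCAGTG", "AGG", cut_offset = 25),
               "cut_offset")

  # + strand: protospacer at [100,120), default offset 17 -> cut at 117
  set.seed(1)
  proto <- "GTATTTAATAGGCAGCAGTG"
  bg <- random_dna(300)
  seq_plus <- paste0(substr(bg, 1, 100), proto, "AGG", substr(bg, 124, 300))
  loc <- target_locus(seq_plus, guide_site(proto, "AGG", "+", 100))
  expect_identical(cut_position(loc), 117L)

  # wrong coordinate is a validation error
  expect_error(target_locus(seq_plus, guide_site(proto, "AGG", "+", 99)),
               "not found")

  # - strand: mirror against a string-reversal oracle.  Embed the site on
  # the minus strand, build the reverse-complemented locus where the guide
  # reads on +, and check the two cut coordinates mirror each other.
  site_rc <- oracle_revcomp(paste0(proto, "AGG"))  # PAM-first on + strand
  seq_minus <- paste0(substr(bg, 1, 80), site_rc, substr(bg, 104, 300))
  # protospacer leftmost base on + strand is 80 + 3
  loc_minus <- target_locus(seq_minus, guide_site(proto, "AGG", "-", 83))
  L <- nchar(seq_minus)
  loc_flip <- target_locus(oracle_revcomp(seq_minus),
                           guide_site(proto, "AGG", "+", L - 83 - 20))
  expect_identical(cut_position(loc_minus), L - cut_position(loc_flip))
})

test_that("donor elements tile the construct and carry inverted target sites", {
  ex <- toy_experiment()
  donor <- ex$donor
  el <- donor$elements
  # contiguous, non-overlapping, tiling
  expect_identical(el$start, c(0L, head(el$end, -1)))
  expect_identical(paste(el$sequence, collapse = ""), donor$full_sequence)
  expect_identical(sum(nchar(el$sequence)), nchar(donor$full_sequence))
  # both inverted sites equal revcomp(protospacer+PAM)
  g <- donor$guide
  inv <- oracle_revcomp(paste0(g$protospacer, g$pam))
  expect_identical(el$sequence[el$label == "left_inverted_site"], inv)
  expect_identical(el$sequence[el$label == "right_inverted_site"], inv)
  # round-trip: slicing full_sequence by coordinates recovers each element
  for (i in seq_len(nrow(el)))
    expect_identical(substr(donor$full_sequence, el$start[i] + 1, el$end[i]),
                     el$sequence[i])
  # non-ACGT payload rejected
  expect_error(build_donor(list(cds = "ACGU"), g, ex$itr), "alphabet")
})

test_that("junction references match direct string construction", {
  ex <- toy_experiment()
  locus <- ex$locus; donor <- ex$donor; refs <- ex$refs
  cut <- cut_position(locus)
  up <- substr(locus$sequence, cut - 250 + 1, cut)
  down <- substr(locus$sequence, cut + 1, cut + 250)
  core <- donor_core(donor)
  full <- donor$full_sequence

  # independent concatenation oracle for the forward 5' junction
  expect_identical(refs$sequence[refs$label == "hiti_forward_5p"],
                   paste0(up, substr(core, 1, 250)))
  expect_identical(refs$sequence[refs$label == "itr_retained_forward_5p"],
                   paste0(up, substr(full, 1, 250)))
  expect_identical(refs$sequence[refs$label == "unedited_5p"],
                   paste0(up, down))
  # reverse classes are built from the reverse complement of the donor part
  expect_identical(refs$sequence[refs$label == "hiti_reverse_5p"],
                   paste0(up, substr(oracle_revcomp(core), 1, 250)))

  # lengths are additive: untruncated retained reference exceeds the
  # forward one by exactly the two retained vector arms (ITR + residual
  # inverted site on each side); the left arm is ITR + 6 nt residual
  wide <- build_expected_junctions(locus, donor, flank_locus = 100,
                                   flank_donor = nchar(full))
  len_ret <- nchar(wide$sequence[wide$label == "itr_retained_forward_5p"])
  len_fwd <- nchar(wide$sequence[wide$label == "hiti_forward_5p"])
  cp <- donor_cut_points(donor)
  left_arm <- cp[["left"]]
  right_arm <- nchar(full) - cp[["right"]]
  expect_identical(len_ret - len_fwd, as.integer(left_arm + right_arm))
  expect_identical(as.integer(left_arm), nchar(ex$itr$sequence) + 6L)

  # forward-HITI junction destroys the protospacer+PAM site
  site <- paste0(locus$guide$protospacer, locus$guide$pam)
  fwd5 <- refs$sequence[refs$label == "hiti_forward_5p"]
  expect_false(grepl(site, fwd5, fixed = TRUE))
  expect_false(grepl(site, refs$sequence[refs$label == "hiti_forward_3p"],
                     fixed = TRUE))
  # ITR-retained references carry >= 10 consecutive ITR bases within
  # 200 bp of the junction
  ret5 <- refs$sequence[refs$label == "itr_retained_forward_5p"]
  jc <- refs$junction_coord[refs$label == "itr_retained_forward_5p"]
  near <- substr(ret5, jc + 1, jc + 200)
  expect_true(grepl(substr(ex$itr$sequence, 1, 10), near, fixed = TRUE))
})

test_that("junction reference sets round-trip through FASTA and donor BED is valid", {
  ex <- toy_experiment()
  fa <- tempfile(fileext = ".fa")
  write_junction_fasta(ex$refs, fa)
  back <- read_junction_fasta(fa)
  expect_identical(back$sequence, ex$refs$sequence)
  expect_identical(back$label, ex$refs$label)
  expect_identical(back$junction_coord, as.integer(ex$refs$junction_coord))

  bed <- tempfile(fileext = ".bed")
  write_donor_bed(ex$donor, bed)
  tab <- read.delim(bed, header = FALSE)
  expect_identical(nrow(tab), nrow(ex$donor$elements))
  expect_true(all(tab$V2 < tab$V3))
  expect_identical(tab$V3[nrow(tab)], nchar(ex$donor$full_sequence))
})

test_that("T2A skipping products split at the glycine-proline boundary", {
  ex <- toy_experiment()
  pp <- predict_processed_products(ex$donor)
  expect_identical(substr(pp$downstream, 1, 1), "P")
  expect_true(grepl("G$", pp$upstream))
  # codon-table oracle for the downstream product
  cds <- ex$donor$elements$sequence[ex$donor$elements$label == "cds"]
  expect_identical(pp$downstream, paste0("P", oracle_translate(cds)))
  # empty CDS degenerates to the single proline marker
  d2 <- build_donor(list(sas = "ACGTACGT", t2a = hitiseq:::t2a_cds(),
                         cds = ""), ex$locus$guide, ex$itr)
  expect_identical(predict_processed_products(d2)$downstream, "P")
  # no T2A element is an error
  d3 <- build_donor(list(sas = "ACGTACGT", cds = "ATGGCC"),
                    ex$locus$guide, ex$itr)
  expect_error(predict_processed_products(d3), "T2A")
})

test_that("strand symmetry: mirrored constructs give reverse-complement references", {
  # building junctions from the reverse-complemented locus with the
  # mirrored guide yields the reverse complements of the + strand refs
  ex <- toy_experiment()
  locus <- ex$locus; donor <- ex$donor
  L <- nchar(locus$sequence)
  g <- locus$guide
  flip <- target_locus(oracle_revcomp(locus$sequence),
                       guide_site(g$protospacer, g$pam, "-",
                                  L - g$start - 20L))
  expect_identical(cut_position(flip), L - cut_position(locus))
  refs <- build_expected_junctions(locus, donor, 150, 150)
  refs_flip <- build_expected_junctions(flip, donor, 150, 150)
  # the 5' junction of the flipped locus is the revcomp of the + 3' one
  for (cls in c("hiti_forward", "itr_retained_forward", "unedited")) {
    a <- refs$sequence[refs$label == paste0(cls, "_3p")]
    b <- refs_flip$sequence[refs_flip$label ==
      paste0(sub("forward", "reverse", cls), "_5p")]
    if (cls == "unedited") b <- refs_flip$sequence[refs_flip$label == "unedited_5p"]
    expect_identical(oracle_revcomp(a), b)
  }
})
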