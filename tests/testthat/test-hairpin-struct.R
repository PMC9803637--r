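# A fixed synthetic 15-nt flank pair stands in for user-supplied genomic
# context in full-construct direction checks; it is not the real flank.
SYNTH_FLANK5 <- "GGAUCCAUGGCUACC"
SYNTH_FLANK3 <- "GGUACCAUCGGAUCC"

test_that("variant specs expand deterministically to the printed formulas", {
  ref <- build_variant(htt_repeat_spec("ref"))
  loi <- build_variant(htt_repeat_spec("loi"))
  expect_equal(nchar(ref), 40 * 3 + 6 + 6 + 7 * 3)  # 153
  expect_equal(nchar(loi), 153)
  # the two alleles differ at exactly two positions, both A -> G
  rc <- strsplit(ref, "")[[1]]
  lc <- strsplit(loi, "")[[1]]
  diff <- which(rc != lc)
  expect_length(diff, 2)
  expect_equal(unique(rc[diff]), "A")
  expect_equal(unique(lc[diff]), "G")
  # a pure (CAG)x7 spec reproduces the synthesized control oligo exactly
  cag7 <- build_variant(variant_spec("cag7", list(list(seq = "CAG", times = 7))))
  expect_equal(cag7, unname(hairpin_oligos()["CtrHP_CAG7"]))
  # flanks are prepended/appended verbatim
  flanked <- build_variant(htt_repeat_spec("ref", flank5 = SYNTH_FLANK5,
                                           flank3 = SYNTH_FLANK3))
  expect_equal(nchar(flanked), 153 + 30)
  expect_equal(substr(flanked, 1, 15), SYNTH_FLANK5)
})

test_that("folding returns a valid MFE structure with recorded settings", {
  s <- fold("GGGGAAAACCCC")
  expect_s3_class(s, "hairpin_structure")
  expect_equal(s$dot_bracket, "((((....))))")
  expect_lt(s$delta_g, 0)
  expect_equal(nrow(s$pair_table), 4)
  expect_true(all(s$pair_table$i < s$pair_table$j))
  expect_match(s$engine, "RNAfold")
  expect_equal(s$settings$parameter_set, "rna_turner1999")
  # folding is deterministic under fixed settings and engine
  expect_identical(fold("GGGGAAAACCCC"), s)
})

test_that("a pair-free sequence folds to the open chain at zero energy", {
  s <- fold("AAAAAAAAAAAA")
  expect_equal(s$dot_bracket, strrep(".", 12))
  expect_equal(s$delta_g, 0)
  expect_equal(nrow(s$pair_table), 0)
  expect_equal(longest_uninterrupted_cag_stem(s), 0)
})

test_that("dot-bracket parsing validates balance and nesting", {
  pt <- parse_dot_bracket("((..))")
  expect_equal(pt$i, c(0, 1))
  expect_equal(pt$j, c(5, 4))
  expect_error(parse_dot_bracket("(()"), "unbalanced")
  expect_error(parse_dot_bracket("())"), "unbalanced")
  expect_error(parse_dot_bracket("(a)"), "may only contain")
})

test_that("stem segmentation tolerates 1x1 loops and splits at bulges", {
  # perfect helix: one segment of 4 pairs
  seg <- stem_segments(parse_dot_bracket("((((....))))"))
  expect_equal(unique(seg$segment), 1)
  expect_equal(nrow(seg), 4)

  # a single 1x1 interior mismatch stays one segment of 6 pairs
  seg2 <- stem_segments(parse_dot_bracket("(((.(((....))).)))"))
  expect_equal(unique(seg2$segment), 1)
  expect_equal(nrow(seg2), 6)

  # a 3-nt bulge splits the helix into two segments
  seg3 <- stem_segments(parse_dot_bracket("(((...(((....)))...)))"))
  expect_equal(max(seg3$segment), 2)

  # segmentation partitions the pair set
  expect_equal(sum(table(seg3$segment)), nrow(seg3))
  expect_false(any(duplicated(seg3[c("i", "j")])))
})

test_that("segmentation is invariant to pair-table row order", {
  db <- "(((.(((....))).)))..((((...))))"
  pt <- parse_dot_bracket(db)
  shuffled <- pt[sample(nrow(pt)), ]
  expect_equal(stem_segments(pt), stem_segments(shuffled))
})

test_that("CAG units count only when C and G pair within one segment", {
  hp <- fold(hairpin_oligos()["CtrHP_CAG12"])
  got <- longest_uninterrupted_cag_stem(hp)
  # independent scan: for every CAG triplet on the 5' arm of each segment,
  # check that its C and G positions are both paired in that segment
  seg <- stem_segments(hp)
  ch <- strsplit(hp$sequence, "")[[1]]
  want <- 0L
  for (sid in unique(seg$segment)) {
    left <- seg$i[seg$segment == sid]
    units <- 0L
    for (c0 in min(left):max(left)) {
      if (c0 + 2 > max(left)) next
      if (paste(ch[(c0 + 1):(c0 + 3)], collapse = "") == "CAG" &&
          c0 %in% left && (c0 + 2) %in% left)
        units <- units + 1L
    }
    want <- max(want, units)
  }
  expect_equal(got, want)
  expect_gt(got, 0)
})

test_that("printed hairpin variants order by stability as expected", {
  oligos <- hairpin_oligos()
  tab <- compare_variants(oligos[c("Ref_HP", "LOI_HP", "AR_HP_3_9",
                                   "AR_HP_3_17")])
  dg <- setNames(tab$delta_g, tab$name)
  stem <- setNames(tab$longest_cag_stem, tab$name)
  # the LOI allele mimetic is more stable with a longer CAG stem
  expect_lt(dg[["LOI_HP"]], dg[["Ref_HP"]])
  expect_gt(stem[["LOI_HP"]], stem[["Ref_HP"]])
  # the 17-repeat AR hairpin is more stable than the 9-repeat one
  expect_lt(dg[["AR_HP_3_17"]], dg[["AR_HP_3_9"]])
  # duplicated input gives identical rows
  tab2 <- compare_variants(c(a = oligos[["Ref_HP"]], b = oligos[["Ref_HP"]]))
  expect_equal(tab2$delta_g[1], tab2$delta_g[2])
  expect_equal(tab2$dot_bracket[1], tab2$dot_bracket[2])
})

test_that("pure-CAG control hairpin stability grows with repeat count", {
  oligos <- hairpin_oligos()
  ctr <- oligos[grep("^CtrHP", names(oligos))]
  dg <- vapply(ctr, function(s) fold(s)$delta_g, numeric(1))
  expect_true(all(diff(dg) <= 0))  # ordered CAG7 .. CAG40
})

test_that("full-length constructs with flanks keep the allele ordering", {
  rep_full <- htt_stem_report(SYNTH_FLANK5, SYNTH_FLANK3)
  expect_equal(rep_full$variant, c("ref", "loi"))
  expect_lt(rep_full$delta_g[2], rep_full$delta_g[1])
  expect_gt(rep_full$longest_cag_stem[2], rep_full$longest_cag_stem[1])
  expect_equal(rep_full$expected, c(15, 25))
  expect_type(rep_full$matches_expected, "logical")
})
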