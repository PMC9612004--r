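test_that("coding exon extraction respects strand and CDS offsets", {
  seqs <- c(c1 = "GTAAGCCTAA", c2 = "GTAC")
  g_plus <- gene_model("gp", "c1", "+", rbind(c(0L, 5L)))
  ex <- extract_coding_exons(list(g_plus), seqs)
  expect_equal(ex$sequence, "GTAAG")
  expect_equal(ex$cds_offset, 0L)
  expect_equal(ex$position_class, "single")

  # palindromic minus-strand check: revcomp("GTAC") == "GTAC"
  g_minus <- gene_model("gm", "c2", "-", rbind(c(0L, 4L)))
  expect_equal(extract_coding_exons(list(g_minus), seqs)$sequence, "GTAC")

  g3 <- gene_model("g3", "c1", "+",
                   rbind(c(0L, 3L), c(4L, 6L), c(7L, 10L)))
  ex3 <- extract_coding_exons(list(g3), seqs)
  expect_equal(ex3$position_class, c("first", "internal", "last"))
  expect_equal(ex3$cds_offset, c(0L, 3L, 5L))

  g_bad <- gene_model("gb", "c2", "+", rbind(c(0L, 9L)))
  expect_error(extract_coding_exons(list(g_bad), seqs), "bounds")
})

test_that("minus-strand exons come out 5'->3' in transcription order", {
  # chrom: exon2(rc) then exon1(rc); transcript = "ATGGTT" + "CCA"
  tx_exon1 <- "ATGGTT"; tx_exon2 <- "CCA"
  chrom <- paste0(revcomp(tx_exon2), "NN", revcomp(tx_exon1))
  g <- gene_model("gm", "c", "-", rbind(c(0L, 3L), c(5L, 11L)))
  ex <- extract_coding_exons(list(g), c(c = chrom))
  expect_equal(ex$sequence, c(tx_exon1, tx_exon2))
  expect_equal(ex$cds_offset, c(0L, 6L))
})

test_that("GT|AG enumeration matches the worked single-segment cases", {
  s1 <- enumerate_gt_ag_segments("GTATTTTTTTTTTTAG")
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$length, 16L)
  expect_equal(s1$signal_class, "GTA|TAG")
  expect_equal(s1$mod3_class, "3n+1")

  s2 <- enumerate_gt_ag_segments(paste0("GT", strrep("A", 11), "AG"))
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$length, 15L)
  expect_equal(s2$signal_class, "GTA|nAG")
  expect_equal(s2$mod3_class, "3n")

  expect_equal(nrow(enumerate_gt_ag_segments("GTAAG")), 0L)
})

test_that("enumeration equals the exhaustive quadratic oracle", {
  set.seed(101)
  for (i in 1:200) {
    L <- sample(10:100, 1)
    s <- random_dna_str(L, at = runif(1, 0.4, 0.8))
    got <- enumerate_gt_ag_segments(s)
    want <- brute_force_segments(s)
    expect_equal(got[, c("start", "end", "length")], want,
                 ignore_attr = TRUE)
  }
})

test_that("antisense enumeration is sense enumeration of the revcomp", {
  set.seed(7)
  for (i in 1:50) {
    s <- random_dna_str(sample(20:80, 1), at = 0.7)
    a <- enumerate_gt_ag_segments(revcomp(s), strand = "sense")
    b <- enumerate_gt_ag_segments(s, strand = "antisense")
    expect_equal(a[, c("start", "end", "length", "signal_class",
                       "mod3_class")],
                 b[, c("start", "end", "length", "signal_class",
                       "mod3_class")], ignore_attr = TRUE)
  }
})

test_that("signal classes partition segments and survive re-extraction", {
  set.seed(33)
  s <- random_dna_str(4000, at = 0.72)
  seg <- enumerate_gt_ag_segments(s)
  expect_gt(nrow(seg), 0L)
  expect_equal(sum(table(seg$signal_class)), nrow(seg))
  expect_equal(sum(table(seg$mod3_class)), nrow(seg))
  for (k in seq_len(min(nrow(seg), 200L))) {
    sub <- substr(s, seg$start[k] + 1L, seg$end[k])
    cl <- classify_segment(sub)
    expect_equal(cl$signal_class, seg$signal_class[k])
    expect_equal(cl$mod3_class, seg$mod3_class[k])
  }
})

test_that("segment classification handles the three signal examples", {
  expect_equal(classify_segment(paste0("GTA", strrep("T", 21), "TAG")),
               list(signal_class = "GTA|TAG", mod3_class = "3n"))
  expect_equal(classify_segment(paste0("GTG", strrep("T", 16), "TAG")),
               list(signal_class = "GTn|TAG", mod3_class = "3n+1"))
  expect_equal(classify_segment(paste0("GTA", strrep("T", 14), "CAG")),
               list(signal_class = "GTA|nAG", mod3_class = "3n+2"))
  expect_error(classify_segment("GTAAA"), "shorter")
  expect_error(classify_segment("TTATTTTTTAG"), "start with GT")
})

test_that("segment_table maps sense segments to genomic coordinates", {
  # plus strand: one GTA|TAG segment planted at exon-local offset 4
  planted <- paste0("GTA", strrep("T", 12), "TAG")      # 18 nt
  exon_seq <- paste0("CCCC", planted, "CCCC")
  chrom <- paste0("AAAAA", exon_seq, "AAAAA")
  gp <- gene_model("gp", "c", "+", rbind(c(5L, 5L + nchar(exon_seq))))
  ex <- extract_coding_exons(list(gp), c(c = chrom))
  seg <- segment_table(ex)
  sense <- seg[seg$strand == "sense" & seg$signal_class == "GTA|TAG", ]
  expect_equal(sense$g_start, 5L + 4L)
  expect_equal(sense$g_end, 5L + 4L + 18L)
  expect_equal(sense$cds_start, 4L)

  # minus strand: same transcript placed reverse-complemented
  chromm <- paste0("AAAAA", revcomp(exon_seq), "AAAAA")
  gm <- gene_model("gm", "c", "-", rbind(c(5L, 5L + nchar(exon_seq))))
  exm <- extract_coding_exons(list(gm), c(c = chromm))
  segm <- segment_table(exm)
  sm <- segm[segm$strand == "sense" & segm$signal_class == "GTA|TAG", ]
  # genomic interval mirrors within the exon
  expect_equal(sm$g_end, 5L + nchar(exon_seq) - 4L)
  expect_equal(sm$g_start, sm$g_end - 18L)
  expect_equal(sm$cds_start, 4L)
})

test_that("flank windows are exonic, truncated, and transcription-sense", {
  seqs <- c(c = paste0(strrep("A", 20), "GTTTTTTTAG", strrep("C", 20)))
  g <- gene_model("g", "c", "+", rbind(c(0L, 20L), c(30L, 50L)))
  w <- intron_flank_windows(g, 1L, seqs)
  expect_equal(w$upstream, strrep("A", 15))
  expect_equal(w$downstream, strrep("C", 15))
  expect_false(w$upstream_truncated)

  g2 <- gene_model("g2", "c", "+", rbind(c(13L, 20L), c(30L, 50L)))
  w2 <- intron_flank_windows(g2, 1L, seqs)
  expect_equal(nchar(w2$upstream), 7L)
  expect_true(w2$upstream_truncated)

  # minus-strand gene: windows come from the transcription-sense sequence
  gm <- gene_model("gm", "c", "-", rbind(c(0L, 20L), c(30L, 50L)))
  wm <- intron_flank_windows(gm, 1L, seqs)
  expect_equal(wm$upstream, strrep("G", 15))   # rc of the C-run exon
  expect_equal(wm$downstream, strrep("T", 15)) # rc of the A-run exon
  expect_error(intron_flank_windows(g, 5L, seqs), "range")
})
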