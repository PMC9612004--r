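jrow <- function(donor, acceptor, reads = 1L, annotated = FALSE,
                 chrom = "c1") {
  data.frame(chrom = chrom, donor = as.integer(donor),
             acceptor = as.integer(acceptor), strand = "+", motif = 1L,
             annotated = annotated, unique_reads = as.integer(reads),
             multi_reads = 0L, overhang = 30L, stringsAsFactors = FALSE)
}

test_that("junction clustering links on shared donor xor acceptor", {
  j <- rbind(jrow(100, 125), jrow(100, 131))
  expect_equal(length(unique(group_alternative_junctions(j)$cluster)), 1L)

  j2 <- rbind(jrow(100, 125), jrow(200, 225))
  expect_equal(length(unique(group_alternative_junctions(j2)$cluster)), 2L)

  # transitive chain through shared donor then shared acceptor
  j3 <- rbind(jrow(100, 125), jrow(100, 131), jrow(90, 131))
  expect_equal(length(unique(group_alternative_junctions(j3)$cluster)), 1L)

  # identical coordinates are the same junction, not an alternative
  j4 <- rbind(jrow(100, 125, 3), jrow(100, 125, 4), jrow(300, 325))
  cl <- group_alternative_junctions(j4)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_equal(length(unique(cl$cluster)), 2L)
})

test_that("retention counting requires full span and dedupes mate pairs", {
  locus <- list(start = 100L, end = 125L)
  reads <- data.frame(start = c(90L, 100L), end = c(130L, 120L),
                      read_id = c("r1", "r2"),
                      pair_id = c(NA, NA), stringsAsFactors = FALSE)
  expect_equal(count_retention(reads, locus), 1L)

  mates <- data.frame(start = c(90L, 95L), end = c(130L, 140L),
                      read_id = c("r1a", "r1b"),
                      pair_id = c("p1", "p1"), stringsAsFactors = FALSE)
  expect_equal(count_retention(mates, locus), 1L)

  # monotonicity: extending a read interval never loses support
  set.seed(4)
  for (i in 1:50) {
    s <- sample(50:120, 1); e <- s + sample(5:80, 1)
    r <- data.frame(start = s, end = e, read_id = "r", pair_id = NA)
    r_ext <- data.frame(start = s - 5L, end = e + 5L, read_id = "r",
                        pair_id = NA)
    expect_gte(count_retention(r_ext, locus), count_retention(r, locus))
  }
})

test_that("locus profiles: proportions, conservation, coverage flag", {
  locus <- list(locus_id = "L1", chrom = "c1", start = 100L, end = 125L)
  j <- rbind(jrow(100, 125, 6))
  reads <- data.frame(start = rep(95L, 4), end = rep(130L, 4),
                      read_id = paste0("r", 1:4), pair_id = NA)
  p <- compute_locus_profile(locus, j, read_intervals = reads)
  expect_equal(c(p$splicing_level, p$retention_level, p$alt_usage),
               c(0.6, 0.4, 0.0))
  expect_equal(p$spliced + p$retained + p$alt, p$total)
  expect_true(p$covered)

  j2 <- rbind(jrow(100, 125, 5), jrow(100, 131, 3))
  p2 <- compute_locus_profile(locus, j2, retained_count = 2L)
  expect_equal(c(p2$splicing_level, p2$retention_level, p2$alt_usage),
               c(0.5, 0.2, 0.3))

  p3 <- compute_locus_profile(locus, jrow(100, 125, 2),
                              retained_count = 1L)
  expect_false(p3$covered)

  # alternative junctions found even when the canonical one is absent
  p4 <- compute_locus_profile(locus, jrow(100, 131, 7),
                              retained_count = 3L)
  expect_equal(p4$alt, 7L)
  expect_equal(p4$spliced, 0L)
})

test_that("interval path and count path produce identical profiles", {
  locus <- list(locus_id = "L1", chrom = "c1", start = 100L, end = 125L)
  j <- rbind(jrow(100, 125, 5), jrow(90, 125, 2))
  reads <- data.frame(start = c(95L, 96L, 99L), end = c(130L, 131L, 126L),
                      read_id = paste0("r", 1:3), pair_id = NA)
  p_int <- compute_locus_profile(locus, j, read_intervals = reads)
  p_cnt <- profiles_from_counts(data.frame(locus_id = "L1", spliced = 5L,
                                           retained = 3L, alt = 2L))
  cols <- c("spliced", "retained", "alt", "total", "splicing_level",
            "retention_level", "alt_usage", "covered")
  expect_equal(p_int[, cols], p_cnt[, cols], ignore_attr = TRUE)
})

test_that("novel junctions match segments exactly or not at all", {
  seg <- data.frame(gene_id = "g1", strand = "sense", chrom = "c1",
                    g_start = 100L, g_end = 125L, length = 25L,
                    signal_class = "GTA|TAG", mod3_class = "3n+1",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(match_novel_junctions_to_segments(
    seg, jrow(100, 125, 4))), 1L)
  expect_equal(match_novel_junctions_to_segments(
    seg, jrow(100, 125, 4))$junction_reads, 4L)
  expect_equal(nrow(match_novel_junctions_to_segments(
    seg, jrow(100, 125, 4, annotated = TRUE))), 0L)
  expect_equal(nrow(match_novel_junctions_to_segments(
    seg, jrow(101, 125, 4))), 0L)

  # replicate evidence is summed
  two_reps <- rbind(jrow(100, 125, 4), jrow(100, 125, 9))
  expect_equal(match_novel_junctions_to_segments(
    seg, two_reps)$junction_reads, 13L)

  dup <- rbind(seg, seg)
  expect_error(match_novel_junctions_to_segments(dup, jrow(100, 125, 4)),
               "multiple identical segments")
})

test_that("splicing-level class summary bins, correlations, exclusions", {
  prof <- data.frame(locus_id = paste0("L", 1:40),
                     splicing_level = rep(0.05, 40), covered = TRUE,
                     mod3_class = "3n", at = 0.75,
                     stringsAsFactors = FALSE)
  s <- splicing_level_class_summary(prof)
  expect_equal(s$bins$n[1], 40L)
  expect_equal(sum(s$bins$n), 40L)

  # 3n fraction rising linearly over bins -> Pearson r = 1
  prof2 <- do.call(rbind, lapply(1:10, function(b) {
    n3 <- b; n_other <- 10 - b
    data.frame(locus_id = paste0("b", b, "_", 1:10),
               splicing_level = b / 10 - 0.05, covered = TRUE,
               mod3_class = c(rep("3n", n3), rep("3n+1", n_other)),
               at = 0.7, stringsAsFactors = FALSE)
  }))
  s2 <- splicing_level_class_summary(prof2)
  expect_equal(s2$bins$fraction_3n, (1:10) / 10)
  expect_equal(s2$correlations$r[s2$correlations$variable ==
                                   "fraction_3n"], 1)

  # uncovered and level-zero loci are excluded
  prof3 <- rbind(prof,
                 data.frame(locus_id = "z1", splicing_level = 0,
                            covered = TRUE, mod3_class = "3n", at = 0.7),
                 data.frame(locus_id = "z2", splicing_level = 0.5,
                            covered = FALSE, mod3_class = "3n", at = 0.7))
  expect_equal(sum(splicing_level_class_summary(prof3)$bins$n), 40L)
})
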