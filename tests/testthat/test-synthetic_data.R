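test_that("simulation is a pure function of (params, seed)", {
  p <- simulation_params(n_genes = 10L, seed = 42L)
  s1 <- simulate_genome(p)
  s2 <- simulate_genome(p)
  expect_identical(s1, s2)
  s3 <- simulate_genome(simulation_params(n_genes = 10L, seed = 43L))
  expect_false(identical(s1$genome, s3$genome))

  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  p1 <- write_simulated_dataset(s1, d1)
  p2 <- write_simulated_dataset(s2, d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
})

test_that("planted intron properties are honoured", {
  sim <- simulate_genome(simulation_params(n_genes = 40L,
                                           gta_tag_intron_fraction = 1,
                                           seed = 8L))
  introns <- derive_intron_records(sim$genes, sim$genome)
  expect_true(all(substr(introns$sequence, 1, 3) == "GTA"))
  expect_true(all(substring(introns$sequence,
                            introns$length - 2) == "TAG"))

  sim0 <- simulate_genome(simulation_params(n_genes = 60L,
                                            gta_tag_intron_fraction = 0,
                                            seed = 9L))
  introns0 <- derive_intron_records(sim0$genes, sim0$genome)
  expect_true(all(introns0$canonical))
  expect_false(any(introns0$signal_class == "GTA|TAG"))

  # intron lengths come from the configured distribution
  sim2 <- simulate_genome(simulation_params(n_genes = 100L, seed = 10L))
  tt <- sim2$truth$introns
  expect_true(all(tt$length >= 15 & tt$length <= 40))
  expect_gt(mean(tt$length >= 21 & tt$length <= 30), 0.85)
})

test_that("exon AT content matches the target within binomial error", {
  sim <- simulate_genome(simulation_params(n_genes = 200L, seed = 5L))
  ex <- extract_coding_exons(sim$genes, sim$genome)
  n_nt <- sum(nchar(ex$sequence))
  at_obs <- sum(nchar(gsub("[^AT]", "", ex$sequence))) / n_nt
  se <- sqrt(0.72 * 0.28 / n_nt)
  expect_lt(abs(at_obs - 0.72), 3 * se)
})

test_that("strand depletion edits exactly the selected stratum fraction", {
  mk <- function(i) {
    # one isolated 3n GTA|TAG segment (27 nt) per sequence, embedded in C/G
    paste0(strrep("C", 6), "GTA", strrep("C", 10), "ATCGCGCGATC", "TAG",
           strrep("G", 6))
  }
  seqs <- vapply(1:5000, mk, character(1))
  base <- segment_table(data.frame(
    gene_id = paste0("g", 1:5000), exon_index = 1L, n_exons = 1L,
    position_class = "single", chrom = "c", start = 0L,
    end = nchar(seqs[1]), strand = "+", cds_offset = 0L, expression = 1,
    sequence = seqs, stringsAsFactors = FALSE), strands = "sense")
  n_target <- sum(base$signal_class == "GTA|TAG" & base$mod3_class == "3n" &
                    base$length >= 21 & base$length <= 30)
  expect_equal(n_target, 5000L)

  d0 <- apply_strand_depletion(seqs, delta = 0, seed = 1L)
  expect_identical(as.character(d0), seqs)
  expect_equal(nrow(attr(d0, "edits")), 0L)

  d1 <- apply_strand_depletion(seqs, delta = 1, seed = 1L)
  surviving <- function(x) {
    seg <- enumerate_gt_ag_segments(x)
    as.numeric(sum(seg$signal_class == "GTA|TAG" & seg$mod3_class == "3n" &
                     seg$length >= 21 & seg$length <= 30))
  }
  expect_equal(sum(vapply(as.character(d1), surviving, numeric(1))), 0)

  d5 <- apply_strand_depletion(seqs, delta = 0.5, seed = 2L)
  surv <- sum(vapply(as.character(d5), surviving, numeric(1)))
  se <- sqrt(5000 * 0.25)
  expect_lt(abs(surv - 2500), 3 * se)
})

test_that("genome-level depletion matches exon-level depletion", {
  sim <- simulate_genome(simulation_params(n_genes = 50L, seed = 14L))
  dep <- deplete_genome(sim, delta = 0.7, seed = 99L)
  ex_direct <- apply_strand_depletion(
    extract_coding_exons(sim$genes, sim$genome)$sequence,
    delta = 0.7, seed = 99L)
  ex_via_genome <- extract_coding_exons(dep$genes, dep$genome)$sequence
  expect_identical(ex_via_genome, as.character(ex_direct))
  # depletion only ever touches exonic positions
  expect_equal(sum(nchar(sim$genome)), sum(nchar(dep$genome)))
})

test_that("expected DSA under depletion has the right closed form", {
  expect_equal(expected_dsa(0), 0)
  expect_equal(expected_dsa(1), -1)
  expect_equal(expected_dsa(0.5), -1 / 3)
  expect_error(expected_dsa(1.5), "delta")
})

test_that("junction-count simulation respects planted levels", {
  loci <- data.frame(locus_id = c("a", "b"), chrom = "c1",
                     start = c(100L, 300L), end = c(125L, 326L),
                     level_spliced = c(1, 0), level_retained = c(0, 1),
                     level_alt = 0, depth = 50L,
                     stringsAsFactors = FALSE)
  out <- simulate_junction_counts(loci, seed = 3L)
  expect_equal(out$counts$spliced, c(50L, 0L))
  expect_equal(out$counts$retained, c(0L, 50L))
  # fully retained locus emits no junction row
  expect_equal(nrow(out$junctions), 1L)
  expect_equal(out$junctions$donor, 100L)

  bad <- loci; bad$level_alt <- 0.5
  expect_error(simulate_junction_counts(bad), "sum to 1")

  expect_identical(simulate_junction_counts(loci, seed = 3L),
                   simulate_junction_counts(loci, seed = 3L))
})
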