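test_that("expression quartiles: balance, ties, rank invariance", {
  e <- setNames(c(1, 2, 3, 4, 5, 6, 7, 8), paste0("g", 1:8))
  q <- assign_expression_quartiles(e)
  expect_equal(as.integer(table(q)), rep(2L, 4))
  expect_equal(unname(q[c("g1", "g8")]), factor(c("Q1", "Q4"),
                                                levels = paste0("Q", 1:4)))

  expect_warning(q2 <- assign_expression_quartiles(
    setNames(rep(3, 8), paste0("g", 1:8))), "all genes assigned to Q1")
  expect_true(all(q2 == "Q1"))

  # invariant under any monotone transform
  expect_equal(assign_expression_quartiles(e),
               assign_expression_quartiles(e^3 + 1))

  expect_message(q3 <- assign_expression_quartiles(
    setNames(c(0, 1:8), paste0("g", 0:8))), "zero expression")
  expect_false("g0" %in% names(q3))
  expect_error(assign_expression_quartiles(setNames(1:3, letters[1:3])),
               "at least 4")

  # quartile sizes sum to the gene count; each within one of n/4
  set.seed(3)
  e4 <- setNames(rlnorm(203), paste0("g", 1:203))
  q4 <- assign_expression_quartiles(e4)
  expect_equal(sum(table(q4)), 203L)
  expect_true(all(abs(table(q4) - 203 / 4) <= 1))
})

test_that("CDS binning uses floor with upward boundary ties", {
  expect_equal(bin_cds_position(0, 1000), 1L)
  expect_equal(bin_cds_position(999, 1000), 10L)
  expect_equal(bin_cds_position(100, 1000), 2L)
  expect_error(bin_cds_position(1000, 1000), "range")
  expect_error(bin_cds_position(-1, 1000), "range")
  # occupancy sums to feature count
  set.seed(9)
  pos <- sample(0:999, 500, replace = TRUE)
  expect_equal(sum(table(bin_cds_position(pos, 1000))), 500L)
})

test_that("gene architecture metrics: density, distances, tail", {
  # 4 exons -> 3 introns, CDS 1500
  g <- gene_model("g", "c", "+",
                  rbind(c(0L, 500L), c(525L, 1000L), c(1030L, 1430L),
                        c(1460L, 1585L)))
  m <- gene_architecture_metrics(g)
  expect_equal(m$cds_length, 1500L)
  expect_equal(m$intron_density, 2.0)
  expect_equal(m$inter_intron_distances, c(475L, 400L))
  expect_equal(m$tail_distance, 125L)

  # spec-style inter-intron example: introns [100,125) and [300,326)
  g2 <- gene_model("g2", "c", "+",
                   rbind(c(0L, 100L), c(125L, 300L), c(326L, 400L)))
  expect_equal(gene_architecture_metrics(g2)$inter_intron_distances, 175L)

  # strand invariance
  gm <- gene_model("g", "c", "-",
                   rbind(c(0L, 500L), c(525L, 1000L), c(1030L, 1430L),
                         c(1460L, 1585L)))
  mm <- gene_architecture_metrics(gm)
  expect_equal(mm$cds_length, m$cds_length)
  expect_equal(mm$intron_density, m$intron_density)
  expect_equal(sort(mm$inter_intron_distances),
               sort(m$inter_intron_distances))

  g1ex <- gene_model("s", "c", "+", rbind(c(0L, 300L)))
  expect_true(is.na(gene_architecture_metrics(g1ex)$tail_distance))
})

test_that("association tests: degenerate, perfect, and oracle cases", {
  out <- association_tests(list(
    unif = list(type = "chisq_uniform", counts = rep(10, 10)),
    anti = list(type = "pearson", x = 1:10, y = 10:1),
    prop = list(type = "two_proportion", x = c(4600, 2700),
                n = c(10000, 10000)),
    wil = list(type = "wilcoxon", x = rnorm(50), y = rnorm(50, 3))))
  expect_equal(out$statistic[out$name == "unif"], 0)
  expect_equal(out$p_value[out$name == "unif"], 1)
  expect_equal(out$estimate[out$name == "anti"], -1)
  oracle <- chisq.test(matrix(c(4600, 5400, 2700, 7300), 2, byrow = TRUE),
                       correct = FALSE)
  expect_equal(out$statistic[out$name == "prop"],
               unname(oracle$statistic))
  expect_lt(out$p_value[out$name == "wil"], 1e-6)

  out2 <- association_tests(list(
    d1 = list(type = "two_proportion", x = c(0, 0), n = c(0, 10)),
    d2 = list(type = "pearson", x = rep(1, 5), y = 1:5)))
  expect_true(all(out2$degenerate))

  out3 <- association_tests(list(
    a = list(type = "pearson", x = 1:20, y = 1:20 + rnorm(20)),
    b = list(type = "pearson", x = 1:20, y = rnorm(20))),
    correction = "bonferroni")
  expect_equal(out3$p_adjusted, pmin(1, out3$p_value * 2))
})

test_that("uniformly placed features pass bin-uniformity in most seeds", {
  passes <- vapply(1:50, function(s) {
    set.seed(s)
    pos <- sample(0:1499, 1000, replace = TRUE)
    counts <- as.integer(table(factor(bin_cds_position(pos, 1500),
                                      levels = 1:10)))
    res <- association_tests(list(u = list(type = "chisq_uniform",
                                           counts = counts)))
    res$p_value > 0.01
  }, logical(1))
  expect_gte(mean(passes), 0.95)
})

test_that("intron signal frequencies stratify by expression quartile", {
  introns <- data.frame(
    gene_id = rep(paste0("g", 1:8), each = 2),
    gta5 = rep(c(TRUE, FALSE), 8),
    tag3 = TRUE, stringsAsFactors = FALSE)
  q <- assign_expression_quartiles(setNames(1:8, paste0("g", 1:8)))
  tab <- intron_signal_by_quartile(introns, q)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$pct_gta_tag, rep(50, 4))
  expect_equal(tab$pct_tag3, rep(100, 4))
})
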