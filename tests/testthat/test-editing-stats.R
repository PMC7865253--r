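test_that("modified-transcript counting is a distinct count", {
  expect_identical(count_modified_transcripts(
    make_sites(c("a", "a", "a", "b", "b"))), 2L)
  expect_identical(count_modified_transcripts(make_sites(character(0))), 0L)
  expect_identical(count_modified_transcripts(make_sites("a")), 1L)
})

test_that("proportion modified uses the expressed-transcript denominator", {
  ab <- abundance_table(c(a = 2, b = 5, c = 0.4, d = 1))
  pm <- proportion_modified(make_sites(c("a", "a", "b")), ab)
  expect_identical(pm$n_expressed, 3L)  # a, b, d
  expect_identical(pm$n_modified, 2L)
  expect_equal(pm$proportion, 2 / 3)
})

test_that("restrict_to_common keeps transcripts expressed in every sample", {
  s1 <- make_sites(c("a", "b", "c"))
  s2 <- make_sites(c("b", "d"))
  ab1 <- abundance_table(c(a = 2, b = 2, c = 2))
  ab2 <- abundance_table(c(b = 2, c = 2, d = 2))
  out <- restrict_to_common(list(s1 = s1, s2 = s2), list(ab1, ab2))
  expect_setequal(out$common_transcripts, c("b", "c"))
  expect_setequal(out$sites$s1$transcript_id, c("b", "c"))
  expect_identical(out$sites$s2$transcript_id, "b")
  # identical expression -> identity
  out2 <- restrict_to_common(list(s1, s1), list(ab1, ab1))
  expect_identical(nrow(out2$sites[[1]]), nrow(s1))
  # disjoint expression -> empty
  out3 <- restrict_to_common(list(s1, s2),
                             list(abundance_table(c(a = 2)),
                                  abundance_table(c(d = 2))))
  expect_identical(nrow(out3$sites[[1]]), 0L)
  expect_length(out3$common_transcripts, 0)
})

test_that("sites-per-transcript histogram conserves total mass", {
  h <- modifications_per_transcript(make_sites(c("a", "b", "c", "c", "c")))
  expect_identical(h, setNames(c(2L, 1L), c("1", "3")))
  expect_length(modifications_per_transcript(make_sites(character(0))), 0)
  # conservation on random inputs (brute-force recount oracle)
  set.seed(5)
  for (rep in 1:20) {
    ids <- sample(letters, sample(1:60, 1), replace = TRUE)
    h <- modifications_per_transcript(make_sites(ids))
    expect_identical(sum(as.integer(names(h)) * h), length(ids))
    expect_identical(sum(h), length(unique(ids)))
  }
})

test_that("region distribution partitions the sites", {
  s <- make_sites(letters[1:4],
                  region = c("cds", "cds", "intron", "three_prime_utr"))
  rd <- region_distribution(s)
  expect_identical(unname(rd[c("cds", "intron", "three_prime_utr")]),
                   c(2L, 1L, 1L))
  expect_identical(sum(rd), 4L)
  expect_identical(sum(region_distribution(make_sites(character(0)))), 0L)
  set.seed(6)
  for (rep in 1:20) {
    regs <- sample(c("five_prime_utr", "cds", "intron", "three_prime_utr"),
                   sample(1:50, 1), replace = TRUE)
    expect_identical(sum(region_distribution(make_sites(seq_along(regs),
                                                        region = regs))),
                     length(regs))
  }
})

test_that("per-codon counts cover the 34 adenosine codons and conserve totals", {
  ctx <- make_contexts(c("AAA", "AAA", "AAA", "GCA"), c(3, 3, 3, 3))
  pc <- per_codon_counts(ctx)
  expect_length(pc$by_codon, 34L)
  expect_identical(unname(pc$by_codon["AAA"]), 3L)
  expect_identical(unname(pc$by_codon["GCA"]), 1L)
  expect_identical(sum(pc$by_codon), nrow(ctx))
  expect_true(all(pc$by_codon[setdiff(names(pc$by_codon), c("AAA", "GCA"))] == 0L))
  # stop-altering contexts are excluded
  ctx2 <- rbind(ctx, make_contexts("TGA", 3))  # TGA>TGG = stop_lost
  expect_identical(sum(per_codon_counts(ctx2)$by_codon), 4L)
})

test_that("codon-position frequencies sum to one and handle edge cases", {
  f <- codon_position_frequencies(make_contexts("AAA", c(3, 3, 3, 1)))
  expect_equal(unname(f), c(0.25, 0, 0.75))
  f2 <- codon_position_frequencies(make_contexts("CAT", 2))
  expect_equal(unname(f2), c(0, 1, 0))
  expect_warning(f3 <- codon_position_frequencies(make_contexts(character(0), integer(0))),
                 "undefined")
  expect_true(all(is.na(f3)))
  # sums to 1 within floating tolerance on random inputs
  set.seed(8)
  for (rep in 1:20) {
    pos <- sample(1:3, sample(1:200, 1), replace = TRUE)
    f <- codon_position_frequencies(make_contexts("AAA", pos))
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
})

test_that("uniform planted positions are recovered within binomial tolerance", {
  set.seed(10)
  pos <- sample(1:3, 3000, replace = TRUE)
  f <- codon_position_frequencies(make_contexts("AAA", pos))
  expect_true(all(abs(f - 1 / 3) < 0.03))
})

test_that("wobble chi-square matches hand calculation and the null case", {
  gc0 <- wobble_enrichment_test(c(10, 10, 10))
  expect_equal(gc0$statistic, 0)
  expect_equal(gc0$p_value, 1)
  gc <- wobble_enrichment_test(c(10, 10, 40))
  # hand: (10-20)^2/20 * 2 + (40-20)^2/20 = 5 + 5 + 20 = 30, df 2
  expect_equal(gc$statistic, 30)
  expect_equal(gc$df, 2, ignore_attr = TRUE)
  expect_lt(gc$p_value, 0.001)
  # observed equal to expected under a non-uniform availability null
  gca <- wobble_enrichment_test(c(10, 20, 70), availability = c(0.1, 0.2, 0.7))
  expect_equal(gca$statistic, 0)
  expect_error(wobble_enrichment_test(c(5, 5, 5), availability = c(0.5, 0.5, 0)),
               "pool")
})

test_that("availability null reflects CDS adenosine composition", {
  ref <- c(c1 = paste0("TT", "ATGAAAGTT", "CC"))
  t <- transcript_model("t", "g", "c1", "+", exons = cbind(1L, 13L),
                        cds = cbind(3L, 11L))
  # CDS = ATG AAA GTT: A at positions (1,1) (1,2) (1,3)... count per frame:
  # pos1: A__ in ATG, AAA -> 2; pos2: A in AAA -> 1; pos3: A in AAA -> 1
  av <- codon_position_availability(list(t = t), ref)
  expect_equal(unname(av), c(2, 1, 1) / 4)
})

test_that("per-codon efficiency averages sites within classes", {
  ctx <- make_contexts(c("AAA", "AAA", "GCA"), c(3, 3, 3),
                       efficiency = c(0.4, 0.6, 1.0),
                       ad_ref = c(6L, 4L, 0L), ad_alt = c(4L, 6L, 10L))
  pe <- per_codon_efficiency(ctx)
  expect_equal(pe$efficiency[pe$codon == "AAA"], 0.5)
  expect_equal(pe$efficiency[pe$codon == "GCA"], 1.0)
  expect_identical(pe$codon_class[pe$codon == "AAA"], "aaA")
  # read-pooled alternative
  pp <- per_codon_efficiency(ctx, method = "pooled")
  expect_equal(pp$efficiency[pp$codon == "AAA"], 10 / 20)
  # zero-site classes are omitted
  expect_identical(nrow(pe), 2L)
})

test_that("efficiency-abundance correlation recovers exact linear relations", {
  s <- make_sites(letters[1:5], efficiency = c(0.1, 0.2, 0.3, 0.4, 0.5))
  ab <- abundance_table(setNames(c(10, 20, 30, 40, 50), letters[1:5]))
  r <- efficiency_abundance_correlation(s, ab)
  expect_equal(r$statistic, 1.0)
  s2 <- make_sites(letters[1:5], efficiency = c(0.5, 0.4, 0.3, 0.2, 0.1))
  r2 <- efficiency_abundance_correlation(s2, ab)
  expect_equal(r2$statistic, -1.0)
  # zero variance -> undefined marker
  s3 <- make_sites(letters[1:5], efficiency = 0.5)
  r3 <- efficiency_abundance_correlation(s3, ab)
  expect_true(is.na(r3$statistic))
  expect_error(efficiency_abundance_correlation(make_sites(c("a", "b")), ab),
               ">= 3")
})

test_that("one-way ANOVA matches the brute-force sum-of-squares formula", {
  groups <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(3, 4, 5))
  gc <- compare_groups(groups, design = "one_way")
  # brute force: SSB = 3*((2-3)^2+(3-3)^2+(4-3)^2) = 6 over df 2;
  # SSW = 2+2+2 = 6 over df 6 -> F = 3/1 = 3
  expect_equal(gc$statistic, 3.0)
  expect_identical(gc$groups$mean, c(2, 3, 4))
  expect_equal(gc$groups$sem, rep(1 / sqrt(3), 3))
  # brute-force equality on random inputs
  set.seed(12)
  for (rep in 1:10) {
    g <- lapply(1:3, function(i) rnorm(sample(3:6, 1), mean = i))
    names(g) <- paste0("g", 1:3)
    fit <- compare_groups(g, design = "one_way")
    all_v <- unlist(g); grand <- mean(all_v)
    ssb <- sum(lengths(g) * (vapply(g, mean, 1) - grand)^2)
    ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
    f_brute <- (ssb / (length(g) - 1)) / (ssw / (length(all_v) - length(g)))
    expect_equal(fit$statistic, f_brute)
  }
})

test_that("identical groups give F = 0 and p = 1", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  gc <- compare_groups(g, design = "one_way")
  expect_equal(gc$statistic, 0)
  expect_equal(gc$p_value, 1)
})

test_that("proportion design reproduces the hand-computed Pearson chi-square", {
  m <- matrix(c(10, 90, 20, 80), nrow = 2, byrow = TRUE)
  gc <- compare_groups(m, design = "proportions")
  # hand: totals 30/170, rows 100 each; E = [[15,85],[15,85]]
  # X2 = 25/15 + 25/85 + 25/15 + 25/85 = 3.9215686...
  expect_equal(gc$statistic, 25 / 15 + 25 / 85 + 25 / 15 + 25 / 85)
  expect_equal(gc$df, 1, ignore_attr = TRUE)
})

test_that("two-way ANOVA handles cell means and replicated designs", {
  df <- data.frame(
    value = c(10, 12, 20, 22, 11, 13, 21, 23),
    genotype = rep(c("wt", "ko"), each = 4),
    category = rep(c("tolerated", "deleterious"), times = 4)
  )
  suppressWarnings(gc <- compare_groups(df, design = "two_way"))
  expect_identical(gc$statistic_name, "two_way_anova")
  expect_true(gc$p_value >= 0 && gc$p_value <= 1)
  # single observation per cell -> additive model still fits
  df1 <- data.frame(value = c(1, 2, 3, 4),
                    genotype = c("a", "a", "b", "b"),
                    category = c("x", "y", "x", "y"))
  gc1 <- compare_groups(df1, design = "two_way")
  expect_true(is.finite(gc1$statistic))
  expect_error(compare_groups(list(only = 1:3), design = "one_way"))
})

test_that("planted wobble bias is detected against the uniform null", {
  set.seed(14)
  rejections <- 0L
  for (rep in 1:100) {
    pos <- sample(1:3, 300, replace = TRUE, prob = c(0.25, 0.25, 0.75))
    ht <- wobble_enrichment_test(as.numeric(table(factor(pos, levels = 1:3))))
    if (ht$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections, 99L)
})

test_that("summarize_editing bundles consistent per-sample statistics", {
  sim <- default_sim()
  sites <- call_inosine_sites(sim$variants, sim$models, sim$abundance,
                              blacklist = sim$blacklist,
                              dialect = sim$config$dialect)
  ctx <- annotate_codons(sites, sim$models, sim$seqs)
  sm <- summarize_editing(sites, sim$abundance, ctx)
  expect_identical(sm$n_sites, nrow(sites))
  expect_lte(sm$n_modified_transcripts, sm$n_expressed_transcripts)
  expect_true(sm$proportion_modified >= 0 && sm$proportion_modified <= 1)
  expect_equal(sum(sm$position_frequencies), 1, tolerance = 1e-12)
  expect_identical(sum(sm$region_counts), nrow(sites))
  h <- sm$per_transcript_histogram
  expect_identical(sum(as.integer(names(h)) * h), nrow(sites))
})
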