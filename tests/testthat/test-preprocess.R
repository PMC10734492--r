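make_table <- function(counts) count_table(counts)

test_that("total-count filter removes at 420 and keeps at 421", {
  # 210 samples; taxon A totals exactly 420 (removed: rule is <=),
  # taxon B totals 421 spread over 21 samples (retained: just above
  # both thresholds), taxon C is never observed
  counts <- matrix(0, 210, 3, dimnames = list(NULL, c("A", "B", "C")))
  counts[1:21, "A"] <- 20     # total 420, prevalence 21/210 = 10%
  counts[1:20, "B"] <- 21     # total 420 ... make it 421
  counts[21, "B"] <- 1
  tab <- make_table(counts)
  filt <- filter_taxa(tab, filter_params())
  expect_equal(colnames(filt$counts), "B")
  expect_equal(sum(filt$counts[, "B"]), 421)
})

test_that("prevalence filter uses a ceiling boundary", {
  # 10 samples, 10% prevalence -> need >= 1 non-zero sample;
  # at 20 samples a taxon in exactly 2 samples (10%) is retained,
  # in 1 sample (5%) removed
  counts <- matrix(0, 20, 2, dimnames = list(NULL, c("ten_pct", "five_pct")))
  counts[1:2, 1] <- 300   # total 600, 2/20 samples
  counts[1, 2] <- 600     # total 600, 1/20 samples
  filt <- filter_taxa(make_table(counts), filter_params())
  expect_equal(colnames(filt$counts), "ten_pct")
})

test_that("filtering everything is an explicit error and is idempotent", {
  counts <- matrix(1, 4, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(filter_taxa(make_table(counts), filter_params()),
               "removed every taxon")
  big <- toy_table()
  p <- filter_params(min_total_count = 5, min_prevalence_fraction = 0.5)
  once <- filter_taxa(big, p)
  twice <- filter_taxa(once, p)
  expect_identical(once$counts, twice$counts)
})

test_that("network filter applies both total and mean-reads rules", {
  # over 210 samples the two criteria coincide at total 420
  counts <- matrix(0, 210, 2, dimnames = list(NULL, c("at420", "under")))
  counts[1:42, "at420"] <- 10    # total 420, mean 2.0
  counts[1:41, "under"] <- 9     # total 369: mean 1.76
  counts[42, "under"] <- 30      # total 399 < 420
  filt <- filter_for_network(make_table(counts))
  expect_equal(colnames(filt$counts), "at420")

  # mean 2.0 on 10 samples still fails the total rule (20 < 420)
  small <- matrix(2, 10, 2, dimnames = list(NULL, c("A", "B")))
  small[, 2] <- 50  # total 500, mean 50: retained
  filt2 <- filter_for_network(make_table(small))
  expect_equal(colnames(filt2$counts), "B")
})

test_that("rarefaction drops shallow samples and conserves depth", {
  counts <- rbind(deep = c(8000, 4000), exact = c(6000, 4000),
                  shallow = c(5000, 999))
  colnames(counts) <- c("t1", "t2")
  tab <- make_table(counts)
  expect_message(rar <- rarefy(tab, 10000, seed = 1), "shallow")
  expect_equal(attr(rar, "dropped_samples"), "shallow")
  expect_true(all(rowSums(rar$counts) == 10000))
  # a sample at exactly the target depth is untouched
  expect_equal(unname(rar$counts["exact", ]), c(6000, 4000))
  expect_error(rarefy(make_table(rbind(c(5, 5))), 100), "cannot rarefy")
})

test_that("rarefied counts follow the hypergeometric expectation", {
  # sample (8000, 4000) rarefied to 6000: taxon 1 count is
  # hypergeometric(8000 successes, 4000 failures, 6000 draws),
  # mean 4000, sd ~= 21.1
  counts <- rbind(s = c(8000, 4000)); colnames(counts) <- c("t1", "t2")
  tab <- make_table(counts)
  draws <- vapply(1:200, function(s)
    rarefy(tab, 6000, seed = s)$counts[1, 1], numeric(1))
  m <- 6000 * 8000 / 12000
  v <- 6000 * (8000 / 12000) * (4000 / 12000) * (12000 - 6000) / (12000 - 1)
  expect_equal(mean(draws), m, tolerance = 3 * sqrt(v / 200) / m)
  expect_equal(sd(draws), sqrt(v), tolerance = 0.2)
  # a taxon absent before rarefaction is absent after
  counts2 <- rbind(s = c(12000, 0)); colnames(counts2) <- c("t1", "t2")
  expect_equal(unname(rarefy(make_table(counts2), 6000, seed = 1)$counts[1, ]),
               c(6000, 0))
})

test_that("aggregation conserves totals and labels unknown genera", {
  tab <- toy_table()
  gen <- aggregate_taxa(tab, "genus")
  expect_true("Family Rikenellaceae - unknown genus" %in% colnames(gen$counts))
  expect_equal(rowSums(gen$counts), rowSums(tab$counts))
  # two features sharing a genus sum their counts
  counts <- rbind(S1 = c(3, 4))
  colnames(counts) <- c("x", "y")
  same_genus <- count_table(counts, c(
    x = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Ruminococcaceae; g__Faecalibacterium; s__a",
    y = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Ruminococcaceae; g__Faecalibacterium; s__b"))
  agg <- aggregate_taxa(same_genus, "genus")
  expect_equal(unname(agg$counts[1, "Faecalibacterium"]), 7)
  expect_error(aggregate_taxa(tab, "species"), "arg")
})

test_that("default synthetic lineages span exactly 8 phyla", {
  study <- generate_study(synthetic_config(n_gain = 2, n_loss = 2, seed = 1))
  phy <- aggregate_taxa(study$counts, "phylum")
  expect_equal(ncol(phy$counts), 8L)
  expect_equal(rowSums(phy$counts), rowSums(study$counts$counts))
})

test_that("log relative abundance follows the transform's closed form", {
  counts <- rbind(a = c(0, 100), b = c(50, 50))
  colnames(counts) <- c("t1", "t2")
  tab <- make_table(counts)
  # zero count maps to exactly 0
  m <- log_relative_abundance(tab, transform_params(30615))
  expect_equal(unname(m["a", "t1"]), 0)
  # count = total (single-taxon sample): log10(avg + 1)
  expect_equal(unname(m["a", "t2"]), log10(30616), tolerance = 1e-12)
  expect_equal(log10(30616), 4.486, tolerance = 1e-4)
  # relative abundance 1/avg gives log10(2)
  counts2 <- rbind(s = c(1, 30615 - 1)); colnames(counts2) <- c("t1", "t2")
  m2 <- log_relative_abundance(make_table(counts2), transform_params(30615))
  expect_equal(unname(m2[1, "t1"]), log10(2))
  # strictly monotone in the count at fixed total
  counts3 <- rbind(s1 = c(10, 90), s2 = c(20, 80), s3 = c(30, 70))
  colnames(counts3) <- c("t1", "t2")
  m3 <- log_relative_abundance(make_table(counts3))
  expect_true(all(diff(m3[, "t1"]) > 0))
  # zero-total sample is an error naming the sample
  counts4 <- rbind(ok = c(1, 1), empty = c(0, 0))
  colnames(counts4) <- c("t1", "t2")
  expect_error(log_relative_abundance(make_table(counts4)), "empty")
})
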