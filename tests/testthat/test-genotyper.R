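test_that("monoallelic genotyping is exact on the model's own output", {
  p <- ac_params()
  cache <- genotyper_cache(p, 10:30, 0:30)
  h <- predict_histogram(p, 20, 17)
  h <- repeat_histogram(h$counts * 1000, repeats = h$repeats)
  g <- genotype_mono(h, p, cache = cache)
  expect_equal(g$status, "called")
  expect_equal(g$alleles, 20L)
  expect_equal(g$cycles, 17L)
  expect_lt(g$distance, 1e-9)
  expect_equal(g$proportion, 1.0)

  # self-consistency across a sweep of (t, l) grid points
  for (l in c(12L, 24L)) for (t in c(0L, 9L, 21L)) {
    hm <- predict_histogram(p, l, t)
    hm <- repeat_histogram(hm$counts * 500, repeats = hm$repeats)
    gg <- genotype_mono(hm, p, cache = cache)
    expect_equal(gg$alleles, l)
    expect_equal(gg$cycles, t)
    expect_lt(gg$distance, 1e-9)
  }
})

test_that("a clean delta is called at zero cycles; thin coverage is gated", {
  p <- ac_params()
  cache <- genotyper_cache(p, 10:30, 0:30)
  g <- genotype_mono(repeat_histogram(100, repeats = 25), p, cache = cache)
  expect_equal(g$status, "called")
  expect_equal(g$alleles, 25L)
  expect_equal(g$cycles, 0L)

  # the 5x coverage gate
  low <- genotype_mono(repeat_histogram(4, repeats = 25), p, cache = cache)
  expect_equal(low$status, "low_coverage")
  expect_length(low$alleles, 0)
  ok <- genotype_mono(repeat_histogram(5, repeats = 25), p, cache = cache)
  expect_equal(ok$status, "called")

  expect_error(genotyper_cache(p, integer(0), 0:10), "empty")
})

test_that("biallelic genotyping recovers exact mixtures and proportions", {
  p <- ac_params()
  cache <- genotyper_cache(p, 12:32, seq(0L, 40L, 4L))
  mix <- predict_mixture(p, 17, 27, 0.5, 28)
  mix <- repeat_histogram(mix$counts * 2000, repeats = mix$repeats)
  g <- genotype_biallelic(mix, p, cache = cache)
  expect_equal(g$alleles, c(17L, 27L))
  expect_equal(g$proportion, 0.5)
  expect_equal(g$cycles, 28L)
  expect_lt(g$distance, 1e-9)

  # asymmetric proportion
  mix2 <- predict_mixture(p, 18, 25, 0.3, 20)
  mix2 <- repeat_histogram(mix2$counts * 2000, repeats = mix2$repeats)
  g2 <- genotype_biallelic(mix2, p, cache = cache)
  expect_equal(g2$alleles, c(18L, 25L))
  expect_equal(g2$proportion, 0.3)

  # pure single-allele signal collapses to a homozygous pair
  h1 <- predict_histogram(p, 22, 20)
  h1 <- repeat_histogram(h1$counts * 2000, repeats = h1$repeats)
  g3 <- genotype_biallelic(h1, p, cache = cache)
  expect_equal(g3$alleles, c(22L, 22L))
  expect_lt(g3$distance, 1e-9)
})

test_that("mono and biallelic calls agree when the truth is homozygous", {
  p <- ac_params()
  lr <- 15:25; cg <- seq(0L, 30L, 5L)
  # exact homozygous model signal: the biallelic search must collapse
  hm <- predict_histogram(p, 20, 25)
  hm <- repeat_histogram(hm$counts * 1000, repeats = hm$repeats)
  gm <- genotype_mono(hm, p, length_range = lr, cycle_grid = cg)
  gb <- genotype_biallelic(hm, p, length_range = lr, cycle_grid = cg)
  expect_equal(gm$alleles, 20L)
  expect_equal(gb$alleles, c(20L, 20L))
  expect_equal(gm$cycles, gb$cycles)
  # on noisy simulated data the mono allele stays within the biallelic pair
  cfg <- simulation_config(p, alleles = 20, initial_molecules = 200,
                           cycles = 25, efficiency = 0.5, reads = 800,
                           seed = 31)
  h <- simulate_pcr(cfg)
  gm2 <- genotype_mono(h, p, length_range = lr, cycle_grid = cg)
  gb2 <- genotype_biallelic(h, p, length_range = lr, cycle_grid = cg)
  expect_equal(gm2$alleles, 20L)
  expect_true(gm2$alleles %in% gb2$alleles)
})

test_that("accuracy does not degrade when coverage increases", {
  p <- ac_params()
  cache <- genotyper_cache(p, 14:31, seq(0L, 40L, 4L))
  hits <- function(reads) {
    n_ok <- 0L
    for (i in 1:20) {
      l <- 15L + (i %% 15L)
      cfg <- simulation_config(p, alleles = l, initial_molecules = 100,
                               cycles = 30, efficiency = 0.5, reads = reads,
                               seed = 500 + i)
      g <- genotype_mono(simulate_pcr(cfg), p, cache = cache)
      n_ok <- n_ok + (g$status == "called" && identical(g$alleles, l))
    }
    n_ok
  }
  expect_gte(hits(500), hits(50))
})

test_that("confidence percentiles rank by distance and ignore order", {
  calls <- data.frame(locus_id = c("a", "b", "c"),
                      allele1 = c(20L, 21L, 22L), allele2 = c(20L, 21L, 22L),
                      proportion = 1, cycles = 1L,
                      distance = c(0.0, 0.5, 1.0),
                      percentile = NA_real_, status = "called",
                      stringsAsFactors = FALSE)
  r <- rank_confidence(calls)
  expect_equal(r$percentile, c(0, 50, 100))

  shuffled <- calls[c(3, 1, 2), ]
  r2 <- rank_confidence(shuffled)
  expect_equal(r2$percentile[r2$locus_id == "b"], 50)
  expect_equal(r2$percentile[r2$locus_id == "a"], 0)

  single <- calls[2, ]
  expect_equal(rank_confidence(single)$percentile, 0)

  # non-called rows keep NA and do not consume percentile mass
  calls$status[2] <- "low_coverage"
  r3 <- rank_confidence(calls)
  expect_true(is.na(r3$percentile[2]))
  expect_equal(r3$percentile[c(1, 3)], c(0, 100))

  # ties share the lower percentile
  tied <- calls; tied$status <- "called"; tied$distance <- c(0.2, 0.2, 0.9)
  r4 <- rank_confidence(tied)
  expect_equal(r4$percentile, c(0, 0, 100))
})

test_that("batch genotyping returns a ranked calls table", {
  p <- ac_params()
  hs <- lapply(c(16L, 22L), function(l) {
    h <- predict_histogram(p, l, 10, locus_id = paste0("L", l))
    repeat_histogram(h$counts * 400, repeats = h$repeats,
                     locus_id = paste0("L", l))
  })
  tab <- genotype_histograms(hs, p, mode = "mono", length_range = 12:26,
                             cycle_grid = seq(0L, 20L, 2L))
  tab <- rank_confidence(tab)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$allele1, c(16L, 22L))
  expect_equal(tab$status, c("called", "called"))
  expect_true(all(!is.na(tab$percentile)))
})
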