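# Genome representation, gene scanning, binding and mutation operators.

test_that("default genome has 10 chromosomes of 10,000 characters", {
  g <- init_genome(seed = 11)
  expect_length(g$chromosomes, 10L)
  expect_true(all(vapply(g$chromosomes, length, 0L) == 10000L))
  expect_setequal(unique(unlist(strsplit(genome_strings(g)[1], ""))),
                  c("0", "1", "2", "3"))
})

test_that("the same seed yields a bit-identical genome", {
  a <- init_genome(seed = 7, n_chromosomes = 1, chrom_length = 500,
                   alphabet = c("0", "1"))
  b <- init_genome(seed = 7, n_chromosomes = 1, chrom_length = 500,
                   alphabet = c("0", "1"))
  expect_identical(a$chromosomes, b$chromosomes)
})

test_that("characters are uniform within a chi-square 99% band", {
  g <- init_genome(seed = 3)
  counts <- tabulate(unlist(genome_ints <- lapply(g$chromosomes,
                                                  as.integer)) + 1L, 4L)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("invalid genome arguments error", {
  expect_error(init_genome(1, n_chromosomes = 0), "positive")
  expect_error(init_genome(1, chrom_length = 0), "positive")
  expect_error(init_genome(1, alphabet = "0"), "alphabet")
})

test_that("a chromosome without promoters yields no loci", {
  g <- genome_from_strings(strrep("2", 400))
  expect_identical(nrow(scan_genes(g)), 0L)
})

test_that("a hand-built gene is found at its promoter offset", {
  g <- genome_from_strings(single_gene_chromosome(14, "regulatory",
                                                  site = "0123",
                                                  payload = "32100213"))
  loci <- scan_genes(g)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$promoter, 14L)
  expect_identical(loci$gene_type, "regulatory")
  expect_identical(loci$binding_site, "0123")
  expect_identical(loci$payload, "32100213")
})

test_that("scan_genes equals the brute-force scanner on random genomes", {
  set.seed(42)
  for (i in 1:100) {
    g <- init_genome(NULL, n_chromosomes = sample(1:3, 1),
                     chrom_length = sample(200:1000, 1))
    got <- scan_genes(g)
    want <- brute_scan(g)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want) > 0L) {
      expect_identical(got$chromosome, want$chromosome)
      expect_identical(got$start, want$start)
      expect_identical(got$gene_type, want$gene_type)
      expect_identical(got$binding_site, want$binding_site)
      expect_identical(got$payload, want$payload)
    }
  }
})

test_that("scanning is pure and deterministic", {
  g <- init_genome(seed = 5, n_chromosomes = 1, chrom_length = 800)
  before <- genome_strings(g)
  a <- scan_genes(g)
  b <- scan_genes(g)
  expect_identical(a, b)
  expect_identical(genome_strings(g), before)
})

test_that("binds follows the complement-match rule", {
  expect_true(binds("0123", "3210", tolerance = 0))   # perfect complement
  expect_false(binds("0123", "0123", tolerance = 0))  # identity is no match
  expect_error(binds("01", "012"), "equal length")
})

test_that("binds agrees with mismatch counting over exhaustive pairs", {
  alpha <- c("0", "1", "2", "3")
  # every pair of length 3 over the 4-letter alphabet
  seqs3 <- apply(expand.grid(alpha, alpha, alpha), 1, paste, collapse = "")
  for (h in 0:2) {
    got <- outer(seqs3, seqs3,
                 Vectorize(function(a, b) binds(a, b, tolerance = h)))
    want <- outer(seqs3, seqs3,
                  Vectorize(function(a, b) brute_mismatches(a, b) <= h))
    expect_identical(got, want)
  }
  # random sample at the default length 4
  set.seed(9)
  for (i in 1:500) {
    a <- paste(sample(alpha, 4, replace = TRUE), collapse = "")
    b <- paste(sample(alpha, 4, replace = TRUE), collapse = "")
    expect_identical(binds(a, b, 1), brute_mismatches(a, b) <= 1)
  }
})

test_that("zero mutation rates give an identical child", {
  p <- init_genome(seed = 2, n_chromosomes = 2, chrom_length = 400)
  child <- replicate_genome(p, mutation_rates(0, 0), seed = 1)
  expect_identical(child$chromosomes, p$chromosomes)
})

test_that("point rate 1 changes every character and preserves length", {
  p <- init_genome(seed = 2, n_chromosomes = 1, chrom_length = 300)
  child <- replicate_genome(p, mutation_rates(1, 0), seed = 1)
  expect_identical(length(child$chromosomes[[1]]), 300L)
  expect_true(all(child$chromosomes[[1]] != p$chromosomes[[1]]))
})

test_that("mean point-mutation count sits in the 99% binomial band", {
  p <- init_genome(seed = 4, n_chromosomes = 2, chrom_length = 5000)
  rate <- 0.001
  L <- 10000
  set.seed(8)
  changed <- vapply(1:200, function(i) {
    ch <- replicate_genome(p, mutation_rates(rate, 0))
    sum(unlist(ch$chromosomes) != unlist(p$chromosomes))
  }, 0)
  expected <- L * rate
  half <- 2.576 * sqrt(L * rate * (1 - rate) / 200)
  expect_lt(abs(mean(changed) - expected), half)
})

test_that("duplication grows the genome by the segment length", {
  p <- init_genome(seed = 6, n_chromosomes = 1, chrom_length = 500)
  set.seed(10)
  for (i in 1:20) {
    ch <- replicate_genome(p, mutation_rates(0, 1, duplication_mean_len = 20))
    expect_gte(length(ch$chromosomes[[1]]), 501L)
    # the duplicated characters come from the parent's alphabet usage
    expect_true(all(as.integer(ch$chromosomes[[1]]) < 4))
  }
})

test_that("genome text files round-trip bit-exactly", {
  g <- init_genome(seed = 12, n_chromosomes = 3, chrom_length = 250)
  path <- tempfile(fileext = ".txt")
  write_genome(g, path)
  back <- read_genome(path)
  expect_identical(back$chromosomes, g$chromosomes)
  expect_identical(back$alphabet, g$alphabet)
  unlink(path)
})
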