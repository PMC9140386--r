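small_genome <- genome_spec(c("c1", "c2"), c(1e6, 1e6), c(100, 100))
small_causal <- causal_locus("c2", 5e5, "G", "A")

test_that("genome_spec validates its fields", {
  expect_error(genome_spec(c("a", "a"), c(10, 10), c(1, 1)), "unique")
  expect_error(genome_spec("a", 0, 1), "length_bp")
  expect_error(genome_spec("a", 10, 0), "map_length_cM")
  expect_error(genetic_position(small_genome, "c1", 2e6), "bounds")
})

test_that("zero background rate yields exactly the causal locus", {
  v <- simulate_parental_variants(small_genome, small_causal,
                                  mutation_model(snp_rate_per_Mb = 0), seed = 1)
  expect_equal(nrow(v), 1)
  expect_true(v$causal)
  expect_equal(v$pos, small_causal$pos)
})

test_that("transition_fraction = 1 forces G>A / C>T background changes", {
  g <- genome_spec("c1", 1e6, 100)
  v <- simulate_parental_variants(g, causal_locus("c1", 100, "G", "A"),
                                  mutation_model(1000, transition_fraction = 1),
                                  seed = 2)
  bg <- v[!v$causal, ]
  expect_gt(nrow(bg), 500)
  expect_true(all(paste0(bg$ref, ">", bg$alt) %in% c("G>A", "C>T")))
})

test_that("background SNP count is Poisson-scaled and seed-reproducible", {
  g <- genome_spec("c1", 30e6, 100)
  v1 <- simulate_parental_variants(g, causal_locus("c1", 100),
                                   mutation_model(10), seed = 7)
  v2 <- simulate_parental_variants(g, causal_locus("c1", 100),
                                   mutation_model(10), seed = 7)
  expect_identical(v1, v2)
  n_bg <- sum(!v1$causal)
  expect_gt(n_bg, 300 - 4 * sqrt(300))   # Poisson(300) within 4 SD
  expect_lt(n_bg, 300 + 4 * sqrt(300))
  expect_false(is.unsorted(v1$pos[v1$chrom == "c1"]))
  expect_equal(anyDuplicated(paste(v1$chrom, v1$pos)), 0)
})

test_that("causal locus outside the genome is rejected", {
  expect_error(simulate_parental_variants(small_genome,
                                          causal_locus("c3", 10), mutation_model()),
               "chromosome")
  expect_error(simulate_parental_variants(small_genome,
                                          causal_locus("c1", 2e6), mutation_model()),
               "position")
})

test_that("single-locus F2 genotype frequencies are 1:2:1", {
  v <- simulate_parental_variants(small_genome, small_causal,
                                  mutation_model(0), seed = 1)
  pop <- simulate_f2_population(v, small_genome, n = 40000, seed = 3)
  f <- tabulate(pop$genotypes[, 1] + 1L, nbins = 3) / 40000
  p <- c(0.25, 0.5, 0.25)
  sd3 <- 3 * sqrt(p * (1 - p) / 40000)
  expect_true(all(abs(f - p) < sd3))
})

test_that("complete linkage makes genotypes identical at both loci", {
  g <- genome_spec("c1", 1e6, 100)
  v <- data.frame(chrom = "c1", pos = c(1000, 1000 + 1), ref = "G", alt = "A",
                  causal = c(TRUE, FALSE))
  # 1 bp apart: recombination fraction ~ 1e-7; effectively 0 over 500 plants
  pop <- simulate_f2_population(v, g, n = 500, seed = 4)
  expect_true(all(pop$genotypes[, 1] == pop$genotypes[, 2]))
})

test_that("gamete recombinant fraction at 50 cM matches Haldane", {
  expect_equal(haldane(50), (1 - exp(-1)) / 2)
  g <- genome_spec("c1", 1e6, 100)
  v <- data.frame(chrom = "c1", pos = c(1, 5e5 + 1), ref = "G", alt = "A",
                  causal = c(TRUE, FALSE))  # 50 cM apart under the linear map
  pop <- simulate_f2_population(v, g, n = 20000, seed = 5, keep_gametes = TRUE)
  gam <- rbind(pop$gametes[[1]], pop$gametes[[2]])
  rec <- mean(gam[, 1] != gam[, 2])
  r <- haldane(50)
  expect_lt(abs(rec - r), 3 * sqrt(r * (1 - r) / nrow(gam)))
})

test_that("recessive phenotypes follow the causal genotype and segregate 3:1", {
  v <- simulate_parental_variants(small_genome, small_causal,
                                  mutation_model(0), seed = 1)
  pop <- simulate_f2_population(v, small_genome, n = 10000, seed = 6)
  pop <- assign_phenotypes(pop, small_causal)
  expect_true(all((pop$genotypes[, 1] == 2) == (pop$phenotype == "mutant")))
  seg <- segregation_chisq(sum(pop$phenotype == "wild"),
                           sum(pop$phenotype == "mutant"))
  expect_true(seg$consistent)
  expect_equal(mean(pop$phenotype == "mutant"), 0.25, tolerance = 0.05)
})

test_that("bulk formation errors name the shortfall and respects phenotype", {
  v <- simulate_parental_variants(small_genome, small_causal,
                                  mutation_model(0), seed = 1)
  pop <- simulate_f2_population(v, small_genome, n = 40, seed = 8)
  pop <- assign_phenotypes(pop, small_causal)
  n_mut <- sum(pop$phenotype == "mutant")
  expect_error(form_bulks(pop, bulk_design(n_mut + 1, 1)),
               sprintf("only %d mutant", n_mut))
  b <- form_bulks(pop, bulk_design(pmin(n_mut, 5), 5), seed = 9)
  expect_length(intersect(b$mutant, b$wild), 0)
  # recessive selection: mutant bulk is fixed for the causal allele
  expect_equal(unname(bulk_allele_freq(pop, b$mutant)[1]), 1)
})

test_that("wild-bulk causal allele frequency averages 1/3", {
  v <- simulate_parental_variants(small_genome, small_causal,
                                  mutation_model(0), seed = 1)
  set.seed(10)
  freqs <- replicate(60, {
    pop <- simulate_f2_population(v, small_genome, n = 400)
    pop <- assign_phenotypes(pop, small_causal)
    b <- form_bulks(pop, bulk_design(20, 200))
    unname(bulk_allele_freq(pop, b$wild)[1])
  })
  se <- stats::sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 1 / 3), 3 * se)
})

test_that("read counts follow the bulk allele frequency", {
  v <- data.frame(chrom = "c1", pos = seq_len(10000), ref = "G", alt = "A",
                  causal = c(TRUE, rep(FALSE, 9999)))
  g <- genome_spec("c1", 1e6, 100)
  pop <- list(genotypes = matrix(1L, nrow = 10, ncol = 10000,
                                 dimnames = list(NULL, paste0("c1:", v$pos))),
              variants = v, genome = g)
  class(pop) <- "f2_population"
  pop$phenotype <- rep("wild", 10)
  pop$causal <- causal_locus("c1", 1, "G", "A")
  bulks <- structure(list(mutant = 1:5, wild = 6:10,
                          design = bulk_design(5, 5)), class = "bulks")
  # all-heterozygous bulks: true allele frequency is exactly 0.5 everywhere
  ds <- simulate_read_counts(pop, bulks, depth_model(30, 0), seed = 11)
  frac <- with(ds$counts, sum(mut_alt) / sum(mut_ref + mut_alt))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / sum(ds$counts$mut_ref + ds$counts$mut_alt)))

  # error-free extremes: p = 1 gives alt = depth, p = 0 gives alt = 0
  pop$genotypes[,] <- 2L
  ds1 <- simulate_read_counts(pop, bulks, depth_model(20, 0), seed = 12)
  expect_true(all(ds1$counts$mut_ref == 0))
  pop$genotypes[,] <- 0L
  ds0 <- simulate_read_counts(pop, bulks, depth_model(20, 0), seed = 13)
  expect_true(all(ds0$counts$mut_alt == 0))
})

test_that("identical seeds give identical datasets end to end", {
  d1 <- simulate_mapping_experiment(n_f2 = 100, seed = 42)
  d2 <- simulate_mapping_experiment(n_f2 = 100, seed = 42)
  expect_identical(d1$counts, d2$counts)
})
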