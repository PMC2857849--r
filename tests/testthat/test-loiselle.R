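make_panel <- function(cnt) {
  geno(cnt, ids = sprintf("i%02d", seq_len(nrow(cnt))),
       map = data.frame(chrom = "chr1",
                        snp = sprintf("s%02d", seq_len(ncol(cnt))),
                        pos = seq(0.1, 0.9, length.out = ncol(cnt))))
}

test_that("hand-evaluated single-locus cases match the estimator", {
  # 10 diploids, p = 0.5, n_l = 20; individuals 1 and 2 heterozygous:
  # cross-term 0, bias 2*0.25/19, denominator 2*0.25 -> 1/19
  cnt <- matrix(1, 10, 1)
  M <- loiselle_relatedness(make_panel(cnt))
  expect_equal(M[1, 2], 1 / 19, tolerance = 1e-12)
  expect_true(is.na(M[1, 1])) # diagonal left blank

  # individuals 1 and 2 homozygous for the counted allele, p still 0.5:
  # (0.5 + 0.5/19)/0.5
  cnt2 <- matrix(c(2, 2, 1, 1, 1, 1, 1, 1, 0, 0), 10, 1)
  M2 <- loiselle_relatedness(make_panel(cnt2))
  expect_equal(M2[1, 2], (0.5 + 0.5 / 19) / 0.5, tolerance = 1e-12)
})

test_that("locus order does not change the matrix", {
  G <- fixture_geno(n = 5, L = 6, seed = 7)
  M <- loiselle_relatedness(G)
  perm <- c(4, 1, 6, 3, 5, 2)
  Gp <- geno(G$counts[, perm], ids = G$ids, map = G$map[perm, ])
  Mp <- loiselle_relatedness(Gp)
  expect_equal(unclass(M)[, ], unclass(Mp)[, ], tolerance = 1e-12)
})

test_that("estimator equals the naive quadruple-loop oracle", {
  cases <- list(
    fixture_geno(n = 5, L = 4, seed = 1),
    fixture_geno(n = 4, L = 4, seed = 2),
    fixture_geno(n = 5, L = 3, seed = 3, missing = 3),
    fixture_geno(n = 3, L = 4, seed = 4, missing = 2)
  )
  for (k in seq_along(cases)) {
    G <- cases[[k]]
    M <- loiselle_relatedness(G)
    O <- loiselle_naive(G$counts)
    expect_equal(unname(unclass(M)[, ]), O, tolerance = 1e-12,
                 label = paste("panel", k))
  }
})

test_that("monomorphic-only panels are rejected", {
  cnt <- matrix(c(0, 0, 0, 2, 2, 2), 3, 2)
  expect_error(loiselle_relatedness(make_panel(cnt)), "monomorphic")
})

test_that("Loiselle values of unrelated HWE individuals centre on zero", {
  set.seed(99)
  reps <- 50
  means <- replicate(reps, {
    p <- runif(30, 0.2, 0.8)
    cnt <- sapply(p, function(pp) rbinom(20, 2, pp))
    M <- loiselle_relatedness(make_panel(cnt))
    mean(M[upper.tri(M)])
  })
  se <- sd(means) / sqrt(reps)
  expect_lt(abs(mean(means)), 3 * se + 0.005)
})

test_that("a duplicated individual is its copy's closest relative", {
  set.seed(5)
  p <- runif(25, 0.2, 0.8)
  cnt <- sapply(p, function(pp) rbinom(12, 2, pp))
  cnt[12, ] <- cnt[1, ] # individual 12 duplicates individual 1
  M <- loiselle_relatedness(make_panel(cnt))
  expect_equal(unname(which.max(M[1, -1])), 11L) # position of i12
})

test_that("full sibs are more related than unrelated animals", {
  set.seed(21)
  pop <- simulate_population(small_sim_config(seed = 21))
  G <- subset_chromosome(pop$genotypes, "chr1")
  M <- loiselle_relatedness(G)
  ped <- pop$pedigree
  kids <- ped[!is.na(ped$sire), ]
  fam <- split(kids$id, paste(kids$sire, kids$dam))
  sib_pairs <- do.call(rbind, lapply(fam[lengths(fam) >= 2], function(f) {
    cbind(f[1], f[2])
  }))
  founders <- ped$id[is.na(ped$sire)]
  unrel_pairs <- cbind(founders[seq(1, 18, 2)], founders[seq(2, 18, 2)])
  sib_vals <- M[cbind(sib_pairs[, 1], sib_pairs[, 2])]
  unrel_vals <- M[cbind(unrel_pairs[, 1], unrel_pairs[, 2])]
  expect_gt(mean(sib_vals), mean(unrel_vals))
})

test_that("fill_diagonal applies the selfcoancestry rule", {
  peds <- fixture_pedigrees()
  ped <- as_pedigree(peds$trio)
  # construct a marker matrix where the parents' relationship is 0.2
  V <- matrix(c(NA, 0.2, 0.1,
                0.2, NA, 0.3,
                0.1, 0.3, NA), 3, 3)
  M <- relmat(V, ids = c("S", "D", "K"), method = "SNPL")
  filled <- fill_diagonal(M, ped)
  expect_equal(filled["K", "K"], 1 + 0.5 * 0.2)
  expect_equal(filled["S", "S"], 1.0) # founder: unknown parents
  expect_false(anyNA(unclass(filled)[, ]))
  expect_error(fill_diagonal(M, as_pedigree(peds$founders)), "absent")
})
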