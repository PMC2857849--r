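# simulate phenotypes from a pedigree A-matrix covariance
simulate_from_A <- function(A, h2, vp = 20, seed = 1) {
  set.seed(seed)
  V <- unclass(A)[, ]
  n <- nrow(V)
  s2a <- vp * h2
  s2e <- vp * (1 - h2)
  a <- as.numeric(t(chol(V)) %*% rnorm(n)) * sqrt(s2a)
  tibble::tibble(id = rownames(V),
                 value = 5 + a + rnorm(n, 0, sqrt(s2e)))
}

# a 1-generation pedigree with n_f founders and n_o full-sib offspring
grid_pedigree <- function(n_f, n_o) {
  stopifnot(n_f %% 2 == 0)
  sires <- sprintf("S%03d", seq_len(n_f / 2))
  dams <- sprintf("D%03d", seq_len(n_f / 2))
  kids <- sprintf("K%04d", seq_len(n_o))
  pair <- rep(seq_len(n_f / 2), length.out = n_o)
  as_pedigree(data.frame(
    id = c(sires, dams, kids),
    sire = c(rep(0, n_f), sires[pair]),
    dam = c(rep(0, n_f), dams[pair])
  ))
}

test_that("solve_blup matches the closed-form GLS oracle", {
  ped <- grid_pedigree(20, 60) # 80 animals
  A <- additive_relationship(ped)
  # phenotype a subset so non-phenotyped animals are predicted through G
  set.seed(3)
  obs_ids <- sample(ped$id, 50)
  ph <- simulate_from_A(A, h2 = 0.4, seed = 3)
  ph <- ph[ph$id %in% obs_ids, ]
  vc <- list(sigma2_a = 8, sigma2_e = 12)
  bv <- solve_blup(ph, A, vc)
  oracle <- blup_gls(ph$value, match(ph$id, rownames(A)),
                     unclass(A)[, ], vc$sigma2_a, vc$sigma2_e)
  expect_equal(attr(bv, "mu"), oracle$mu, tolerance = 1e-6)
  expect_equal(bv$ebv, oracle$a, tolerance = 1e-6)
})

test_that("pure-noise data yields near-zero heritability", {
  ped <- grid_pedigree(100, 400) # 500 animals
  A <- additive_relationship(ped)
  h2s <- vapply(1:10, function(s) {
    set.seed(100 + s)
    ph <- tibble::tibble(id = ped$id, value = rnorm(500))
    fit_reml(ph, A)$h2
  }, numeric(1))
  expect_lte(mean(h2s), 0.1)
})

test_that("REML fits are deterministic and monotone in log-likelihood", {
  ped <- grid_pedigree(20, 80)
  A <- additive_relationship(ped)
  ph <- simulate_from_A(A, h2 = 0.5, seed = 7)
  f1 <- fit_reml(ph, A)
  f2 <- fit_reml(ph, A)
  expect_identical(f1$sigma2_a, f2$sigma2_a)
  expect_identical(f1$loglik, f2$loglik)
  expect_true(all(diff(f1$loglik_trace) >= -1e-8 * abs(f1$loglik)))
})

test_that("adding a constant to phenotypes shifts mu and not the EBVs", {
  ped <- grid_pedigree(20, 60)
  A <- additive_relationship(ped)
  ph <- simulate_from_A(A, h2 = 0.5, seed = 11)
  vc <- list(sigma2_a = 10, sigma2_e = 10)
  b0 <- solve_blup(ph, A, vc)
  ph_shift <- ph
  ph_shift$value <- ph$value + 100
  b1 <- solve_blup(ph_shift, A, vc)
  expect_equal(attr(b1, "mu"), attr(b0, "mu") + 100, tolerance = 1e-8)
  expect_equal(b1$ebv, b0$ebv, tolerance = 1e-8)
})

test_that("the solver is agnostic to the matrix provenance tag", {
  ped <- grid_pedigree(10, 30)
  A <- additive_relationship(ped)
  ph <- simulate_from_A(A, h2 = 0.5, seed = 13)
  vc <- list(sigma2_a = 10, sigma2_e = 10)
  as_marker <- relmat(unclass(A)[, ], ids = rownames(A), method = "SNPL")
  expect_equal(solve_blup(ph, A, vc)$ebv,
               solve_blup(ph, as_marker, vc)$ebv, tolerance = 1e-12)
})

test_that("vanishing genetic variance shrinks all EBVs to zero", {
  ped <- grid_pedigree(10, 30)
  A <- additive_relationship(ped)
  ph <- simulate_from_A(A, h2 = 0.5, seed = 17)
  bv <- solve_blup(ph, A, list(sigma2_a = 0, sigma2_e = 10))
  expect_true(all(bv$ebv == 0))
  expect_equal(attr(bv, "mu"), mean(ph$value))
})

test_that("a non-phenotyped identical twin gets its twin's EBV", {
  ped <- grid_pedigree(10, 20)
  A <- additive_relationship(ped)
  V <- unclass(A)[, ]
  # duplicate the first offspring's row/column as a new animal TWIN
  k <- which(rownames(V) == "K0001")
  V2 <- rbind(cbind(V, V[, k]), c(V[k, ], V[k, k]))
  ids2 <- c(rownames(V), "TWIN")
  G2 <- bend_to_pd(relmat(V2, ids = ids2), 1e-8)
  ph <- simulate_from_A(A, h2 = 0.5, seed = 19)
  ph <- ph[ph$id != "TWIN", ]
  bv <- solve_blup(ph, G2, list(sigma2_a = 10, sigma2_e = 10))
  # the bending shift perturbs the duplicate slightly; equality is tight
  expect_equal(bv$ebv[bv$id == "TWIN"], bv$ebv[bv$id == "K0001"],
               tolerance = 1e-4)
})

test_that("heritability worked examples and guards", {
  expect_equal(round(heritability(19.23, 21.32), 2), 0.47)
  expect_equal(round(heritability(6.50, 9.58), 2), 0.40)
  expect_equal(heritability(0, 10), 0)
  expect_error(heritability(0, 0), "undefined")
  expect_error(heritability(-1, 2), "nonnegative")
})

test_that("tidy and glance summarise a fit", {
  ped <- grid_pedigree(10, 30)
  A <- additive_relationship(ped)
  ph <- simulate_from_A(A, h2 = 0.5, seed = 23)
  fit <- fit_reml(ph, A)
  td <- tidy(fit)
  expect_equal(td$term, c("sigma2_a", "sigma2_e", "mu"))
  gl <- glance(fit)
  expect_equal(gl$h2, fit$h2)
  expect_equal(heritability(fit), fit$h2)
  expect_s3_class(td, "tbl_df")
})

test_that("non-phenotyped full sibs are identical under pedigree BLUP but
           differ under a marker matrix", {
  pop <- simulate_population(small_sim_config(seed = 31))
  ped <- pop$pedigree
  A <- additive_relationship(ped)
  ph <- pop$phenotypes[pop$phenotypes$time == 530, c("id", "value")]
  fit <- fit_reml(ph, A)
  bv <- solve_blup(ph, A, fit)
  # masked full-sib family with no phenotyped descendants
  masked <- pop$masked_ids
  kids <- ped[ped$id %in% masked, ]
  fam <- split(kids$id, paste(kids$sire, kids$dam))
  fam <- fam[lengths(fam) >= 3][[1]]
  ped_ebv <- bv$ebv[match(fam, bv$id)]
  expect_lt(max(ped_ebv) - min(ped_ebv), 1e-8)

  # same family under a marker matrix: Mendelian sampling separates sibs
  Gm <- subset_chromosome(pop$genotypes, "chr1")
  M <- bend_to_pd(fill_diagonal(loiselle_relatedness(Gm), ped), 1e-6)
  bvm <- solve_blup(ph, M, fit_reml(ph, M))
  mark_ebv <- bvm$ebv[match(fam, bvm$id)]
  expect_gt(max(mark_ebv) - min(mark_ebv), 1e-4)
})
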