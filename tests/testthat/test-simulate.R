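test_that("configuration invariants are validated", {
  expect_error(sim_config(n_founders = 0), "positive|at least")
  expect_error(sim_config(target_heritability = 1.2), "proportion")
  expect_error(sim_config(time_points = c(0, 132, 132)), "increasing")
  expect_error(sim_config(n_qtl = 10^6), "more QTLs")
  expect_error(sim_config(n_validation_unphenotyped = 10^6),
               "final generation")
  expect_error(sim_config(extrapolation_time = 100), "exceed")
})

test_that("the same seed reproduces the population exactly", {
  p1 <- simulate_population(small_sim_config(seed = 7))
  p2 <- simulate_population(small_sim_config(seed = 7))
  expect_identical(p1$pedigree, p2$pedigree)
  expect_identical(p1$genotypes$counts, p2$genotypes$counts)
  expect_identical(p1$phenotypes, p2$phenotypes)
  expect_identical(p1$true_bv, p2$true_bv)
  p3 <- simulate_population(small_sim_config(seed = 8))
  expect_false(identical(p1$genotypes$counts, p3$genotypes$counts))
})

test_that("no QTLs means no genetic signal", {
  pop <- simulate_population(small_sim_config(seed = 9, n_qtl = 0))
  expect_equal(var(pop$true_bv$true_bv), 0)
  # phenotypes still have residual noise
  expect_gt(var(pop$phenotypes$value[pop$phenotypes$time == 530]), 0)
})

test_that("gene dropping conserves founder alleles", {
  pop <- simulate_population(small_sim_config(seed = 10))
  nf <- pop$config$n_founders
  O1 <- pop$founder_origin$paternal
  O2 <- pop$founder_origin$maternal
  L <- n_loci(pop$genotypes)
  idx <- seq_len(nf)
  # founders carry their own labels (1..nf paternal, nf+1..2nf maternal)
  expect_true(all(O1[idx, ] == matrix(idx, nf, L)))
  expect_true(all(O2[idx, ] == matrix(nf + idx, nf, L)))
  # every allele copy in the population traces to a founder haplotype
  expect_true(all(O1 >= 1 & O1 <= 2 * nf))
  expect_true(all(O2 >= 1 & O2 <= 2 * nf))
  # transmission: a child's haplotype labels at every locus come from the
  # corresponding parent's two haplotypes
  ped <- pop$pedigree
  pos <- match(ped$id, pop$genotypes$ids)
  non_f <- which(!is.na(ped$sire))
  for (i in sample(non_f, 30)) {
    si <- pos[match(ped$sire[i], ped$id)]
    di <- pos[match(ped$dam[i], ped$id)]
    ci <- pos[i]
    expect_true(all(O1[ci, ] == O1[si, ] | O1[ci, ] == O2[si, ]))
    expect_true(all(O2[ci, ] == O1[di, ] | O2[ci, ] == O2[di, ]))
  }
})

test_that("realized heritability tracks the target across seeds", {
  h2_by_time <- sapply(1:10, function(s) {
    pop <- simulate_population(small_sim_config(seed = 200 + s))
    ph <- pop$phenotypes
    tb <- pop$true_bv
    vapply(pop$config$time_points, function(tp) {
      bv <- tb$true_bv[tb$time == tp]
      vg <- var(bv)
      keep <- ph[ph$time == tp, ]
      resid <- keep$value - (10 + 0.05 * tp) -
        tb$true_bv[tb$time == tp][match(keep$id, tb$id[tb$time == tp])]
      vg / (vg + var(resid))
    }, numeric(1))
  })
  expect_true(all(abs(rowMeans(h2_by_time) - 0.5) < 0.05))
})

test_that("genetic variance grows with time and correlations decay with lag", {
  pop <- simulate_population(small_sim_config(seed = 12))
  vg <- vapply(pop$config$time_points, function(tp) {
    var(pop$true_bv$true_bv[pop$true_bv$time == tp])
  }, numeric(1))
  expect_true(all(diff(vg) > 0))
})

test_that("population files round-trip and masking is respected", {
  pop <- simulate_population(small_sim_config(seed = 13))
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  back <- read_population(dir)
  expect_equal(as.data.frame(back$pedigree)[, c("id", "sire", "dam")],
               as.data.frame(pop$pedigree)[, c("id", "sire", "dam")])
  expect_equal(back$genotypes$counts, pop$genotypes$counts)
  expect_equal(back$phenotypes$value, pop$phenotypes$value)
  expect_equal(back$true_bv$true_bv, pop$true_bv$true_bv)
  # masked animals absent from phenotypes, present everywhere else
  expect_false(any(pop$masked_ids %in% back$phenotypes$id))
  expect_true(all(pop$masked_ids %in% back$pedigree$id))
  expect_true(all(pop$masked_ids %in% back$genotypes$ids))
  # genotype rows align with pedigree rows
  expect_equal(length(back$genotypes$ids), nrow(back$pedigree))
})

test_that("masked validation families have no phenotyped member", {
  pop <- simulate_population(small_sim_config(seed = 14))
  ped <- pop$pedigree
  kids <- ped[ped$id %in% pop$masked_ids, ]
  fams <- unique(paste(kids$sire, kids$dam))
  # all but possibly one (partially masked) family is fully masked
  full_fam <- vapply(fams, function(f) {
    members <- ped$id[!is.na(ped$sire) & paste(ped$sire, ped$dam) == f]
    all(members %in% pop$masked_ids)
  }, logical(1))
  expect_gte(sum(full_fam), length(fams) - 1L)
})
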