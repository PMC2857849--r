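# Independent oracles used to freeze expected values. These deliberately use
# different algorithms from the package (recursion instead of the tabular
# method, explicit quadruple loops instead of matrix algebra, GLS closed
# forms instead of the mixed model equations).

# Recursive coancestry (kinship) oracle: f(i,j) by Malecot's recursion on a
# sorted pedigree given as parent index vectors (NA = unknown).
kinship_recursive <- function(si, di) {
  n <- length(si)
  f <- matrix(NA_real_, n, n)
  fk <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (!is.na(f[i, j])) return(f[i, j])
    val <- if (i == j) {
      0.5 * (1 + fk(ifelse(is.na(si[i]), 0L, si[i]),
                    ifelse(is.na(di[i]), 0L, di[i])))
    } else {
      a <- max(i, j) # later-born individual (parents precede offspring)
      b <- min(i, j)
      0.5 * (fk(b, ifelse(is.na(si[a]), 0L, si[a])) +
               fk(b, ifelse(is.na(di[a]), 0L, di[a])))
    }
    f[i, j] <<- val
    f[j, i] <<- val
    val
  }
  for (i in seq_len(n)) for (j in seq_len(i)) fk(i, j)
  f
}

# Naive Loiselle oracle: per locus, per allele, per chromosome-copy pair.
# Genotypes as dosage matrix (NA = missing); frequencies from the full
# sample; loci with a missing call in either member are skipped for that
# pair (numerator and denominator alike).
loiselle_naive <- function(cnt) {
  n <- nrow(cnt)
  L <- ncol(cnt)
  n_l <- 2 * colSums(!is.na(cnt))
  p <- colSums(cnt, na.rm = TRUE) / n_l
  # haplotype indicator pairs consistent with the dosage (order irrelevant
  # for the mean cross-product): dosage g -> copies carry g/2 on average
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- 0
      den <- 0
      for (l in seq_len(L)) {
        gi <- cnt[i, l]
        gj <- cnt[j, l]
        if (is.na(gi) || is.na(gj)) next
        pl <- p[l]
        if (pl <= 0 || pl >= 1) next
        # explicit copies: x = 1 if the copy carries the counted allele
        xi <- c(gi >= 1, gi == 2) * 1 # two chromosome copies
        xj <- c(gj >= 1, gj == 2) * 1
        for (a in 1:2) { # allele a = counted, then alternate
          pa <- if (a == 1) pl else 1 - pl
          ya <- if (a == 1) xi else 1 - xi
          yb <- if (a == 1) xj else 1 - xj
          cross <- 0
          for (ci in 1:2) for (cj in 1:2) {
            cross <- cross + (ya[ci] - pa) * (yb[cj] - pa)
          }
          num <- num + cross / 4 + pa * (1 - pa) / (n_l[l] - 1)
          den <- den + pa * (1 - pa)
        }
      }
      out[i, j] <- num / den
      out[j, i] <- out[i, j]
    }
  }
  out
}

# Closed-form GLS / conditional-expectation oracle for BLUP:
# mu = (X'V^-1 X)^-1 X'V^-1 y,  a_hat = s2a * G Z' V^-1 (y - X mu),
# V = Z G Z' s2a + I s2e.
blup_gls <- function(y, obs_idx, Gfull, s2a, s2e) {
  n <- length(y)
  N <- nrow(Gfull)
  Z <- matrix(0, n, N)
  Z[cbind(seq_len(n), obs_idx)] <- 1
  V <- Z %*% Gfull %*% t(Z) * s2a + diag(s2e, n)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  mu <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)[1, 1]
  a <- s2a * Gfull %*% t(Z) %*% Vi %*% (y - mu)
  list(mu = mu, a = as.numeric(a))
}

# small pedigree fixtures (id/sire/dam data frames; 0 = unknown)
fixture_pedigrees <- function() {
  list(
    founders = data.frame(id = c("A", "B", "C"), sire = 0, dam = 0),
    trio = data.frame(id = c("S", "D", "K"),
                      sire = c(0, 0, "S"), dam = c(0, 0, "D")),
    full_sibs = data.frame(id = c("S", "D", "K1", "K2"),
                           sire = c(0, 0, "S", "S"),
                           dam = c(0, 0, "D", "D")),
    parent_offspring_mating = data.frame(
      id = c("S", "D", "K", "M"),
      sire = c(0, 0, "S", "S"), dam = c(0, 0, "D", "K")),
    three_generations = data.frame(
      id = c("A", "B", "C", "D", "E", "F", "G", "H"),
      sire = c(0, 0, 0, "A", "A", "C", "E", "E"),
      dam = c(0, 0, 0, "B", "B", "D", "F", "F")),
    half_sibs_inbred = data.frame(
      id = c("A", "B", "C", "X", "Y", "Z", "W"),
      sire = c(0, 0, 0, "A", "A", "X", "X"),
      dam = c(0, 0, 0, "B", "C", "Y", "Y")),
    twelve = data.frame(
      id = sprintf("I%02d", 1:12),
      sire = c(0, 0, 0, 0, "I01", "I01", "I03", "I05", "I05", "I07",
               "I09", "I09"),
      dam = c(0, 0, 0, 0, "I02", "I04", "I04", "I06", "I06", "I08",
              "I10", "I10"))
  )
}

# deterministic small genotype panel
fixture_geno <- function(n = 5, L = 4, seed = 42, missing = 0) {
  set.seed(seed)
  cnt <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  if (missing > 0) {
    miss <- sample(length(cnt), missing)
    cnt[miss] <- NA
  }
  # ensure every locus polymorphic and has a call
  for (l in seq_len(L)) {
    col <- cnt[, l]
    if (all(is.na(col))) cnt[1, l] <- 1
    v <- col[!is.na(col)]
    if (length(unique(v)) < 2) cnt[which(!is.na(col))[1], l] <-
        if (v[1] == 0) 2 else 0
  }
  geno(cnt, ids = sprintf("i%02d", seq_len(n)),
       map = data.frame(chrom = "chr1", snp = sprintf("s%02d", seq_len(L)),
                        pos = seq(0.1, 0.9, length.out = L)))
}

# small, fast simulation config for tests
small_sim_config <- function(seed = 1, n_qtl = 10, ...) {
  sim_config(n_founders = 20, n_generations = 2, offspring_per_mating = 6,
             n_chromosomes = 2, snps_per_chromosome = 40,
             n_qtl = n_qtl, n_validation_unphenotyped = 60, seed = seed, ...)
}
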