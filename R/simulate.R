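#' Simulation configuration
#'
#' Parameters of the synthetic population generator. The defaults emulate a
#' multi-generation full-sib-family population with a growth-like trait
#' recorded at five time points, whose genetic and residual variances grow
#' with time at constant heritability, and with a held-out final generation
#' whose true breeding values at a later time are retained for validation.
#'
#' @param n_founders Number of founder animals (generation 0); sexes are
#'   balanced.
#' @param n_generations Number of offspring generations bred from the
#'   founders.
#' @param offspring_per_mating Full-sib family size (every mating produces
#'   this many offspring).
#' @param n_chromosomes,snps_per_chromosome,chromosome_length_morgans Genome
#'   layout; SNP positions are drawn uniformly along each chromosome.
#' @param n_qtl Number of panel SNPs that act as QTLs on the trait
#'   trajectory.
#' @param fraction_qtl_variance_on_chr1 Share of trajectory-coefficient
#'   genetic variance contributed by chromosome-1 QTLs.
#' @param time_points Phenotyping times (strictly increasing).
#' @param extrapolation_time Held-out time at which true breeding values are
#'   retained for validation.
#' @param target_heritability Heritability at every phenotyping time;
#'   residual variances are scaled to the realized genetic variance per time
#'   point to hold it.
#' @param trajectory_var Genetic variances of the three trajectory
#'   coefficients (intercept, slope, curvature). The defaults give a genetic
#'   variance rising from about 0.05 at time 0 to about 19 at time 530.
#' @param n_validation_unphenotyped Number of final-generation animals whose
#'   phenotypes are masked at all time points.
#' @param seed Single global seed for all randomness.
#' @return A validated `snpblup_sim_config` list.
#' @export
sim_config <- function(n_founders = 60,
                       n_generations = 2,
                       offspring_per_mating = 10,
                       n_chromosomes = 5,
                       snps_per_chromosome = 90,
                       chromosome_length_morgans = 1,
                       n_qtl = 20,
                       fraction_qtl_variance_on_chr1 = 0.8,
                       time_points = c(0, 132, 265, 397, 530),
                       extrapolation_time = 600,
                       target_heritability = 0.5,
                       trajectory_var = c(0.05, 4.3e-5, 8.9e-11),
                       n_validation_unphenotyped = 1000,
                       seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    offspring_per_mating = as.integer(offspring_per_mating),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    chromosome_length_morgans = chromosome_length_morgans,
    n_qtl = as.integer(n_qtl),
    fraction_qtl_variance_on_chr1 = fraction_qtl_variance_on_chr1,
    time_points = time_points,
    extrapolation_time = extrapolation_time,
    target_heritability = target_heritability,
    trajectory_var = trajectory_var,
    n_validation_unphenotyped = as.integer(n_validation_unphenotyped),
    seed = as.integer(seed)
  )
  counts <- c("n_founders", "n_generations", "offspring_per_mating",
              "n_chromosomes", "snps_per_chromosome")
  for (nm in counts) {
    if (cfg[[nm]] < 1) stop(nm, " must be a positive count", call. = FALSE)
  }
  if (cfg$n_qtl < 0) stop("n_qtl must be nonnegative", call. = FALSE)
  if (cfg$n_founders < 2) stop("need at least 2 founders", call. = FALSE)
  if (cfg$chromosome_length_morgans <= 0) {
    stop("chromosome_length_morgans must be positive", call. = FALSE)
  }
  props <- c("fraction_qtl_variance_on_chr1", "target_heritability")
  for (nm in props) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop(nm, " must be a proportion in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$target_heritability >= 1) {
    stop("target_heritability must be below 1", call. = FALSE)
  }
  if (any(diff(cfg$time_points) <= 0)) {
    stop("time points must be strictly increasing", call. = FALSE)
  }
  if (length(cfg$time_points) < 3) {
    stop("at least 3 phenotyping time points are required", call. = FALSE)
  }
  if (cfg$extrapolation_time <= max(cfg$time_points)) {
    stop("extrapolation_time must exceed the last phenotyping time",
         call. = FALSE)
  }
  if (length(cfg$trajectory_var) != 3 || any(cfg$trajectory_var < 0)) {
    stop("trajectory_var must be 3 nonnegative variances", call. = FALSE)
  }
  n_loci_total <- cfg$n_chromosomes * cfg$snps_per_chromosome
  if (cfg$n_qtl > n_loci_total) {
    stop("more QTLs (", cfg$n_qtl, ") than loci (", n_loci_total, ")",
         call. = FALSE)
  }
  sizes <- generation_sizes(cfg)
  final_n <- sizes[length(sizes)]
  if (cfg$n_validation_unphenotyped > final_n) {
    stop("n_validation_unphenotyped (", cfg$n_validation_unphenotyped,
         ") exceeds the final generation size (", final_n, ")",
         call. = FALSE)
  }
  structure(cfg, class = "snpblup_sim_config")
}

generation_sizes <- function(cfg) {
  sizes <- cfg$n_founders
  for (g in seq_len(cfg$n_generations)) {
    prev <- sizes[g]
    n_m <- ceiling(prev / 2)
    n_f <- prev - n_m
    sizes <- c(sizes, min(n_m, n_f) * cfg$offspring_per_mating)
  }
  sizes
}

#' Simulate a population for the relationship-matrix comparison
#'
#' Generates a discrete-generation pedigree of full-sib families by random
#' pairing within each generation, drops founder haplotypes through the
#' pedigree with Haldane-model recombination, assigns additive QTL effects
#' to the three coefficients of each animal's quadratic breeding-value
#' trajectory (so true breeding values are exactly quadratic in time), and
#' records phenotypes `value = mean(t) + true_bv(t) + residual` at each
#' phenotyping time with residual variance set from the realized genetic
#' variance to hold the target heritability. A block of final-generation
#' animals is masked: they keep genotypes and pedigree links but have no
#' phenotype records.
#'
#' Founder allele frequencies are Uniform(0.05, 0.5) for the counted allele;
#' founder haplotypes are drawn under Hardy-Weinberg equilibrium. QTLs are
#' panel SNPs; their effects are rescaled so that chromosome-1 QTLs
#' contribute `fraction_qtl_variance_on_chr1` of each coefficient's
#' realized genetic variance.
#'
#' @param config A [sim_config()].
#' @return A `snpblup_population`: list with `pedigree` (tibble: id, sire,
#'   dam, generation, sex), `genotypes` (a [geno]), `qtl` (tibble of QTL loci
#'   and scaled effects), `coefficients` (tibble: id, beta0, beta1, beta2),
#'   `true_bv` (tibble: id, time, true_bv; includes the extrapolation time),
#'   `phenotypes` (tibble: id, time, value; masked animals absent),
#'   `masked_ids`, `founder_origin` (two haplotype-origin matrices), and
#'   `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "snpblup_sim_config"))
  set.seed(config$seed)
  cfg <- config

  ## pedigree ----
  sizes <- generation_sizes(cfg)
  n_total <- sum(sizes)
  ids <- sprintf("ID%05d", seq_len(n_total))
  generation <- rep(seq_along(sizes) - 1L, sizes)
  sex <- character(n_total)
  sire <- rep(NA_character_, n_total)
  dam <- rep(NA_character_, n_total)
  # alternating sexes keep the sex ratio balanced in every family
  sex[generation == 0L] <- rep_len(c("M", "F"), sizes[1])
  offset <- sizes[1]
  resample <- function(x, n = length(x)) x[sample.int(length(x), n)]
  for (g in seq_len(cfg$n_generations)) {
    prev_idx <- which(generation == g - 1L)
    males <- resample(prev_idx[sex[prev_idx] == "M"])
    females <- resample(prev_idx[sex[prev_idx] == "F"])
    n_mat <- min(length(males), length(females))
    gen_idx <- offset + seq_len(sizes[g + 1])
    fam <- rep(seq_len(n_mat), each = cfg$offspring_per_mating)
    sire[gen_idx] <- ids[males[fam]]
    dam[gen_idx] <- ids[females[fam]]
    sex[gen_idx] <- rep_len(c("M", "F"), length(gen_idx))
    offset <- offset + sizes[g + 1]
  }
  ped <- new_pedigree(tibble::tibble(
    id = ids, sire = sire, dam = dam,
    generation = generation, sex = sex
  ))

  ## genome ----
  L_chr <- cfg$snps_per_chromosome
  n_chr <- cfg$n_chromosomes
  L <- L_chr * n_chr
  chr_fmt <- if (n_chr > 9) "chr%02d" else "chr%d"
  map <- tibble::tibble(
    chrom = rep(sprintf(chr_fmt, seq_len(n_chr)), each = L_chr),
    pos = as.numeric(vapply(seq_len(n_chr), function(k) {
      sort(stats::runif(L_chr, 0, cfg$chromosome_length_morgans))
    }, numeric(L_chr)))
  )
  map$snp <- sprintf("%s_snp%03d", map$chrom, rep(seq_len(L_chr), n_chr))
  p_founder <- stats::runif(L, 0.05, 0.5)

  # per-locus switch probabilities for gamete formation: a fresh 0.5 draw at
  # each chromosome start, Haldane recombination fraction between neighbours
  chr_start <- !duplicated(map$chrom)
  dist <- c(0, diff(map$pos))
  switch_p <- ifelse(chr_start, 0.5, 0.5 * (1 - exp(-2 * dist)))

  H1 <- matrix(0L, n_total, L)
  H2 <- matrix(0L, n_total, L)
  O1 <- matrix(0L, n_total, L) # founder-haplotype origin labels
  O2 <- matrix(0L, n_total, L)
  nf <- sizes[1]
  H1[seq_len(nf), ] <- matrix(stats::rbinom(nf * L, 1, rep(p_founder, each = nf)),
                              nf, L)
  H2[seq_len(nf), ] <- matrix(stats::rbinom(nf * L, 1, rep(p_founder, each = nf)),
                              nf, L)
  O1[seq_len(nf), ] <- matrix(seq_len(nf), nf, L)
  O2[seq_len(nf), ] <- matrix(nf + seq_len(nf), nf, L)

  idx_of <- stats::setNames(seq_len(n_total), ids)
  gamete_from <- function(par) {
    s <- cumsum(stats::runif(L) < switch_p) %% 2L
    list(
      allele = H1[par, ] * (1L - s) + H2[par, ] * s,
      origin = O1[par, ] * (1L - s) + O2[par, ] * s
    )
  }
  for (i in which(generation > 0L)) {
    gs <- gamete_from(idx_of[[sire[i]]])
    gd <- gamete_from(idx_of[[dam[i]]])
    H1[i, ] <- gs$allele
    O1[i, ] <- gs$origin
    H2[i, ] <- gd$allele
    O2[i, ] <- gd$origin
  }
  counts <- H1 + H2
  genotypes <- geno(counts, ids = ids, map = map)

  ## QTL effects on trajectory coefficients ----
  betas <- matrix(0, n_total, 3)
  qtl <- tibble::tibble(chrom = character(0), snp = character(0),
                        pos = numeric(0), gamma0 = numeric(0),
                        gamma1 = numeric(0), gamma2 = numeric(0))
  if (cfg$n_qtl > 0) {
    chr1 <- which(genotypes$map$chrom == "chr1")
    other <- which(genotypes$map$chrom != "chr1")
    want_chr1 <- if (length(other) == 0) cfg$n_qtl else
      max(1L, min(length(chr1), ceiling(cfg$n_qtl / 2)))
    n_other <- min(length(other), cfg$n_qtl - want_chr1)
    qtl_idx <- c(sort(chr1[sample.int(length(chr1), want_chr1)]),
                 sort(other[sample.int(length(other), n_other)]))
    gamma <- matrix(stats::rnorm(length(qtl_idx) * 3), length(qtl_idx), 3)
    on_chr1 <- qtl_idx %in% chr1
    Z <- genotypes$counts[, qtl_idx, drop = FALSE]
    Z <- sweep(Z, 2, colMeans(Z)) # centred dosages
    f1 <- if (any(!on_chr1)) cfg$fraction_qtl_variance_on_chr1 else 1
    for (k in 1:3) {
      target <- cfg$trajectory_var[k]
      b_chr1 <- Z[, on_chr1, drop = FALSE] %*% gamma[on_chr1, k]
      b_rest <- Z[, !on_chr1, drop = FALSE] %*% gamma[!on_chr1, k]
      c1 <- scale_to_var(b_chr1, f1 * target)
      c2 <- scale_to_var(b_rest, (1 - f1) * target)
      gamma[on_chr1, k] <- gamma[on_chr1, k] * c1
      gamma[!on_chr1, k] <- gamma[!on_chr1, k] * c2
      betas[, k] <- c1 * b_chr1 + c2 * b_rest
    }
    betas <- sweep(betas, 2, colMeans(betas))
    qtl <- tibble::tibble(
      chrom = genotypes$map$chrom[qtl_idx],
      snp = genotypes$map$snp[qtl_idx],
      pos = genotypes$map$pos[qtl_idx],
      gamma0 = gamma[, 1], gamma1 = gamma[, 2], gamma2 = gamma[, 3]
    )
  }
  coefficients <- tibble::tibble(id = ids, beta0 = betas[, 1],
                                 beta1 = betas[, 2], beta2 = betas[, 3])

  ## true breeding values (exactly quadratic in time) ----
  all_times <- c(cfg$time_points, cfg$extrapolation_time)
  true_bv <- tidyr::expand_grid(id = ids, time = all_times)
  bmap <- match(true_bv$id, ids)
  true_bv$true_bv <- betas[bmap, 1] + betas[bmap, 2] * true_bv$time +
    betas[bmap, 3] * true_bv$time^2

  ## phenotypes with per-time residual variance holding h2 ----
  # mask whole full-sib families of the final generation until the
  # validation count is reached (last family possibly partial), so the
  # validation set contains families with no phenotyped member while the
  # rest of the final generation keeps its records
  final_idx <- which(generation == cfg$n_generations)
  masked_ids <- character(0)
  if (cfg$n_validation_unphenotyped > 0) {
    fam_key <- paste(sire[final_idx], dam[final_idx])
    fams <- unique(fam_key)
    fams <- fams[sample.int(length(fams))]
    take <- integer(0)
    for (f in fams) {
      if (length(take) >= cfg$n_validation_unphenotyped) break
      take <- c(take, final_idx[fam_key == f])
    }
    take <- take[seq_len(cfg$n_validation_unphenotyped)]
    masked_ids <- ids[sort(take)]
  }
  pheno_ids <- setdiff(ids, masked_ids)
  h2 <- cfg$target_heritability
  ph_rows <- lapply(cfg$time_points, function(tp) {
    bv_t <- betas[, 1] + betas[, 2] * tp + betas[, 3] * tp^2
    vg <- stats::var(bv_t)
    # zero genetic variance (e.g. no QTLs): unit residual noise
    sd_e <- if (vg > 0 && h2 > 0) sqrt(vg * (1 - h2) / h2) else 1
    keep <- match(pheno_ids, ids)
    tibble::tibble(
      id = pheno_ids,
      time = tp,
      value = 10 + 0.05 * tp + bv_t[keep] +
        stats::rnorm(length(keep), 0, sd_e)
    )
  })
  phenotypes <- dplyr::bind_rows(ph_rows)

  structure(
    list(
      pedigree = ped, genotypes = genotypes, qtl = qtl,
      coefficients = coefficients, true_bv = true_bv,
      phenotypes = phenotypes, masked_ids = masked_ids,
      founder_origin = list(paternal = O1, maternal = O2),
      config = cfg
    ),
    class = "snpblup_population"
  )
}

scale_to_var <- function(b, target) {
  v <- stats::var(as.numeric(b))
  if (length(b) == 0 || v == 0 || target <= 0) return(0)
  sqrt(target / v)
}

#' @export
print.snpblup_population <- function(x, ...) {
  cat(sprintf(
    "<simulated population> %d animals (%d generations), %d masked for validation\n  %d SNPs on %d chromosomes, %d QTLs\n",
    nrow(x$pedigree), x$config$n_generations + 1L, length(x$masked_ids),
    n_loci(x$genotypes), x$config$n_chromosomes, nrow(x$qtl)))
  invisible(x)
}

#' Write a simulated population to disk
#'
#' Emits `pedigree.csv` (id, sire, dam; unknown parent coded 0),
#' `genotypes.txt` + `map.txt` (see [write_genotypes()]),
#' `phenotypes.csv` (id, time, value; masked animals absent) and
#' `true_bv.csv` (id, time, true_bv). Round-trips through
#' [read_population()].
#'
#' @param pop A `snpblup_population`.
#' @param directory Output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_population <- function(pop, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ped_out <- data.frame(
    id = pop$pedigree$id,
    sire = ifelse(is.na(pop$pedigree$sire), "0", pop$pedigree$sire),
    dam = ifelse(is.na(pop$pedigree$dam), "0", pop$pedigree$dam)
  )
  utils::write.csv(ped_out, file.path(directory, "pedigree.csv"),
                   row.names = FALSE, quote = FALSE)
  write_genotypes(pop$genotypes, file.path(directory, "genotypes.txt"),
                  file.path(directory, "map.txt"))
  utils::write.csv(as.data.frame(pop$phenotypes),
                   file.path(directory, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(pop$true_bv),
                   file.path(directory, "true_bv.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(directory)
}

#' Read population files written by [write_population()]
#'
#' @param directory Directory containing `pedigree.csv`, `genotypes.txt`,
#'   `map.txt`, `phenotypes.csv` and (optionally) `true_bv.csv`.
#' @return List with `pedigree`, `genotypes`, `phenotypes`, `true_bv`
#'   (`NULL` when absent).
#' @export
read_population <- function(directory) {
  tb_path <- file.path(directory, "true_bv.csv")
  list(
    pedigree = read_pedigree(file.path(directory, "pedigree.csv")),
    genotypes = read_genotypes(file.path(directory, "genotypes.txt"),
                               file.path(directory, "map.txt")),
    phenotypes = tibble::as_tibble(
      utils::read.csv(file.path(directory, "phenotypes.csv"),
                      colClasses = c(id = "character"))),
    true_bv = if (file.exists(tb_path)) {
      tibble::as_tibble(utils::read.csv(tb_path,
                                        colClasses = c(id = "character")))
    }
  )
}
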