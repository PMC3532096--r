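#' Forward-in-time simulation configuration
#'
#' Describes an overlapping-generation pedigreed population bred in yearly
#' steps: founders, herds, parent eligibility ages, truncation selection on
#' an index of EBV proxies with era-dependent weights (allowing mid-span
#' sign reversals), sire-usage skew (artificial-insemination style), a SNP
#' map with uniform recombination, and pleiotropic QTLs. With `n_traits = 0`
#' parents are chosen at random (neutral drift control).
#'
#' Setting `years_step` to the generation interval and `parent_age` to
#' `c(step, step)` collapses the overlapping-generation machinery to
#' discrete generations.
#'
#' @param seed RNG seed for the whole simulation.
#' @param years first and last breeding year.
#' @param years_step breeding-year spacing (1 = every year).
#' @param n_per_year offspring born per breeding year (split across herds).
#' @param n_founders founder animals (born before `years[1]`, ages drawn to
#'   make them eligible in the first breeding year).
#' @param parent_age min/max parent age in years.
#' @param prop_sires,prop_dams fraction of eligible males/females selected
#'   as parents each year.
#' @param sire_skew geometric usage weight across selected sires ranked by
#'   index (1 = uniform usage; smaller = heavier use of top sires).
#' @param herd_props herd size proportions (must sum to 1); matings stay
#'   within herd, emulating closed sub-populations.
#' @param n_chromosomes,snps_per_chrom,chrom_length_bp,morgans_per_chrom
#'   marker map: uniform positions, Haldane recombination, no interference.
#' @param founder_freq_range founder allele frequencies drawn uniformly in
#'   this range.
#' @param n_traits,trait_h2,ebv_r2 number of traits, heritabilities, and
#'   accuracies (r2) of the EBV proxies animals are selected on.
#' @param n_qtl QTLs sampled among the SNPs (pleiotropic across traits).
#' @param qtl_effects optional `n_qtl x n_traits` effect matrix (drawn
#'   standard normal through `qtl_effect_corr` if NULL).
#' @param qtl_effect_corr trait-by-trait correlation of QTL effects.
#' @param qtl_loci optional SNP indices to use as QTLs.
#' @param qtl_freq optional founder frequency forced at the QTL loci.
#' @param index_eras list of `list(until = year, weights = <n_traits>)`
#'   selection-index eras, tried in order; default one era of equal weights.
#' @param missing_rate genotype missingness injected at output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       years = c(1950, 2000), years_step = 1,
                       n_per_year = 60, n_founders = 200,
                       parent_age = c(2, 8),
                       prop_sires = 0.2, prop_dams = 0.8, sire_skew = 0.85,
                       herd_props = 1,
                       n_chromosomes = 5, snps_per_chrom = 200,
                       chrom_length_bp = 1e8, morgans_per_chrom = 1,
                       founder_freq_range = c(0.1, 0.9),
                       n_traits = 0, trait_h2 = NULL, ebv_r2 = NULL,
                       n_qtl = 0, qtl_effects = NULL, qtl_effect_corr = NULL,
                       qtl_loci = NULL, qtl_freq = NULL,
                       index_eras = NULL, missing_rate = 0) {
  stopifnot(length(years) == 2, years[2] > years[1], years_step >= 1,
            n_per_year >= 2, n_founders >= 4,
            parent_age[1] >= 1, parent_age[2] >= parent_age[1],
            prop_sires > 0, prop_sires <= 1, prop_dams > 0, prop_dams <= 1,
            sire_skew > 0, sire_skew <= 1,
            abs(sum(herd_props) - 1) < 1e-8,
            n_chromosomes >= 1, snps_per_chrom >= 1,
            missing_rate >= 0, missing_rate < 1)
  if (n_traits > 0) {
    trait_h2 <- trait_h2 %||% rep(0.4, n_traits)
    ebv_r2 <- ebv_r2 %||% rep(0.7, n_traits)
    stopifnot(length(trait_h2) == n_traits, all(trait_h2 > 0 & trait_h2 < 1),
              length(ebv_r2) == n_traits, all(ebv_r2 > 0 & ebv_r2 <= 1))
    if (n_qtl < 1) stop("selected traits need n_qtl >= 1")
    index_eras <- index_eras %||%
      list(list(until = Inf, weights = rep(1, n_traits)))
    for (era in index_eras) {
      if (length(era$weights) != n_traits || !all(is.finite(era$weights))) {
        stop("each era needs finite weights of length n_traits")
      }
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

# One gamete from a parent's two haplotypes: Haldane crossovers at Poisson
# count per chromosome, uniform positions, random starting phase.
sim_gamete <- function(h1, h2, chrom_index, pos_morgan, morgans) {
  out <- integer(length(h1))
  for (ch in seq_along(chrom_index)) {
    idx <- chrom_index[[ch]]
    k <- rpois(1, morgans)
    start <- runif(1) < 0.5
    if (k == 0L) {
      out[idx] <- if (start) h1[idx] else h2[idx]
    } else {
      cuts <- sort(runif(k, 0, morgans))
      seg <- findInterval(pos_morgan[idx], cuts)
      use1 <- (seg + !start) %% 2L == 1L
      out[idx] <- ifelse(use1, h1[idx], h2[idx])
    }
  }
  out
}

#' Simulate a pedigreed population under (or free of) selection
#'
#' Runs the forward model described by [sim_config()]: founders drawn at
#' Hardy-Weinberg from per-locus founder frequencies, then yearly breeding
#' cycles in which eligible parents are truncation-selected within herd on
#' the era's index of EBV proxies (or chosen at random when no traits are
#' configured), matings produce offspring through Mendelian segregation with
#' Haldane recombination, and every animal's true breeding values and noisy
#' EBV proxies are recorded. Reproducible: the same config (including seed)
#' gives a bit-identical population.
#'
#' @param cfg a [sim_config()].
#' @return object of class `sim_population`: `pedigree` ([pedigree()]),
#'   `genotypes` ([genotype_dataset()] over all animals, with missingness
#'   injected if configured), `tbv` and `ebv` (animals x traits), `sex`
#'   (`"M"`/`"F"`), `herd`, `truth` (QTL SNP ids, effect matrix, founder
#'   frequencies), `trajectories` (birth-year x SNP allele-frequency matrix)
#'   and the `config`.
#' @export
simulate_selected_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, sim_population_impl(cfg))
}

sim_population_impl <- function(cfg) {
  m <- cfg$n_chromosomes * cfg$snps_per_chrom
  chrom <- rep(as.character(seq_len(cfg$n_chromosomes)),
               each = cfg$snps_per_chrom)
  pos_bp <- unlist(lapply(seq_len(cfg$n_chromosomes), function(i)
    sort(as.integer(round(runif(cfg$snps_per_chrom, 1, cfg$chrom_length_bp))))))
  map <- data.frame(snp = paste0("snp", seq_len(m)), chrom = chrom,
                    pos = pos_bp, stringsAsFactors = FALSE)
  pos_morgan <- (pos_bp / cfg$chrom_length_bp) * cfg$morgans_per_chrom
  chrom_index <- split(seq_len(m), chrom)[as.character(seq_len(cfg$n_chromosomes))]

  p0 <- runif(m, cfg$founder_freq_range[1], cfg$founder_freq_range[2])
  n_tr <- cfg$n_traits
  qtl <- integer(0); eff <- NULL
  if (cfg$n_qtl > 0) {
    qtl <- cfg$qtl_loci %||% sort(sample.int(m, cfg$n_qtl))
    if (!is.null(cfg$qtl_freq)) p0[qtl] <- cfg$qtl_freq
    if (is.null(cfg$qtl_effects)) {
      eff <- matrix(rnorm(cfg$n_qtl * max(n_tr, 1)), cfg$n_qtl)
      if (!is.null(cfg$qtl_effect_corr)) {
        eff <- eff %*% chol(cfg$qtl_effect_corr)
      }
    } else {
      eff <- as.matrix(cfg$qtl_effects)
      stopifnot(nrow(eff) == cfg$n_qtl)
    }
  }

  breeding_years <- seq(cfg$years[1], cfg$years[2], by = cfg$years_step)
  n_herds <- length(cfg$herd_props)
  births_per_herd <- pmax(2L, as.integer(round(cfg$n_per_year * cfg$herd_props)))
  n_total <- cfg$n_founders + length(breeding_years) * sum(births_per_herd)

  H1 <- matrix(0L, n_total, m); H2 <- matrix(0L, n_total, m)
  sire_i <- integer(n_total); dam_i <- integer(n_total)
  birth_year <- integer(n_total); sex <- integer(n_total)  # 1 = M, 2 = F
  herd <- integer(n_total)

  # founders: HWE draws, ages spread over the eligibility window, herds and
  # sexes interleaved so every herd starts with both sexes
  nf <- cfg$n_founders
  H1[1:nf, ] <- matrix(rbinom(nf * m, 1L, rep(p0, each = nf)), nf)
  H2[1:nf, ] <- matrix(rbinom(nf * m, 1L, rep(p0, each = nf)), nf)
  f_years <- seq(cfg$years[1] - cfg$parent_age[2],
                 cfg$years[1] - cfg$parent_age[1])
  birth_year[1:nf] <- rep_len(f_years, nf)
  herd[1:nf] <- rep_len(rep(seq_len(n_herds), round(cfg$herd_props * 100)), nf)
  sex[1:nf] <- rep_len(c(1L, 2L), nf)

  tbv <- matrix(0, n_total, max(n_tr, 1))
  ebv <- matrix(0, n_total, max(n_tr, 1))
  compute_tbv <- function(rows) {
    if (!length(qtl)) return()
    dos <- H1[rows, qtl, drop = FALSE] + H2[rows, qtl, drop = FALSE]
    tbv[rows, ] <<- dos %*% eff
  }
  compute_tbv(1:nf)
  # per-trait scale anchors from the founder cohort
  sd_tbv <- pmax(apply(tbv[1:nf, , drop = FALSE], 2, sd), 1e-8)
  if (n_tr > 0) {
    ebv_noise_sd <- sd_tbv * sqrt((1 - cfg$ebv_r2) / cfg$ebv_r2)
    ebv[1:nf, ] <- tbv[1:nf, ] +
      matrix(rnorm(nf * n_tr), nf) %*% diag(ebv_noise_sd, n_tr)
  }

  era_weights <- function(y) {
    if (n_tr == 0) return(NULL)
    for (era in cfg$index_eras) if (y <= era$until) return(era$weights)
    cfg$index_eras[[length(cfg$index_eras)]]$weights
  }

  cur <- nf
  for (y in breeding_years) {
    w <- era_weights(y)
    for (h in seq_len(n_herds)) {
      elig <- which(seq_len(n_total) <= cur & herd == h &
                      birth_year <= y - cfg$parent_age[1] &
                      birth_year >= y - cfg$parent_age[2])
      males <- elig[sex[elig] == 1L]
      females <- elig[sex[elig] == 2L]
      if (!length(males) || !length(females)) {
        stop("extinction in year ", y, " (herd ", h,
             "): no eligible ", if (length(males)) "dams" else "sires")
      }
      score <- function(rows) {
        if (is.null(w) || all(w == 0)) return(runif(length(rows)))
        as.numeric(ebv[rows, , drop = FALSE] %*% (w / sd_tbv))
      }
      ns <- max(1L, ceiling(cfg$prop_sires * length(males)))
      nd <- max(1L, ceiling(cfg$prop_dams * length(females)))
      sires <- males[order(score(males), decreasing = TRUE)][1:ns]
      dams <- females[order(score(females), decreasing = TRUE)][1:nd]

      nb <- births_per_herd[h]
      sire_pick <- sires[sample.int(ns, nb, replace = TRUE,
                                    prob = cfg$sire_skew^(0:(ns - 1)))]
      dam_pick <- if (nb <= nd) dams[sample.int(nd, nb)] else
        dams[sample.int(nd, nb, replace = TRUE)]
      rows <- cur + seq_len(nb)
      for (b in seq_len(nb)) {
        i <- rows[b]
        H1[i, ] <- sim_gamete(H1[sire_pick[b], ], H2[sire_pick[b], ],
                              chrom_index, pos_morgan, cfg$morgans_per_chrom)
        H2[i, ] <- sim_gamete(H1[dam_pick[b], ], H2[dam_pick[b], ],
                              chrom_index, pos_morgan, cfg$morgans_per_chrom)
      }
      sire_i[rows] <- sire_pick
      dam_i[rows] <- dam_pick
      birth_year[rows] <- y
      herd[rows] <- h
      sex[rows] <- rbinom(nb, 1L, 0.5) + 1L
      compute_tbv(rows)
      if (n_tr > 0) {
        ebv[rows, ] <- tbv[rows, ] +
          matrix(rnorm(nb * n_tr), nb) %*% diag(ebv_noise_sd, n_tr)
      }
      cur <- cur + nb
    }
  }

  ids <- paste0("A", seq_len(n_total))
  # within-year fraction kept strictly below 1 so floor() recovers the cohort
  birth_date <- birth_year + floor(runif(n_total) * 1000) / 1000
  calls <- H1 + H2
  storage.mode(calls) <- "double"
  rownames(calls) <- ids; colnames(calls) <- map$snp
  if (cfg$missing_rate > 0) {
    calls[matrix(runif(length(calls)) < cfg$missing_rate,
                 nrow(calls))] <- NA_real_
  }
  g <- genotype_dataset(calls, map, birth_date)

  ped <- pedigree(ids,
                  ifelse(sire_i > 0, paste0("A", sire_i), "0"),
                  ifelse(dam_i > 0, paste0("A", dam_i), "0"),
                  birth_date)
  years_all <- sort(unique(birth_year))
  traj <- t(vapply(years_all, function(yy) {
    rows <- birth_year == yy
    colMeans(H1[rows, , drop = FALSE] + H2[rows, , drop = FALSE]) / 2
  }, numeric(m)))
  rownames(traj) <- years_all

  dimnames(tbv) <- list(ids, if (n_tr > 0) paste0("trait", 1:n_tr) else NULL)
  dimnames(ebv) <- dimnames(tbv)
  structure(list(
    pedigree = ped, genotypes = g,
    tbv = if (n_tr > 0) tbv else NULL,
    ebv = if (n_tr > 0) ebv else NULL,
    sex = c("M", "F")[sex], herd = herd,
    truth = list(qtl_snp = map$snp[qtl], qtl_index = qtl, effects = eff,
                 founder_freq = p0, sd_tbv = if (n_tr > 0) sd_tbv else NULL),
    trajectories = traj,
    config = cfg), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("sim_population:", nrow(x$genotypes$calls), "animals,",
      ncol(x$genotypes$calls), "SNPs,",
      length(unique(x$herd)), "herd(s)\n")
  cat(sprintf("  birth years %d-%d; %d QTL(s)\n",
              min(floor(x$genotypes$birth_date)),
              max(floor(x$genotypes$birth_date)),
              length(x$truth$qtl_index)))
  invisible(x)
}

#' Draw a genotyped subsample from a simulated population
#'
#' Emulates genotyping-depth schedules. `"random"` samples uniformly;
#' `"herd_shift"` is family-biased temporal sampling: animals born before
#' `split_year` are drawn from the herds other than `late_herd`, animals
#' born at or after it only from `late_herd` — the confounding of family
#' with time that breaks naive scans.
#'
#' @param pop a `sim_population`.
#' @param n animals to sample.
#' @param scheme `"random"` or `"herd_shift"`.
#' @param split_year year separating the early and late sampling windows.
#' @param late_herd herd index sampled in the late window.
#' @param early_frac fraction of the sample drawn from the early window.
#' @param seed RNG seed.
#' @return character vector of animal ids.
#' @export
sample_genotyped <- function(pop, n, scheme = c("random", "herd_shift"),
                             split_year = NULL, late_herd = NULL,
                             early_frac = 0.5, seed = NULL) {
  scheme <- match.arg(scheme)
  ids <- rownames(pop$genotypes$calls)
  by <- floor(pop$genotypes$birth_date)
  with_seed(seed, {
    if (scheme == "random") {
      sample(ids, n)
    } else {
      if (is.null(split_year) || is.null(late_herd)) {
        stop("herd_shift needs split_year and late_herd")
      }
      n_early <- round(n * early_frac)
      early_pool <- ids[by < split_year & pop$herd != late_herd]
      late_pool <- ids[by >= split_year & pop$herd == late_herd]
      if (length(early_pool) < n_early || length(late_pool) < n - n_early) {
        stop("sampling pools too small for requested n")
      }
      c(sample(early_pool, n_early), sample(late_pool, n - n_early))
    }
  })
}

#' Neutral Wright-Fisher drift trajectories
#'
#' Binomial resampling of allele frequencies with `2 Ne` gametes per
#' generation; fixation is absorbing. Optionally draws diploid
#' Hardy-Weinberg genotype samples at requested generations.
#'
#' @param Ne effective population size (> 0).
#' @param p0 starting frequencies (one per locus), strictly inside (0, 1).
#' @param generations number of transitions to simulate.
#' @param sample_sizes optional named vector `generation -> n` of cohort
#'   genotype samples to draw (generation 0 = initial state).
#' @param seed RNG seed.
#' @return list: `trajectories` ((generations + 1) x loci frequency matrix,
#'   row names = generation), `samples` (named list of n x loci dosage
#'   matrices), `Ne`.
#' @export
simulate_neutral_drift <- function(Ne, p0, generations, sample_sizes = NULL,
                                   seed = NULL) {
  if (Ne <= 0) stop("Ne must be positive")
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must lie strictly inside (0, 1)")
  m <- length(p0)
  with_seed(seed, {
    traj <- matrix(NA_real_, generations + 1, m,
                   dimnames = list(0:generations, NULL))
    traj[1, ] <- p <- p0
    two_ne <- round(2 * Ne)
    for (g in seq_len(generations)) {
      free <- p > 0 & p < 1
      p[free] <- rbinom(sum(free), two_ne, p[free]) / two_ne
      traj[g + 1, ] <- p
    }
    samples <- list()
    if (!is.null(sample_sizes)) {
      for (gen in names(sample_sizes)) {
        pg <- traj[as.character(gen), ]
        ns <- sample_sizes[[gen]]
        samples[[gen]] <- matrix(rbinom(ns * m, 2L, rep(pg, each = ns)), ns)
      }
    }
    list(trajectories = traj, samples = samples, Ne = Ne)
  })
}

#' Simulate ASE-level selection response with known trait intensities
#'
#' Generates per-SNP trait ASEs and the birth-date ASEs they would induce
#' under the expected allele-frequency response to index selection,
#' `delta_q = -i p q a / sigma`, directly on the ASE scale: trait ASEs are
#' standard normal (uncorrelated traits), and the birth-date ASE of SNP `j`
#' is `sum_t i_t * p_j q_j * a_jt / sd(a_t) + noise`. The default noise puts
#' the strongest trait's single-trait coefficient of determination near 0.6,
#' the magnitude seen in cattle ASE regressions.
#'
#' @param m number of SNPs.
#' @param intensities true relative selection intensities, one per trait
#'   (signed).
#' @param noise_sd residual standard deviation on the birth-date ASEs.
#' @param freq_range allele frequencies drawn uniformly in this range.
#' @param seed RNG seed.
#' @return list: `birth_ases`, `trait_ases` (m x traits), `p`,
#'   `intensities`.
#' @export
simulate_ase_response <- function(m = 935, intensities = c(1, 0.3, 0),
                                  noise_sd = 0.15,
                                  freq_range = c(0.1, 0.9), seed = NULL) {
  with_seed(seed, {
    n_tr <- length(intensities)
    p <- runif(m, freq_range[1], freq_range[2])
    a <- matrix(rnorm(m * n_tr), m,
                dimnames = list(NULL, paste0("trait", seq_len(n_tr))))
    x <- sweep(a, 2L, apply(a, 2, sd), "/") * (p * (1 - p))
    birth <- as.numeric(x %*% intensities) + rnorm(m, 0, noise_sd)
    list(birth_ases = birth, trait_ases = a, p = p,
         intensities = intensities)
  })
}

# ---- registered fixtures ----------------------------------------------------

#' Built-in simulation fixtures
#'
#' `make_fixture()` builds one of the registered in-memory fixtures used by
#' the test-suite and documentation; `make_fixture_bundle()` writes it to
#' disk in the same formats the readers consume (counts CSV + map CSV +
#' pedigree CSV, truth TSV, and a key = value config log).
#'
#' Fixtures:
#' \describe{
#'   \item{tiny_qc}{400 animals x 10 SNPs with exactly one violation of each
#'     QC filter (call rate, animal call rate, MAF, HWE).}
#'   \item{gblup_oracle}{n = 50, m = 200 unstructured genotypes with a
#'     polygenic dependent variable; for dense-solver and SNP-BLUP oracles.}
#'   \item{confounded_sampling}{neutral two-herd population (one small
#'     closed herd) with herd-shifted temporal sampling of 300 animals at
#'     1,000 SNPs; neutral loci, but family confounded with time.}
#'   \item{selected_sweep}{one large-effect QTL under 10 generations of
#'     truncation selection (500 animals/generation, discrete generations),
#'     500 genotyped.}
#'   \item{neutral_null}{random-mating single-herd population, 500 genotyped
#'     at 1,000 SNPs; calibration null.}
#' }
#'
#' @param name fixture name (see Details).
#' @param seed RNG seed.
#' @return `make_fixture()`: a list whose contents depend on the fixture
#'   (always includes a [genotype_dataset()] `g`); `make_fixture_bundle()`:
#'   named character vector of the files written.
#' @export
make_fixture <- function(name = c("tiny_qc", "gblup_oracle",
                                  "confounded_sampling", "selected_sweep",
                                  "neutral_null"),
                         seed = 20111) {
  name <- match.arg(name)
  switch(name,
         tiny_qc = fixture_tiny_qc(seed),
         gblup_oracle = fixture_gblup_oracle(seed),
         confounded_sampling = fixture_confounded(seed),
         selected_sweep = fixture_sweep(seed),
         neutral_null = fixture_neutral_null(seed))
}

fixture_tiny_qc <- function(seed) {
  with_seed(seed, {
    n <- 400
    # clean template: exact HWE proportions at p = 0.5 (chi-square 0, MAF 0.5)
    clean <- sample(rep(c(2, 1, 0), c(100, 200, 100)))
    calls <- sapply(1:10, function(j) sample(clean))
    colnames(calls) <- paste0("qc", 1:10)
    rownames(calls) <- paste0("ind", 1:n)
    calls[1:60, 1] <- NA          # snp call rate 85% < 90%
    calls[, 2] <- 2                # monomorphic: MAF 0
    calls[, 3] <- sample(rep(c(2, 0), c(200, 200)))  # no hets: HWE chi2 = 400
    calls[1, 4:5] <- NA            # animal 1 call rate 8/10 = 80% < 95%
    map <- data.frame(snp = colnames(calls), chrom = "1",
                      pos = (1:10) * 1e5, stringsAsFactors = FALSE)
    list(g = genotype_dataset(calls, map, birth_date = rep(2000, n)),
         expected_removed = c(snp_call_rate = 1, animal_call_rate = 1,
                              maf = 1, hwe = 1))
  })
}

fixture_gblup_oracle <- function(seed, n = 50, m = 200, h2 = 0.5) {
  with_seed(seed, {
    p0 <- runif(m, 0.2, 0.8)
    calls <- matrix(rbinom(n * m, 2L, rep(p0, each = n)), n,
                    dimnames = list(paste0("ind", 1:n), paste0("snp", 1:m)))
    storage.mode(calls) <- "double"
    map <- data.frame(snp = colnames(calls), chrom = "1", pos = (1:m) * 1e4,
                      stringsAsFactors = FALSE)
    alpha <- rnorm(m, 0, sqrt(1 / m))
    gval <- as.numeric(scale(calls %*% alpha)) * sqrt(h2)
    y <- gval + rnorm(n, 0, sqrt(1 - h2))
    g <- genotype_dataset(calls, map, birth_date = 1990 + runif(n, 0, 20))
    list(g = g, y = y, p = colMeans(calls) / 2, alpha = alpha, h2 = h2)
  })
}

fixture_confounded <- function(seed) {
  cfg <- sim_config(seed = seed,
                    years = c(1950, 2000), n_per_year = 60, n_founders = 200,
                    herd_props = c(0.8, 0.2),
                    prop_sires = 0.2, prop_dams = 0.8, sire_skew = 0.85,
                    n_chromosomes = 5, snps_per_chrom = 200)
  pop <- simulate_selected_population(cfg)
  ids <- sample_genotyped(pop, 300, scheme = "herd_shift",
                          split_year = 1985, late_herd = 2,
                          early_frac = 0.5, seed = seed + 1)
  list(pop = pop, g = subset_genotypes(pop$genotypes, animals = ids),
       genotyped_ids = ids)
}

fixture_sweep <- function(seed) {
  # One QTL at founder frequency 0.15, 10 discrete generations of 500
  # (years_step = parent ages = the 5-year generation interval). Sizing by
  # the breeder's equation: mean intensity i ~ 0.5 (sires top 50%, dams top
  # 90%), proxy accuracy r = 0.6, so per-generation dq ~ i*pq*a*r/sd(TBV)
  # starts near 0.08 and the sweep reaches ~0.95 without fixing.
  cfg <- sim_config(seed = seed,
                    years = c(1950, 1995), years_step = 5,
                    n_per_year = 500, n_founders = 500,
                    parent_age = c(5, 5),
                    prop_sires = 0.5, prop_dams = 0.9, sire_skew = 1,
                    n_chromosomes = 5, snps_per_chrom = 200,
                    n_traits = 1, trait_h2 = 0.4, ebv_r2 = 0.36,
                    n_qtl = 1, qtl_loci = 500L, qtl_freq = 0.15,
                    qtl_effects = matrix(0.485, 1, 1))
  pop <- simulate_selected_population(cfg)
  ids <- sample_genotyped(pop, 500, scheme = "random", seed = seed + 1)
  list(pop = pop, g = subset_genotypes(pop$genotypes, animals = ids),
       genotyped_ids = ids, qtl_snp = pop$truth$qtl_snp)
}

fixture_neutral_null <- function(seed) {
  cfg <- sim_config(seed = seed,
                    years = c(1950, 2000), n_per_year = 60, n_founders = 200,
                    prop_sires = 0.5, prop_dams = 0.9, sire_skew = 1,
                    n_chromosomes = 5, snps_per_chrom = 200)
  pop <- simulate_selected_population(cfg)
  ids <- sample_genotyped(pop, 500, scheme = "random", seed = seed + 1)
  list(pop = pop, g = subset_genotypes(pop$genotypes, animals = ids),
       genotyped_ids = ids)
}

#' @rdname make_fixture
#' @param dir output directory (created if needed).
#' @export
make_fixture_bundle <- function(name, dir, seed = 20111) {
  fx <- make_fixture(name, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, paste0(name, "_genotypes.csv")),
             map = file.path(dir, paste0(name, "_map.csv")))
  write_genotypes(fx$g, paths["genotypes"], format = "counts_csv",
                  map_path = paths["map"])
  if (!is.null(fx$pop)) {
    paths["pedigree"] <- file.path(dir, paste0(name, "_pedigree.csv"))
    write_pedigree(fx$pop$pedigree, paths["pedigree"])
    paths["truth"] <- file.path(dir, paste0(name, "_truth.tsv"))
    tr <- data.frame(snp = fx$pop$genotypes$map$snp,
                     founder_freq = fx$pop$truth$founder_freq,
                     is_qtl = fx$pop$genotypes$map$snp %in% fx$pop$truth$qtl_snp)
    write.table(tr, paths["truth"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths["config"] <- file.path(dir, paste0(name, "_config.txt"))
    cfg <- fx$pop$config
    keys <- vapply(cfg, function(v)
      paste(deparse(v, width.cutoff = 500), collapse = " "), "")
    writeLines(paste(names(cfg), keys, sep = " = "), paths["config"])
  }
  paths
}
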